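#' Map reads to genomes with exact k-mer seeding and ungapped extension
#'
#' Every genome sharing an exact `seed_k`-mer with the read (on either
#' strand) is scored by ungapped extension over the full read; hits with
#' percent identity at or above `min_identity_pct` are reported.  Reads
#' overhanging a genome end are scored over the overlapping bases only.
#' Each read's best hit (highest identity, then longest alignment, ties
#' broken by lexicographically smallest `(genome_id, start)`) is flagged.
#'
#' Coordinates are 0-based half-open on the genome.
#'
#' @param reads Read tibble (`read_id`, `sequence`).
#' @param genomes Reference tibble (`genome_id`, `sequence`) or a named
#'   character vector of sequences.
#' @param seed_k Exact seed length (1-31); must not exceed the read length
#'   for a read to be mappable.
#' @param min_identity_pct Identity threshold in percent, inclusive.
#' @param stride Spacing between successive seed positions along the read.
#' @return Tibble of hits: `read_id`, `genome_id`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`), `matches`, `aligned_length`, `percent_identity`, `best`.
#' @export
map_reads <- function(reads, genomes, seed_k = 21, min_identity_pct = 95,
                      stride = 1) {
  if (is.data.frame(genomes)) {
    genomes <- setNames(genomes$sequence, genomes$genome_id)
  }
  if (length(genomes) == 0) stop("empty genome set", call. = FALSE)
  if (min_identity_pct < 0 || min_identity_pct > 100) {
    stop("min_identity_pct must be in [0, 100]", call. = FALSE)
  }
  hits <- cpp_map_reads(reads$sequence, unname(genomes), as.integer(seed_k),
                        min_identity_pct, as.integer(stride))
  out <- tibble::tibble(
    read_id = reads$read_id[hits$read_idx],
    genome_id = names(genomes)[hits$genome_idx],
    start = hits$start,
    end = hits$end,
    strand = ifelse(hits$forward == 1, "+", "-"),
    matches = hits$matches,
    aligned_length = hits$aligned_length,
    percent_identity = 100 * hits$matches / hits$aligned_length
  )
  flag_best_hits(out)
}

# Deterministic best-hit flag: highest identity, then longest alignment,
# then lexicographic (genome_id, start).
flag_best_hits <- function(hits) {
  if (nrow(hits) == 0) {
    hits$best <- logical(0)
    return(hits)
  }
  ord <- order(hits$read_id, -hits$percent_identity, -hits$aligned_length,
               hits$genome_id, hits$start)
  best_rows <- ord[!duplicated(hits$read_id[ord])]
  hits$best <- seq_len(nrow(hits)) %in% best_rows
  hits
}

#' Remove reads matching a host genome
#'
#' Reads with any hit to the host genome at or above the identity threshold
#' are discarded; what remains is the sample's decontaminated read set,
#' whose size normalises downstream abundances.
#'
#' @param reads Read tibble.
#' @param host_genome Host genome sequence (single string).
#' @param min_identity_pct Identity threshold (inclusive), default 95.
#' @param seed_k,stride Passed to [map_reads()].
#' @return Tibble of retained reads with attribute `n_removed`.
#' @export
remove_host <- function(reads, host_genome, min_identity_pct = 95,
                        seed_k = 21, stride = 1) {
  hits <- map_reads(reads, c(host = host_genome), seed_k = seed_k,
                    min_identity_pct = min_identity_pct, stride = stride)
  keep <- !(reads$read_id %in% hits$read_id)
  res <- reads[keep, ]
  attr(res, "n_removed") <- sum(!keep)
  res
}

#' Run the full read-processing chain
#'
#' Enforces the pipeline order trim -> de-duplicate -> host removal and
#' returns the decontaminated reads together with a read-accounting table.
#'
#' @param reads Raw read tibble.
#' @param host_genome Host genome sequence.
#' @param phred_min,min_length Passed to [quality_trim()].
#' @param min_identity_pct,seed_k,stride Passed to [remove_host()].
#' @return List with `reads` (decontaminated read tibble) and `accounting`
#'   (tibble of counts after each stage; the final count is the sample's
#'   decontaminated read number).
#' @export
process_reads <- function(reads, host_genome, phred_min = 10, min_length = 50,
                          min_identity_pct = 95, seed_k = 21, stride = 1) {
  trimmed <- quality_trim(reads, phred_min, min_length)
  deduped <- deduplicate(trimmed)
  decon <- remove_host(deduped, host_genome, min_identity_pct, seed_k, stride)
  acc <- tibble::tibble(
    stage = c("raw", "trimmed", "deduplicated", "host_removed"),
    reads = c(nrow(reads), nrow(trimmed), nrow(deduped), nrow(decon))
  )
  list(reads = decon, accounting = acc)
}
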