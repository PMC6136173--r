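#' Simulation configuration for shotgun read generation
#'
#' @param reads_per_sample Reads per sample (>= 1).
#' @param read_length Read length in bp.
#' @param substitution_error_rate Per-base substitution probability.
#' @param host_contamination_fraction Fraction of reads drawn from the host
#'   genome rather than the viral community.
#' @param duplicate_rate Fraction of reads that are exact copies of
#'   previously emitted reads (PCR/optical duplicates).
#' @param base_quality Phred score assigned to every simulated base.
#' @param seed Integer RNG seed; per-sample sub-seeds are derived from it so
#'   samples can be generated independently yet reproducibly.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(reads_per_sample = 50000,
                       read_length = 150,
                       substitution_error_rate = 0.005,
                       host_contamination_fraction = 0.3,
                       duplicate_rate = 0.05,
                       base_quality = 37L,
                       seed = 1) {
  if (reads_per_sample < 1) stop("reads_per_sample must be >= 1", call. = FALSE)
  check_fraction(substitution_error_rate, "substitution_error_rate")
  check_fraction(host_contamination_fraction, "host_contamination_fraction")
  check_fraction(duplicate_rate, "duplicate_rate")
  structure(list(reads_per_sample = as.integer(reads_per_sample),
                 read_length = as.integer(read_length),
                 substitution_error_rate = substitution_error_rate,
                 host_contamination_fraction = host_contamination_fraction,
                 duplicate_rate = duplicate_rate,
                 base_quality = as.integer(base_quality),
                 seed = as.integer(seed)),
            class = "sim_config")
}

mutate_sequences <- function(seqs, error_rate) {
  if (error_rate <= 0) return(seqs)
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, error_rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(n_err > 0)) {
    pos <- sample.int(lens[i], n_err[i])
    s <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    for (p in pos) {
      s[p] <- sample(setdiff(bases, s[p]), 1)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

simulate_sample_reads <- function(sample_id, abund, reference, host_genome,
                                  config, sample_seed) {
  L <- config$read_length
  n <- config$reads_per_sample
  ok <- reference$length >= L
  if (any(!ok)) {
    warning("rejected ", sum(!ok), " genome(s) shorter than read_length",
            call. = FALSE)
  }
  weights <- abund[reference$genome_id] * reference$length
  weights[!ok] <- 0

  withr::with_seed(sample_seed, {
    is_host <- runif(n) < config$host_contamination_fraction
    origin <- rep("host", n)
    n_vir <- sum(!is_host)
    if (n_vir > 0) {
      if (sum(weights) <= 0) {
        stop("no viral genome available to sample reads from", call. = FALSE)
      }
      origin[!is_host] <- sample(reference$genome_id, n_vir, replace = TRUE,
                                 prob = weights)
    }
    src_len <- ifelse(is_host, nchar(host_genome),
                      reference$length[match(origin, reference$genome_id)])
    start <- 1L + floor(runif(n) * (src_len - L + 1))
    src_seq <- ifelse(is_host, host_genome,
                      reference$sequence[match(origin, reference$genome_id)])
    seqs <- substr(src_seq, start, start + L - 1L)
    rev <- runif(n) < 0.5
    if (any(rev)) {
      seqs[rev] <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs[rev])))
    }
    seqs <- mutate_sequences(seqs, config$substitution_error_rate)

    # duplicates: exact copies of an earlier read
    read_id <- sprintf("%s_r%06d", sample_id, seq_len(n))
    is_dup <- runif(n) < config$duplicate_rate & seq_len(n) > 1
    if (any(is_dup)) {
      idx <- which(is_dup)
      src <- 1L + floor(runif(length(idx)) * (idx - 1))
      seqs[idx] <- seqs[src]
      origin[idx] <- origin[src]
      read_id[idx] <- paste0(read_id[idx], "_dup")
    }

    qual <- strrep(rawToChar(as.raw(config$base_quality + 33L)), L)
    list(
      reads = tibble::tibble(read_id = read_id, sequence = seqs,
                             quality = qual),
      truth = tibble::tibble(sample_id = sample_id, read_id = read_id,
                             origin = origin, is_duplicate = is_dup)
    )
  })
}

#' Simulate shotgun reads from a designed community
#'
#' Reads are drawn from genomes with probability proportional to true
#' abundance times genome length, at uniform start positions and random
#' strand, with independent substitution errors; a configurable fraction of
#' reads comes from the host genome, and a fraction are exact duplicates of
#' earlier reads.
#'
#' @param design A `community_design` from [design_communities()].
#' @param host_genome Host genome sequence (single string), e.g. from
#'   [simulate_host_genome()].
#' @param config A [sim_config()].
#' @param samples Optional character vector restricting which samples to
#'   simulate; per-sample output is identical either way.
#' @param outdir Optional directory: per-sample FASTQ files plus a
#'   `truth.tsv` table are written there.
#' @return List with `reads` (named list of per-sample read tibbles:
#'   `read_id`, `sequence`, `quality`) and `truth` (tibble of per-read
#'   origins).
#' @export
simulate_reads <- function(design, host_genome, config = sim_config(),
                           samples = NULL, outdir = NULL) {
  stopifnot(inherits(design, "community_design"),
            inherits(config, "sim_config"))
  if (nchar(host_genome) < config$read_length) {
    stop("host genome must be at least read_length long", call. = FALSE)
  }
  all_ids <- design$samples$sample_id
  if (is.null(samples)) samples <- all_ids
  abund <- abund_matrix(design$abundance)

  res <- purrr::map(samples, function(sid) {
    simulate_sample_reads(sid, abund[sid, ], design$reference, host_genome,
                          config, derive_seed(config$seed, match(sid, all_ids)))
  })
  out <- list(reads = setNames(purrr::map(res, "reads"), samples),
              truth = purrr::list_rbind(purrr::map(res, "truth")))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    for (sid in samples) {
      write_fastq(out$reads[[sid]], file.path(outdir, paste0(sid, ".fastq")))
    }
    write.table(out$truth, file.path(outdir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  out
}

#' Write reads to a FASTQ file (Phred+33)
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quality))
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a read tibble
#'
#' @param path FASTQ path.
#' @return Tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  tibble::tibble(read_id = names(x),
                 sequence = as.character(x),
                 quality = as.character(S4Vectors::mcols(x)$qualities))
}
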