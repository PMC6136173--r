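#' Default host-taxonomy composition for simulated viral reference databases
#'
#' Phylum proportions follow the host-phylum mix typical of lower-airway
#' phage databases (37% Proteobacteria, 36% Firmicutes, 23% Actinobacteria,
#' 3% Bacteriodetes, 1% Fusobacteria), with genus weights concentrated on
#' the dominant airway genera (e.g. most Actinobacteria phages infecting
#' *Propionibacterium*, most Firmicutes phages infecting *Streptococcus*).
#'
#' @return A tibble with columns `host_phylum`, `host_genus` and `weight`
#'   (weights sum to 1).
#' @export
default_host_taxonomy <- function() {
  tibble::tribble(
    ~host_phylum,     ~host_genus,         ~weight,
    "Proteobacteria", "Neisseria",         0.37 * 0.30,
    "Proteobacteria", "Escherichia",       0.37 * 0.25,
    "Proteobacteria", "Acinetobacter",     0.37 * 0.20,
    "Proteobacteria", "Burkholderia",      0.37 * 0.15,
    "Proteobacteria", "Shigella",          0.37 * 0.10,
    "Firmicutes",     "Streptococcus",     0.36 * 0.60,
    "Firmicutes",     "Lactobacillus",     0.36 * 0.15,
    "Firmicutes",     "Bacillus",          0.36 * 0.15,
    "Firmicutes",     "Veillonella",       0.36 * 0.10,
    "Actinobacteria", "Propionibacterium", 0.23 * 0.78,
    "Actinobacteria", "Gardnerella",       0.23 * 0.12,
    "Actinobacteria", "Actinomyces",       0.23 * 0.10,
    "Bacteriodetes",  "Prevotella",        0.03 * 1.00,
    "Fusobacteria",   "Leptotrichia",      0.01 * 1.00
  )
}

random_dna <- function(n_seqs, lengths) {
  vapply(seq_len(n_seqs), function(i) {
    paste(sample(c("A", "C", "G", "T"), lengths[i], replace = TRUE),
          collapse = "")
  }, character(1))
}

#' Generate a synthetic viral reference database
#'
#' Draws uniform-base genome sequences and assigns each phage a bacterial
#' host genus/phylum according to `taxonomy`; a small fraction of genomes are
#' eukaryotic viruses without a bacterial host.
#'
#' @param n_genomes Number of genomes (>= 1).
#' @param length_range Two-element integer range of genome lengths (min >=
#'   1000 bp).
#' @param taxonomy Tibble with `host_phylum`, `host_genus`, `weight`
#'   (weights must sum to 1); see [default_host_taxonomy()].
#' @param eukaryotic_fraction Expected fraction of eukaryotic (non-phage)
#'   viruses.
#' @param seed Integer RNG seed; fixed seed gives byte-identical output.
#' @return Tibble with columns `genome_id`, `sequence`, `length`,
#'   `virus_type` (`"phage"` or `"eukaryotic"`), `host_phylum`, `host_genus`
#'   (`NA` for eukaryotic viruses).
#' @export
generate_reference_db <- function(n_genomes = 200,
                                  length_range = c(1500, 8000),
                                  taxonomy = default_host_taxonomy(),
                                  eukaryotic_fraction = 0.01,
                                  seed = 1) {
  if (!is.numeric(n_genomes) || n_genomes < 1) {
    stop("n_genomes must be >= 1", call. = FALSE)
  }
  if (length_range[1] < 1000) {
    stop("genome lengths must be >= 1000 bp", call. = FALSE)
  }
  if (abs(sum(taxonomy$weight) - 1) > 1e-8) {
    stop("taxonomy weights must sum to 1", call. = FALSE)
  }
  check_fraction(eukaryotic_fraction, "eukaryotic_fraction")
  n_genomes <- as.integer(n_genomes)

  withr::with_seed(seed, {
    lengths <- sample(length_range[1]:length_range[2], n_genomes,
                      replace = TRUE)
    seqs <- random_dna(n_genomes, lengths)
    is_euk <- runif(n_genomes) < eukaryotic_fraction
    tax_idx <- sample.int(nrow(taxonomy), n_genomes, replace = TRUE,
                          prob = taxonomy$weight)
    tibble::tibble(
      genome_id = sprintf("vpop_%04d", seq_len(n_genomes)),
      sequence = seqs,
      length = lengths,
      virus_type = ifelse(is_euk, "eukaryotic", "phage"),
      host_phylum = ifelse(is_euk, NA_character_,
                           taxonomy$host_phylum[tax_idx]),
      host_genus = ifelse(is_euk, NA_character_,
                          taxonomy$host_genus[tax_idx])
    )
  })
}

#' Simulate a host genome used as the decontamination target
#'
#' A single random sequence standing in for host genomic background; host
#' contamination reads are drawn from it and removed again by
#' [remove_host()].
#'
#' @param length Genome length in bp.
#' @param seed Integer RNG seed.
#' @return A single character string of A/C/G/T.
#' @export
simulate_host_genome <- function(length = 1e5, seed = 1) {
  stopifnot(length >= 1)
  withr::with_seed(seed, random_dna(1, as.integer(length)))
}

#' Write reference genomes to FASTA
#'
#' @param reference Tibble from [generate_reference_db()] (or any tibble with
#'   `genome_id` and `sequence`).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  x <- Biostrings::DNAStringSet(reference$sequence)
  names(x) <- reference$genome_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}
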