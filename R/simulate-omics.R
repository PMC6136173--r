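#' Simulate companion metabolite, cytokine and bacteriome matrices
#'
#' Metabolite and cytokine features are Gaussian log-intensities with a
#' planted between-group mean shift; the bacteriome is a relative-abundance
#' matrix with no group effect (its shift defaults to 0), mirroring a study
#' design in which viral communities and metabolomes differ between groups
#' while bacterial communities do not.  A dropout parameter controls the
#' fraction of samples in which a feature is undetected (value 0), feeding
#' the >= 50%-presence reporting filter.
#'
#' @param design A `community_design` (supplies sample ids and groups).
#' @param n_metabolites,n_cytokines,n_bacteria Feature counts (> 0).
#' @param shift Named list of group mean shifts in SD units:
#'   `metabolite`, `cytokine`, `bacteriome` (default 2, 1, 0); the shift is
#'   added to the first group's shifted features.
#' @param shifted_fraction Fraction of metabolite/cytokine features carrying
#'   the shift.
#' @param dropout Per-feature probability that a sample is a non-detect.
#' @param seed Integer RNG seed.
#' @return List of three wide tibbles (`metabolites`, `cytokines`,
#'   `bacteria`) plus `shifted_features` (character vector of planted
#'   feature names).
#' @export
simulate_omics <- function(design, n_metabolites = 83, n_cytokines = 39,
                           n_bacteria = 100,
                           shift = list(metabolite = 2, cytokine = 1,
                                        bacteriome = 0),
                           shifted_fraction = 0.7,
                           dropout = 0,
                           seed = 1) {
  if (any(c(n_metabolites, n_cytokines, n_bacteria) <= 0)) {
    stop("feature counts must be positive", call. = FALSE)
  }
  check_fraction(dropout, "dropout")
  samples <- design$samples
  g1 <- samples$group == samples$group[1]

  gauss_block <- function(prefix, p, delta) {
    m <- matrix(rnorm(nrow(samples) * p), nrow(samples), p,
                dimnames = list(samples$sample_id,
                                sprintf("%s_%03d", prefix, seq_len(p))))
    n_shift <- round(shifted_fraction * p)
    if (n_shift > 0 && delta != 0) {
      m[g1, seq_len(n_shift)] <- m[g1, seq_len(n_shift)] + delta
    }
    if (dropout > 0) {
      m[matrix(runif(length(m)) < dropout, nrow(m))] <- 0
    }
    list(tbl = abund_tibble(m),
         shifted = if (delta != 0) colnames(m)[seq_len(n_shift)]
                   else character())
  }

  withr::with_seed(seed, {
    met <- gauss_block("met", n_metabolites, shift$metabolite)
    cyt <- gauss_block("cyt", n_cytokines, shift$cytokine)
    # bacteriome: log-normal relative abundances, exchangeable across groups
    bshift <- if (is.null(shift$bacteriome)) 0 else shift$bacteriome
    bm <- matrix(rlnorm(nrow(samples) * n_bacteria), nrow(samples), n_bacteria,
                 dimnames = list(samples$sample_id,
                                 sprintf("otu_%03d", seq_len(n_bacteria))))
    if (bshift != 0) {
      k <- round(shifted_fraction * n_bacteria)
      bm[g1, seq_len(k)] <- bm[g1, seq_len(k)] * exp(bshift)
    }
    bm <- bm / rowSums(bm)
    list(metabolites = met$tbl, cytokines = cyt$tbl,
         bacteria = abund_tibble(bm),
         shifted_features = c(met$shifted, cyt$shifted))
  })
}
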