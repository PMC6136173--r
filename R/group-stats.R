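#' Mann-Whitney U test between two groups
#'
#' Exact enumeration p-value when the combined sample size is at most 12
#' and there are no ties; otherwise the normal approximation with tie and
#' continuity correction.
#'
#' @param x,y Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return One-row tibble: `method`, `statistic` (U of `x`), `p_value`,
#'   group sizes and medians, and whether the exact branch was used.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (length(x) < 1 || length(y) < 1) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 12 && !ties
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = alternative, exact = use_exact,
                correct = TRUE))
  tibble::tibble(method = "mann_whitney",
                 statistic = unname(wt$statistic),
                 p_value = min(1, wt$p.value),
                 n_x = length(x), n_y = length(y),
                 median_x = median(x), median_y = median(y),
                 exact = use_exact)
}

#' Pearson chi-squared test on a 2x2 contingency table
#'
#' Uses the uncorrected Pearson statistic by default (no Yates continuity
#' correction); the corrected variant is available by flag.
#'
#' @param table A 2x2 matrix of non-negative counts, or a length-4 vector
#'   `(a, b, c, d)` filled by row.
#' @param continuity_correction Apply the Yates correction.
#' @return One-row tibble: `method`, `statistic`, `df`, `p_value`.
#' @export
chi_squared_2x2 <- function(table, continuity_correction = FALSE) {
  if (!is.matrix(table)) table <- matrix(table, 2, 2, byrow = TRUE)
  if (any(table < 0) || sum(table) < 1) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("table has a zero margin", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(table, correct = continuity_correction))
  tibble::tibble(method = "chi_squared",
                 statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = ct$p.value)
}

#' Bonferroni correction
#'
#' `p_adj = min(1, m * p)` over the family of `m` p-values.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Adjusted p-values (same order).
#' @export
bonferroni <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(p_values, method = "bonferroni")
}

#' Metastats-style differential-abundance test
#'
#' Two-part procedure per feature: features detected in at least
#' `sparse_min_nonzero` samples overall get an unequal-variance t statistic
#' on their (relative) abundances with a group-label permutation p-value
#' (two-sided on |t|, add-one estimator); sparser features get Fisher's
#' exact test on the 2x2 table of detection counts by group.  Features
#' undetected everywhere are reported as `NA`.
#'
#' @param abundance Wide abundance tibble (relative abundances or counts).
#' @param groups Grouping vector (two levels, each with >= 2 samples), in
#'   sample order.
#' @param n_perm Number of label permutations (default 1000).
#' @param sparse_min_nonzero Minimum number of non-zero samples for the
#'   t-statistic branch.
#' @param seed Integer RNG seed.
#' @return Tibble with one row per feature: `feature_id`, `method`
#'   (`"permutation_t"`, `"fisher"` or `NA`), `statistic`, group means,
#'   `p_value`, `p_fdr` (Benjamini-Hochberg across tested features).
#' @export
metastats_test <- function(abundance, groups, n_perm = 1000,
                           sparse_min_nonzero = 4, seed = 1) {
  m <- abund_matrix(abundance)
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(m))
  lev <- unique(groups)
  if (length(lev) != 2 || any(table(groups) < 2)) {
    stop("need exactly two groups with >= 2 samples each", call. = FALSE)
  }
  g1 <- groups == lev[1]
  n1 <- sum(g1); n2 <- sum(!g1)

  welch_t <- function(sub) {
    m1 <- colSums(sub[seq_len(n1), , drop = FALSE]) / n1
    m2 <- colSums(sub[-seq_len(n1), , drop = FALSE]) / n2
    v1 <- (colSums(sub[seq_len(n1), , drop = FALSE]^2) - n1 * m1^2) /
      (n1 - 1)
    v2 <- (colSums(sub[-seq_len(n1), , drop = FALSE]^2) - n2 * m2^2) /
      (n2 - 1)
    se <- sqrt(v1 / n1 + v2 / n2)
    t <- (m1 - m2) / se
    t[!is.finite(t)] <- 0
    t
  }

  nonzero <- unname(colSums(m > 0))
  kind <- ifelse(nonzero == 0, "none",
                 ifelse(nonzero < sparse_min_nonzero, "fisher",
                        "permutation_t"))
  mean1 <- unname(colMeans(m[g1, , drop = FALSE]))
  mean2 <- unname(colMeans(m[!g1, , drop = FALSE]))

  p <- rep(NA_real_, ncol(m))
  statistic <- rep(NA_real_, ncol(m))

  dense <- which(kind == "permutation_t")
  if (length(dense) > 0) {
    ord <- c(which(g1), which(!g1))
    sub <- m[ord, dense, drop = FALSE]
    t_obs <- welch_t(sub)
    withr::with_seed(seed, {
      exceed <- numeric(length(dense))
      for (b in seq_len(n_perm)) {
        t_b <- welch_t(sub[sample.int(n1 + n2), , drop = FALSE])
        exceed <- exceed + (abs(t_b) >= abs(t_obs))
      }
    })
    statistic[dense] <- unname(t_obs)
    p[dense] <- unname((1 + exceed) / (1 + n_perm))
  }

  sparse <- which(kind == "fisher")
  for (j in sparse) {
    det <- m[, j] > 0
    tab <- matrix(c(sum(det & g1), sum(!det & g1),
                    sum(det & !g1), sum(!det & !g1)), 2, 2)
    p[j] <- fisher.test(tab)$p.value
  }

  out <- tibble::tibble(
    feature_id = colnames(m),
    method = ifelse(kind == "none", NA_character_, kind),
    statistic = statistic,
    mean_1 = mean1, mean_2 = mean2,
    p_value = p
  )
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lev[1])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lev[2])
  out$p_fdr <- NA_real_
  tested <- !is.na(out$p_value)
  out$p_fdr[tested] <- p.adjust(out$p_value[tested], method = "BH")
  out
}
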