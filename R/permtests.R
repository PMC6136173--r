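ord_axes <- function(ordination, n_axes) {
  if (inherits(ordination, "pcoa_result")) {
    coords <- ordination$coordinates
  } else {
    coords <- ordination
  }
  m <- as.matrix(coords[setdiff(names(coords), "sample_id")])
  if (ncol(m) == 0) stop("ordination has no retained axes", call. = FALSE)
  m[, seq_len(min(n_axes, ncol(m))), drop = FALSE]
}

fit_result <- function(method, effect, p_raw, n_perm, direction = NULL) {
  out <- tibble::tibble(method = method, effect = effect, p_raw = p_raw,
                        p_adjusted = NA_real_, n_permutations = n_perm)
  if (!is.null(direction)) out$direction <- list(direction)
  class(out) <- c("fit_result", class(out))
  out
}

#' Bonferroni-adjust a family of permutation fits
#'
#' @param fits A row-bound tibble of fit results (`p_raw` column).
#' @return The same tibble with `p_adjusted` filled in.
#' @export
adjust_fits <- function(fits) {
  fits$p_adjusted <- bonferroni(fits$p_raw)
  fits
}

#' Permutation factor fitting of a grouping to ordination coordinates
#'
#' Measures how much of the spread of the first `n_axes` ordination
#' coordinates is explained by group centroids:
#' `r2 = 1 - SS_within / SS_total`.  Significance is assessed by permuting
#' the group labels; the add-one estimator
#' `p = (1 + #{r2_perm >= r2_obs}) / (1 + n_perm)` never returns 0.
#'
#' @param ordination A `pcoa_result` (or coordinate tibble).
#' @param labels Grouping vector, one per sample; >= 2 groups with >= 2
#'   samples each.
#' @param n_perm Number of label permutations.
#' @param n_axes Number of leading axes used (default 2, matching 2-D
#'   ordination plots).
#' @param seed Integer RNG seed.
#' @return A one-row `fit_result` tibble: `method`, `effect` (r2), `p_raw`,
#'   `p_adjusted` (`NA` until [adjust_fits()]), `n_permutations`.
#' @export
factor_fit <- function(ordination, labels, n_perm = 9999, n_axes = 2,
                       seed = 1) {
  x <- ord_axes(ordination, n_axes)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(x))
  tab <- table(labels)
  if (length(tab) < 2 || any(tab < 2)) {
    stop("need >= 2 groups with >= 2 samples each", call. = FALSE)
  }
  xc <- sweep(x, 2, colMeans(x))
  sst <- sum(xc^2)
  if (sst == 0) {
    return(fit_result("factor_fit", 0, 1, n_perm))
  }
  r2_of <- function(lab) {
    s <- rowsum(x, lab)           # group sums
    n_g <- as.vector(table(lab)[rownames(s)])
    ssb <- sum(rowSums(s^2) / n_g) - sum(colSums(x)^2) / nrow(x)
    ssb / sst
  }
  r2_obs <- r2_of(labels)
  withr::with_seed(seed, {
    r2_perm <- vapply(seq_len(n_perm), function(b) r2_of(sample(labels)),
                      numeric(1))
  })
  p <- (1 + sum(r2_perm >= r2_obs)) / (1 + n_perm)
  fit_result("factor_fit", r2_obs, p, n_perm)
}

#' Permutation vector fitting of a continuous variable to an ordination
#'
#' Regresses the variable on the first `n_axes` coordinates; the effect is
#' the regression r-squared and the direction the unit coefficient vector.
#' Significance by permuting the variable across samples (add-one
#' estimator).
#'
#' @inheritParams factor_fit
#' @param variable Numeric vector, one value per sample; must not be
#'   constant.
#' @return A one-row `fit_result` tibble with a `direction` list-column.
#' @export
vector_fit <- function(ordination, variable, n_perm = 9999, n_axes = 2,
                       seed = 1) {
  x <- ord_axes(ordination, n_axes)
  stopifnot(length(variable) == nrow(x))
  if (sd(variable) == 0) stop("variable is constant", call. = FALSE)
  xc <- sweep(x, 2, colMeans(x))
  q <- qr.Q(qr(xc))
  r2_of <- function(y) {
    yc <- y - mean(y)
    sum(crossprod(q, yc)^2) / sum(yc^2)
  }
  r2_obs <- r2_of(variable)
  b <- qr.coef(qr(xc), variable - mean(variable))
  b[is.na(b)] <- 0
  direction <- unname(b / sqrt(sum(b^2)))
  withr::with_seed(seed, {
    r2_perm <- vapply(seq_len(n_perm), function(i) r2_of(sample(variable)),
                      numeric(1))
  })
  p <- (1 + sum(r2_perm >= r2_obs)) / (1 + n_perm)
  fit_result("vector_fit", r2_obs, p, n_perm, direction = direction)
}

#' Mantel test between two distance matrices
#'
#' Correlates the upper triangles of two distance matrices over the same
#' samples (Spearman by default) and assesses significance by simultaneous
#' row/column permutation of the second matrix; one-sided
#' `p = (1 + #{r_perm >= r_obs}) / (1 + n_perm)`.
#'
#' @param d1,d2 `dist` objects (or symmetric matrices) over the same
#'   samples in the same order; n >= 4.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm Number of permutations.
#' @param seed Integer RNG seed.
#' @return A one-row `fit_result` tibble (`effect` = Mantel's r).
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 9999, seed = 1) {
  method <- match.arg(method)
  m1 <- as.matrix(d1); m2 <- as.matrix(d2)
  n <- nrow(m1)
  if (n < 4) stop("mantel test needs >= 4 samples", call. = FALSE)
  if (!identical(dim(m1), dim(m2))) stop("dimension mismatch", call. = FALSE)
  l1 <- rownames(m1); l2 <- rownames(m2)
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2)) {
    stop("sample ids of the two matrices differ", call. = FALSE)
  }
  v1 <- upper_tri_vec(m1)
  if (method == "spearman") v1 <- rank(v1)
  # under row/column permutation the multiset of pair values is unchanged,
  # so pair ranks can be precomputed once on the full symmetric matrix
  r2full <- m2
  r2full[upper.tri(m2)] <- if (method == "spearman")
    rank(upper_tri_vec(m2)) else upper_tri_vec(m2)
  r2full[lower.tri(r2full)] <- t(r2full)[lower.tri(r2full)]
  ut <- upper.tri(m2)
  r_of <- function(perm) {
    cor(v1, r2full[perm, perm][ut])
  }
  r_obs <- r_of(seq_len(n))
  withr::with_seed(seed, {
    r_perm <- vapply(seq_len(n_perm), function(b) r_of(sample.int(n)),
                     numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_perm)
  fit_result(paste0("mantel_", method), r_obs, p, n_perm)
}
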