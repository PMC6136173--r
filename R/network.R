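#' Centered log-ratio transform of compositional abundances
#'
#' Each row is first closed to proportions (so per-sample scale drops out
#' exactly), a pseudocount is added, and the per-sample log mean is
#' subtracted: `z_ij = ln(p_ij + pc) - mean_j ln(p_ij + pc)`.
#'
#' @param abundance Wide abundance tibble (non-negative).
#' @param pseudocount Positive value added before the log; default is half
#'   the smallest non-zero proportion.
#' @return Wide tibble of CLR values (rows sum to 0) with attribute
#'   `pseudocount`.
#' @export
clr_transform <- function(abundance, pseudocount = NULL) {
  m <- abund_matrix(abundance)
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  rs <- rowSums(m)
  if (any(rs == 0)) stop("all-zero sample row(s)", call. = FALSE)
  m <- m / rs
  if (is.null(pseudocount)) pseudocount <- min(m[m > 0]) / 2
  if (pseudocount <= 0) stop("pseudocount must be > 0", call. = FALSE)
  lm_ <- log(m + pseudocount)
  z <- lm_ - rowMeans(lm_)
  out <- abund_tibble(z)
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Association network by Meinshausen-Buhlmann neighborhood selection
#'
#' Each feature is regressed on all others with an L1 penalty
#' (standardised predictors); an edge joins `i` and `j` when the
#' coefficient of `i` in `j`'s regression is non-zero, symmetrised by OR
#' (default) or AND.  When `lambda` is not given, a 10-value log-spaced
#' grid from `lambda_max = max |X'y|/n` down two decades is fitted and the
#' penalty minimising the extended BIC (gamma = 0.5) summed over the
#' per-feature regressions is selected; the full edge-count path is kept on
#' the result for inspection.
#'
#' @param clr Wide tibble of CLR-transformed abundances (>= 4 samples,
#'   >= 3 features).
#' @param lambda Penalty (>= 0); `NULL` for the grid heuristic.
#' @param symmetrize `"or"` or `"and"`.
#' @param n_lambda Grid size when `lambda` is `NULL`.
#' @param ebic_gamma Extended-BIC density penalty used for the default
#'   penalty choice.
#' @return An `mb_network`: list with `adjacency` (logical features x
#'   features), `lambda`, `lambda_grid`, `edge_counts`, `symmetrize`.
#' @export
mb_network <- function(clr, lambda = NULL, symmetrize = c("or", "and"),
                       n_lambda = 10, ebic_gamma = 0.5) {
  symmetrize <- match.arg(symmetrize)
  x <- abund_matrix(clr)
  n <- nrow(x); p <- ncol(x)
  if (n < 4) stop("need >= 4 samples", call. = FALSE)
  if (p < 3) stop("need >= 3 features", call. = FALSE)
  if (!is.null(lambda) && lambda < 0) stop("lambda must be >= 0",
                                           call. = FALSE)
  xs <- scale(x)
  xs[is.na(xs)] <- 0

  lambda_max <- max(abs(crossprod(xs)[upper.tri(diag(p))])) / n
  grid <- if (is.null(lambda)) {
    exp(seq(log(lambda_max), log(lambda_max / 100), length.out = n_lambda))
  } else {
    lambda
  }

  adj_at <- function(coefs, lam_idx) {
    a <- matrix(FALSE, p, p, dimnames = list(colnames(x), colnames(x)))
    for (j in seq_len(p)) {
      nz <- coefs[[j]][, lam_idx] != 0
      a[setdiff(seq_len(p), j)[nz], j] <- TRUE
    }
    if (symmetrize == "or") a | t(a) else a & t(a)
  }

  # one glmnet path per feature over the shared grid
  coefs <- lapply(seq_len(p), function(j) {
    fit <- glmnet::glmnet(xs[, -j, drop = FALSE], xs[, j], lambda = grid,
                          standardize = FALSE, intercept = FALSE)
    as.matrix(fit$beta)
  })
  n_grid <- length(grid)
  adjs <- lapply(seq_len(n_grid), function(k) adj_at(coefs, k))
  edge_counts <- vapply(adjs, function(a) sum(a) / 2, numeric(1))

  pick <- if (n_grid == 1) 1 else {
    # extended BIC summed over the per-feature regressions
    ebic <- vapply(seq_len(n_grid), function(k) {
      sum(vapply(seq_len(p), function(j) {
        b <- coefs[[j]][, k]
        rss <- sum((xs[, j] - xs[, -j, drop = FALSE] %*% b)^2)
        df <- sum(b != 0)
        n * log(rss / n) + df * (log(n) + 2 * ebic_gamma * log(p - 1))
      }, numeric(1)))
    }, numeric(1))
    which.min(ebic)
  }
  structure(list(adjacency = adjs[[pick]],
                 lambda = grid[pick],
                 lambda_grid = grid,
                 edge_counts = edge_counts,
                 symmetrize = symmetrize),
            class = "mb_network")
}

#' @export
#' @method print mb_network
print.mb_network <- function(x, ...) {
  cat("<mb_network> ", ncol(x$adjacency), " features, ",
      sum(x$adjacency) / 2, " edges at lambda = ",
      signif(x$lambda, 3), " (", x$symmetrize, " symmetrisation)\n",
      sep = "")
  invisible(x)
}

#' @export
tidy.mb_network <- function(x, ...) {
  a <- x$adjacency
  idx <- which(a & upper.tri(a), arr.ind = TRUE)
  tibble::tibble(from = rownames(a)[idx[, 1]],
                 to = colnames(a)[idx[, 2]])
}

#' @export
glance.mb_network <- function(x, ...) {
  tibble::tibble(n_features = ncol(x$adjacency),
                 n_edges = sum(x$adjacency) / 2,
                 lambda = x$lambda,
                 symmetrize = x$symmetrize)
}

#' Edge count along the penalty grid
#'
#' @param object An `mb_network`.
#' @param ... Unused.
#' @return A ggplot of edge count against penalty.
#' @export
autoplot.mb_network <- function(object, ...) {
  df <- tibble::tibble(lambda = object$lambda_grid,
                       edges = object$edge_counts)
  ggplot2::ggplot(df, ggplot2::aes(.data$lambda, .data$edges)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$lambda, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "penalty", y = "edges") +
    ggplot2::theme_minimal()
}

#' Connected-component clusters of an association network
#'
#' Components with at least two features are numbered clusters; isolated
#' features are labelled noise.
#'
#' @param network An `mb_network` or a logical adjacency matrix.
#' @return Tibble with `feature_id`, `cluster` (`NA` for noise),
#'   `cluster_size`; attributes `n_clusters` and `cluster_sizes`.
#' @export
detect_clusters <- function(network) {
  a <- if (inherits(network, "mb_network")) network$adjacency else network
  g <- igraph::graph_from_adjacency_matrix(a * 1, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  sizes <- comp$csize[comp$membership]
  cluster <- ifelse(sizes >= 2, comp$membership, NA_integer_)
  out <- tibble::tibble(feature_id = colnames(a),
                        cluster = cluster,
                        cluster_size = as.integer(sizes))
  keep <- comp$csize >= 2
  attr(out, "n_clusters") <- sum(keep)
  attr(out, "cluster_sizes") <- comp$csize[keep]
  out
}
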