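#' Principal coordinates analysis (classical metric MDS)
#'
#' Double-centers `-0.5 * D^2` and eigendecomposes it; coordinates are
#' eigenvectors scaled by the square root of their (positive) eigenvalues.
#' Negative eigenvalues are reported but their axes dropped.  Axis signs
#' are fixed so each axis's largest-magnitude loading is positive, making
#' results reproducible across platforms.
#'
#' @param d A `dist` object over at least 3 samples.
#' @param tol Eigenvalues below `tol * max(eigenvalue)` are treated as zero.
#' @return A `pcoa_result`: list with `coordinates` (tibble `sample_id`,
#'   `Axis1`, ...), `eigenvalues` (all, descending), and
#'   `proportion_explained` (relative to the positive-eigenvalue total).
#' @export
pcoa <- function(d, tol = 1e-8) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) stop("pcoa needs a dist over >= 3 samples",
                                call. = FALSE)
  ids <- attr(d, "Labels") %||% as.character(seq_len(n))
  fit <- suppressWarnings(cmdscale(d, k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > tol * max(abs(eig), 1e-300))
  pts <- fit$points
  if (length(pos) == 0) {
    coords <- tibble::tibble(sample_id = ids)
  } else {
    pts <- pts[, seq_along(pos), drop = FALSE]
    # sign convention: largest |loading| positive on each axis
    for (j in seq_len(ncol(pts))) {
      i <- which.max(abs(pts[, j]))
      if (pts[i, j] < 0) pts[, j] <- -pts[, j]
    }
    colnames(pts) <- paste0("Axis", seq_len(ncol(pts)))
    coords <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                               tibble::as_tibble(pts))
  }
  structure(list(
    coordinates = coords,
    eigenvalues = eig,
    proportion_explained = if (length(pos)) eig[pos] / sum(eig[pos])
                           else numeric()
  ), class = "pcoa_result")
}

#' @export
#' @method print pcoa_result
print.pcoa_result <- function(x, ...) {
  k <- length(x$proportion_explained)
  cat("<pcoa_result> ", nrow(x$coordinates), " samples, ", k,
      " positive axes", sep = "")
  if (k >= 2) {
    cat(sprintf(" (Axis1 %.1f%%, Axis2 %.1f%%)",
                100 * x$proportion_explained[1],
                100 * x$proportion_explained[2]))
  }
  cat("\n")
  invisible(x)
}

#' @export
tidy.pcoa_result <- function(x, ...) x$coordinates

#' @export
glance.pcoa_result <- function(x, ...) {
  tibble::tibble(
    n_samples = nrow(x$coordinates),
    n_positive_axes = length(x$proportion_explained),
    prop_axis1 = if (length(x$proportion_explained) >= 1)
      x$proportion_explained[1] else NA_real_,
    prop_axis2 = if (length(x$proportion_explained) >= 2)
      x$proportion_explained[2] else NA_real_,
    sum_negative_eig = sum(pmin(x$eigenvalues, 0))
  )
}

#' Plot a PCoA ordination
#'
#' @param object A `pcoa_result`.
#' @param labels Optional grouping vector (in sample order) mapped to colour.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pcoa_result <- function(object, labels = NULL, ...) {
  df <- object$coordinates
  if (ncol(df) < 3) stop("need at least two retained axes to plot",
                         call. = FALSE)
  if (!is.null(labels)) df$group <- labels
  pe <- 100 * object$proportion_explained
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$Axis1, .data$Axis2)) +
    ggplot2::geom_point(
      if (is.null(labels)) NULL
      else ggplot2::aes(colour = .data$group)) +
    ggplot2::labs(x = sprintf("PCo1 (%.1f%%)", pe[1]),
                  y = sprintf("PCo2 (%.1f%%)", pe[2])) +
    ggplot2::theme_minimal()
  if (!is.null(labels)) {
    p <- p + ggplot2::stat_ellipse(ggplot2::aes(colour = .data$group))
  }
  p
}
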