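#' Alpha diversity per sample: richness, Shannon's H, Pielou's J
#'
#' Shannon entropy is computed in natural log (nats) so that Pielou's
#' evenness is `J = H / ln(S)`; `J` is defined as 0 for `S <= 1`.
#'
#' @param abundance Wide abundance tibble (non-negative values; rows are
#'   normalised to proportions internally).
#' @return Tibble with `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(abundance) {
  m <- abund_matrix(abundance)
  if (any(m < 0)) stop("abundances must be non-negative", call. = FALSE)
  if (any(rowSums(m) == 0)) {
    warning("all-zero sample(s): diversity reported as 0", call. = FALSE)
  }
  s <- vegan::specnumber(m)
  h <- vegan::diversity(m, index = "shannon")
  j <- ifelse(s > 1, h / log(s), 0)
  tibble::tibble(sample_id = rownames(m), richness = as.integer(s),
                 shannon = as.numeric(h), pielou = as.numeric(j))
}

#' Bray-Curtis dissimilarity between samples
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)`.  A pair of all-zero rows
#' has distance 0 (with a warning).  Negative values are an error; for
#' autoscaled intensity data apply [min_shift_nonneg()] first.
#'
#' @param abundance Wide abundance tibble.
#' @param exclude Optional character vector of sample ids to drop before
#'   computing distances (explicit outlier-exclusion list).
#' @return A `dist` object labelled by sample id.
#' @export
bray_curtis <- function(abundance, exclude = NULL) {
  m <- abund_matrix(abundance)
  if (!is.null(exclude)) m <- m[!rownames(m) %in% exclude, , drop = FALSE]
  if (any(m < 0)) {
    stop("Bray-Curtis requires non-negative values; ",
         "min-shift intensity data first (see min_shift_nonneg())",
         call. = FALSE)
  }
  d <- suppressWarnings(vegan::vegdist(m, method = "bray"))
  if (anyNA(d)) {
    warning("pair(s) of all-zero samples: distance set to 0", call. = FALSE)
    d[is.na(d)] <- 0
  }
  d
}

#' Euclidean distance between samples
#'
#' @param x Wide tibble of (typically autoscaled) sample profiles.
#' @param exclude Optional sample ids to drop.
#' @return A `dist` object.
#' @export
euclidean_dist <- function(x, exclude = NULL) {
  m <- abund_matrix(x)
  if (!is.null(exclude)) m <- m[!rownames(m) %in% exclude, , drop = FALSE]
  stats::dist(m)
}

#' Shift each feature to be non-negative
#'
#' Subtracts the per-feature minimum where it is negative, so that
#' Bray-Curtis dissimilarity is defined for autoscaled intensity data.
#'
#' @param x Wide tibble.
#' @return Wide tibble with all values >= 0.
#' @export
min_shift_nonneg <- function(x) {
  m <- abund_matrix(x)
  mins <- apply(m, 2, min)
  m <- sweep(m, 2, pmin(mins, 0))
  abund_tibble(m)
}

#' Autoscale features (zero mean, unit standard deviation)
#'
#' Constant features cannot be scaled and are dropped with a warning.
#'
#' @param x Wide tibble of intensities.
#' @return Autoscaled wide tibble.
#' @export
autoscale <- function(x) {
  m <- abund_matrix(x)
  sds <- apply(m, 2, sd)
  if (any(sds == 0)) {
    warning("dropping constant feature(s): ",
            paste(head(colnames(m)[sds == 0], 5), collapse = ", "),
            call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(m)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  abund_tibble(z)
}

#' Filter features by detection prevalence
#'
#' Keeps features detected (value different from `sentinel` and not `NA`)
#' in at least `min_fraction` of the samples; the boundary is inclusive.
#'
#' @param x Wide tibble.
#' @param min_fraction Minimum detection fraction, default 0.5.
#' @param sentinel Value marking a non-detect, default 0.
#' @return Filtered wide tibble.
#' @export
presence_filter <- function(x, min_fraction = 0.5, sentinel = 0) {
  m <- abund_matrix(x)
  detected <- !is.na(m) & m != sentinel
  keep <- colMeans(detected) >= min_fraction
  abund_tibble(m[, keep, drop = FALSE])
}
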