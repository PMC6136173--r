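#' Per-position read depth for one genome in one sample
#'
#' Depth at position `p` is the number of qualifying hits (identity at or
#' above the threshold; best hits only if a `best` column is present) whose
#' half-open interval `[start, end)` contains `p`.
#'
#' @param hits Hit tibble for a single genome/sample.
#' @param genome_length Genome length (> 0).
#' @param min_identity_pct Identity threshold, inclusive.
#' @return Integer depth vector of length `genome_length` with attribute
#'   `n_qualifying_reads`.
#' @export
coverage_track <- function(hits, genome_length, min_identity_pct = 95) {
  stopifnot(genome_length > 0)
  h <- hits[hits$percent_identity >= min_identity_pct, , drop = FALSE]
  if ("best" %in% names(h)) h <- h[h$best, , drop = FALSE]
  if (nrow(h) > 0 && any(h$end > genome_length | h$start < 0)) {
    stop("hit coordinates outside [0, genome_length)", call. = FALSE)
  }
  depth <- if (nrow(h) == 0) {
    integer(genome_length)
  } else {
    as.integer(IRanges::coverage(IRanges::IRanges(start = h$start + 1L,
                                                  end = h$end),
                                 width = genome_length))
  }
  attr(depth, "n_qualifying_reads") <- nrow(h)
  depth
}

#' Call presence of a viral population from its coverage track
#'
#' A population is present when at least `min_run_bp` consecutive genome
#' positions are covered by qualifying reads; disjoint covered stretches do
#' not add up.
#'
#' @param track Integer depth vector from [coverage_track()].
#' @param min_run_bp Minimum consecutive covered stretch (inclusive).
#' @return One-row tibble: `present`, `longest_run_bp`,
#'   `n_qualifying_reads`.
#' @export
call_presence <- function(track, min_run_bp = 200) {
  r <- rle(track > 0)
  longest <- if (any(r$values)) max(r$lengths[r$values]) else 0L
  tibble::tibble(
    present = longest >= min_run_bp,
    longest_run_bp = as.integer(longest),
    n_qualifying_reads = attr(track, "n_qualifying_reads") %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Median-coverage abundance of one population in one sample
#'
#' The median read depth over all genome positions (zeros included), scaled
#' per million decontaminated reads.  Populations failing the presence rule
#' get abundance 0.
#'
#' @param track Integer depth vector.
#' @param decontaminated_read_count Sample's read count after trimming,
#'   de-duplication and host removal (> 0).
#' @param min_run_bp Presence-rule run length; set `NULL` to skip the
#'   presence gate.
#' @param zeros Include zero-depth positions in the median (default); with
#'   `zeros = FALSE` the median is over covered positions only.
#' @return Median depth per million decontaminated reads.
#' @export
median_coverage_abundance <- function(track, decontaminated_read_count,
                                      min_run_bp = 200, zeros = TRUE) {
  if (decontaminated_read_count <= 0) {
    stop("decontaminated_read_count must be > 0", call. = FALSE)
  }
  if (!is.null(min_run_bp) && !call_presence(track, min_run_bp)$present) {
    return(0)
  }
  x <- if (zeros) track else track[track > 0]
  if (length(x) == 0) return(0)
  median(x) / (decontaminated_read_count / 1e6)
}

#' Quantify all populations of a sample from its viral hits
#'
#' @param hits Hit tibble from [map_reads()] or [read_sam()] for one sample.
#' @param reference Reference tibble (`genome_id`, `length`).
#' @param decontaminated_read_count Decontaminated read number (> 0).
#' @param min_identity_pct,min_run_bp,zeros Quantification thresholds.
#' @return Tibble with one row per reference genome: `genome_id`,
#'   `present`, `longest_run_bp`, `n_reads`, `abundance`
#'   (median coverage per million decontaminated reads).
#' @export
quantify_sample <- function(hits, reference, decontaminated_read_count,
                            min_identity_pct = 95, min_run_bp = 200,
                            zeros = TRUE) {
  if ("best" %in% names(hits)) hits <- hits[hits$best, , drop = FALSE]
  hits <- hits[hits$percent_identity >= min_identity_pct, , drop = FALSE]
  by_genome <- split(hits, hits$genome_id)
  purrr::map(reference$genome_id, function(g) {
    h <- by_genome[[g]]
    len <- reference$length[match(g, reference$genome_id)]
    if (is.null(h) || nrow(h) == 0) {
      return(tibble::tibble(genome_id = g, present = FALSE,
                            longest_run_bp = 0L, n_reads = 0L,
                            abundance = 0))
    }
    track <- coverage_track(h, len, min_identity_pct)
    pc <- call_presence(track, min_run_bp)
    tibble::tibble(
      genome_id = g, present = pc$present,
      longest_run_bp = pc$longest_run_bp, n_reads = nrow(h),
      abundance = median_coverage_abundance(track, decontaminated_read_count,
                                            min_run_bp, zeros)
    )
  }) %>% purrr::list_rbind()
}

#' Assemble per-sample quantifications into an abundance table
#'
#' Features absent in every sample are dropped; in `"relative"` mode each
#' sample's row is divided by its sum (all-zero rows are kept and reported).
#'
#' @param quantifications Long tibble with `sample_id`, `genome_id` (or
#'   `feature_id`) and `abundance` columns, e.g. row-bound outputs of
#'   [quantify_sample()].
#' @param normalize `"relative"` (default) or `"median_cov_per_million"`.
#' @return Wide abundance tibble (`sample_id` + one column per retained
#'   feature) with attribute `value_kind`.
#' @export
build_abundance_matrix <- function(quantifications,
                                   normalize = c("relative",
                                                 "median_cov_per_million")) {
  normalize <- match.arg(normalize)
  feat_col <- if ("feature_id" %in% names(quantifications)) "feature_id"
              else "genome_id"
  if (any(quantifications$abundance < 0)) {
    stop("abundance values must be non-negative", call. = FALSE)
  }
  wide <- quantifications %>%
    dplyr::select("sample_id", dplyr::all_of(feat_col), "abundance") %>%
    tidyr::pivot_wider(names_from = dplyr::all_of(feat_col),
                       values_from = "abundance", values_fill = 0)
  m <- abund_matrix(wide)
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (normalize == "relative") {
    rs <- rowSums(m)
    empty <- rs == 0
    if (any(empty)) {
      message("sample(s) with no detected populations kept as all-zero: ",
              paste(rownames(m)[empty], collapse = ", "))
      rs[empty] <- 1
    }
    m <- m / rs
  }
  out <- abund_tibble(m)
  attr(out, "value_kind") <- normalize
  out
}

#' Aggregate population abundances by host taxonomy
#'
#' Sums each sample's abundances within the host genus or phylum of the
#' phage's bacterial host; eukaryotic viruses are grouped as their own
#' class.  Row totals are conserved exactly.
#'
#' @param abundance Wide abundance tibble (features = genome ids).
#' @param reference Reference tibble with taxonomy columns.
#' @param rank `"genus"` or `"phylum"`.
#' @return Wide abundance tibble with host taxa as features.
#' @export
aggregate_by_host <- function(abundance, reference,
                              rank = c("genus", "phylum")) {
  rank <- match.arg(rank)
  m <- abund_matrix(abundance)
  tax_col <- paste0("host_", rank)
  idx <- match(colnames(m), reference$genome_id)
  if (any(is.na(idx))) {
    stop("features missing from reference: ",
         paste(head(colnames(m)[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  }
  taxon <- reference[[tax_col]][idx]
  taxon[reference$virus_type[idx] == "eukaryotic"] <- "Eukaryotic viruses"
  if (any(is.na(taxon))) {
    stop("features without ", rank, " annotation: ",
         paste(head(colnames(m)[is.na(taxon)], 5), collapse = ", "),
         call. = FALSE)
  }
  agg <- t(rowsum(t(m), taxon))
  out <- abund_tibble(agg)
  attr(out, "value_kind") <- attr(abundance, "value_kind")
  out
}
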