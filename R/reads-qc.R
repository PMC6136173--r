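#' Quality-trim reads from both ends
#'
#' Bases are removed from each end of a read while their Phred quality is
#' below `phred_min`; trimmed reads shorter than `min_length` are dropped.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (Phred+33).
#' @param phred_min Minimum terminal base quality (>= 0).
#' @param min_length Minimum retained read length.
#' @return Tibble of retained (possibly shortened) reads, with attribute
#'   `n_dropped` giving the number of reads removed.
#' @export
quality_trim <- function(reads, phred_min = 10, min_length = 50) {
  stopifnot(phred_min >= 0)
  bad <- nchar(reads$sequence) != nchar(reads$quality)
  if (any(bad)) {
    stop("malformed read record(s) at index ",
         paste(head(which(bad), 5), collapse = ", "),
         ": sequence and quality lengths differ", call. = FALSE)
  }
  b <- cpp_trim_bounds(reads$quality, 33L + as.integer(phred_min))
  out <- reads
  out$sequence <- substr(out$sequence, b[, 1], b[, 2])
  out$quality <- substr(out$quality, b[, 1], b[, 2])
  keep <- b[, 1] > 0 & (b[, 2] - b[, 1] + 1) >= min_length
  res <- out[keep, ]
  attr(res, "n_dropped") <- sum(!keep)
  res
}

#' Remove exact-sequence duplicate reads
#'
#' Keeps the first occurrence of each distinct sequence, preserving read
#' order otherwise.
#'
#' @param reads Read tibble.
#' @return De-duplicated tibble with attribute `n_removed`.
#' @export
deduplicate <- function(reads) {
  keep <- !duplicated(reads$sequence)
  res <- reads[keep, ]
  attr(res, "n_removed") <- sum(!keep)
  res
}
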