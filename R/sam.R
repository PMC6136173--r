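#' Read alignments from a SAM file as identity-annotated hits
#'
#' Percent identity is computed from the NM tag as
#' `100 * (aligned_length - NM) / aligned_length`, where `aligned_length`
#' counts the aligned (non-clipped) bases of the record (CIGAR operations
#' M/=/X/I/D).  Records without an NM tag fall back to CIGAR `=`/`X`
#' operations; if neither is available the record is an error.  Unmapped
#' records are always skipped; secondary/supplementary records are skipped
#' by default.
#'
#' SAM's 1-based coordinates are converted to the package's 0-based
#' half-open convention.
#'
#' @param path Path to a SAM (or BAM) file with `@SQ` header lines.
#' @param reference_lengths Optional named vector of genome lengths used to
#'   validate hit coordinates.
#' @param include_secondary Keep secondary/supplementary alignments.
#' @return Hit tibble as returned by [map_reads()].
#' @export
read_sam <- function(path, reference_lengths = NULL,
                     include_secondary = FALSE) {
  bam <- if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    path
  } else {
    Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                     indexDestination = FALSE)
  }
  p <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar"), tag = "NM")
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]

  flag <- rec$flag
  keep <- !bitwAnd(flag, 4L)
  if (!include_secondary) {
    keep <- keep & !bitwAnd(flag, 256L) & !bitwAnd(flag, 2048L)
  }
  qname <- rec$qname[keep]
  cigar <- rec$cigar[keep]
  nm_all <- rec$tag$NM
  if (is.null(nm_all)) nm_all <- rep(NA_real_, length(rec$qname))
  nm <- nm_all[keep]
  pos <- rec$pos[keep]
  rname <- as.character(rec$rname)[keep]
  strand <- ifelse(bitwAnd(flag[keep], 16L), "-", "+")
  if (length(qname) == 0) {
    return(flag_best_hits(tibble::tibble(
      read_id = character(), genome_id = character(), start = integer(),
      end = integer(), strand = character(), matches = integer(),
      aligned_length = integer(), percent_identity = numeric())))
  }

  ops <- lapply(regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar)),
                function(x) {
                  data.frame(len = as.integer(sub("[A-Z=]", "", x)),
                             op = sub("[0-9]+", "", x))
                })
  sum_ops <- function(o, which) sum(o$len[o$op %in% which])
  alen <- vapply(ops, sum_ops, numeric(1), which = c("M", "=", "X", "I", "D"))
  ref_span <- vapply(ops, sum_ops, numeric(1), which = c("M", "=", "X", "D", "N"))

  # NM fallback from =/X CIGAR operators
  no_nm <- is.na(nm)
  if (any(no_nm)) {
    has_eq <- vapply(ops[no_nm], function(o) any(o$op %in% c("=", "X")),
                     logical(1))
    if (any(!has_eq)) {
      stop("records without NM tag or =/X CIGAR: ",
           paste(head(qname[no_nm][!has_eq], 5), collapse = ", "),
           call. = FALSE)
    }
    nm[no_nm] <- vapply(ops[no_nm], sum_ops, numeric(1),
                        which = c("X", "I", "D"))
  }

  out <- tibble::tibble(
    read_id = qname,
    genome_id = rname,
    start = pos - 1L,
    end = as.integer(pos - 1L + ref_span),
    strand = strand,
    matches = as.integer(alen - nm),
    aligned_length = as.integer(alen),
    percent_identity = 100 * (alen - nm) / alen
  )
  if (!is.null(reference_lengths)) {
    too_far <- out$end > reference_lengths[out$genome_id]
    if (any(too_far, na.rm = TRUE)) {
      stop("alignment(s) extend past the reference end: ",
           paste(head(out$read_id[too_far], 5), collapse = ", "),
           call. = FALSE)
    }
  }
  flag_best_hits(out)
}
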