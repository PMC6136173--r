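# Internal helpers shared across modules.

# Wide abundance tibble (sample_id + numeric feature columns) -> matrix with
# sample_id rownames.  The wide tibble is the package's user-facing form of
# the samples x features table; matrices are used internally.
abund_matrix <- function(tbl, id_col = "sample_id") {
  stopifnot(is.data.frame(tbl))
  if (!id_col %in% names(tbl)) {
    stop("abundance table must have a '", id_col, "' column", call. = FALSE)
  }
  m <- as.matrix(tbl[setdiff(names(tbl), id_col)])
  if (!is.numeric(m)) stop("feature columns must be numeric", call. = FALSE)
  rownames(m) <- as.character(tbl[[id_col]])
  m
}

abund_tibble <- function(m, id_col = "sample_id") {
  tibble::as_tibble(m, rownames = id_col)
}

# Seeds threaded through the package stay below 2^31.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(i)) %% .Machine$integer.max)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(name, " must be a single value in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

upper_tri_vec <- function(m) m[upper.tri(m)]
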