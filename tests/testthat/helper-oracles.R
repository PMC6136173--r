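# Independent oracles and small fixture builders used across tests.

# longest run of covered positions, by explicit scan
brute_longest_run <- function(depth) {
  best <- 0L; cur <- 0L
  for (d in depth) {
    if (d > 0) {
      cur <- cur + 1L
      if (cur > best) best <- cur
    } else {
      cur <- 0L
    }
  }
  best
}

# exact lasso by coordinate descent: minimise 1/(2n)||y - Xb||^2 + lambda|b|_1
# (no intercept; X as given)
exact_lasso_cd <- function(x, y, lambda, tol = 1e-10, max_iter = 10000) {
  n <- nrow(x); p <- ncol(x)
  b <- rep(0, p)
  xtx <- colSums(x^2) / n
  for (it in seq_len(max_iter)) {
    b_old <- b
    for (j in seq_len(p)) {
      r <- y - x[, -j, drop = FALSE] %*% b[-j]
      rho <- sum(x[, j] * r) / n
      b[j] <- sign(rho) * max(0, abs(rho) - lambda) / xtx[j]
    }
    if (max(abs(b - b_old)) < tol) break
  }
  b
}

# classical MDS by explicit Gower double-centering
hand_pcoa <- function(d_mat) {
  n <- nrow(d_mat)
  a <- -0.5 * d_mat^2
  j <- diag(n) - matrix(1 / n, n, n)
  b <- j %*% a %*% j
  e <- eigen(b, symmetric = TRUE)
  keep <- e$values > 1e-9 * max(abs(e$values))
  pts <- e$vectors[, keep, drop = FALSE] %*%
    diag(sqrt(e$values[keep]), sum(keep))
  list(points = pts, eig = e$values)
}

# substitute exactly n_sub bases of a sequence at given positions
substitute_bases <- function(seq, positions) {
  s <- strsplit(seq, "")[[1]]
  for (p in positions) {
    s[p] <- setdiff(c("A", "C", "G", "T"), s[p])[1]
  }
  paste(s, collapse = "")
}

make_reads <- function(sequences, quality_char = "F",
                       ids = sprintf("r%03d", seq_along(sequences))) {
  tibble::tibble(read_id = ids, sequence = sequences,
                 quality = strrep(quality_char, nchar(sequences)))
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

small_reference <- function(n = 20, seed = 11, len = c(1000, 2000)) {
  generate_reference_db(n, len, seed = seed)
}

# hit tibble builder for quantification tests
make_hits <- function(start, end, identity = 100,
                      genome_id = "g1",
                      read_id = sprintf("r%03d", seq_along(start))) {
  tibble::tibble(read_id = read_id, genome_id = genome_id,
                 start = start, end = end, strand = "+",
                 matches = end - start, aligned_length = end - start,
                 percent_identity = identity, best = TRUE)
}
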