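#' UPGMA (average-linkage) hierarchical clustering
#'
#' Labels are sorted lexicographically before clustering so that exact ties
#' in merge heights resolve deterministically and the topology does not
#' depend on input order.  Returned as an `ape` phylogeny; for two leaves
#' at distance `d` each branch has length `d/2`.
#'
#' @param d A `dist` object (or symmetric matrix) with labels.
#' @return An object of class `phylo`.
#' @export
upgma <- function(d) {
  m <- as.matrix(d)
  if (is.null(rownames(m))) {
    rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  }
  ord <- order(rownames(m))
  m <- m[ord, ord]
  hc <- hclust(as.dist(m), method = "average")
  ape::as.phylo(hc)
}

#' Write a tree to a Newick file
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
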