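#' Neighbor-joining tree from pairwise identities
#'
#' Builds a neighbor-joining tree on the distance
#' `d = 1 - identity / 100`, with identity from [pairwise_identity()].
#' Leaves are processed in lexicographic id order so that tie-breaking is
#' deterministic.
#'
#' @param records A protein record table with at least 3 rows.
#' @param as_phylo Return the `ape::phylo` object instead of a newick
#'   string.
#' @return A newick string (default) or a `phylo` object.
#' @export
nj_tree <- function(records, as_phylo = FALSE) {
  if (nrow(records) < 3)
    stop("neighbor-joining requires at least 3 sequences")
  records <- records[order(records$id), , drop = FALSE]
  n <- nrow(records)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    d[i, j] <- d[j, i] <-
      1 - pairwise_identity(records$sequence[i], records$sequence[j]) / 100
  }
  tr <- ape::nj(as.dist(d))
  # numerical noise can produce tiny negative branch lengths
  tr$edge.length[abs(tr$edge.length) < 1e-12] <- 0
  if (as_phylo) tr else ape::write.tree(tr)
}
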