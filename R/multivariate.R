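#' Principal component analysis of sample profiles
#'
#' Singular-value decomposition of the column-scaled matrix (samples in
#' rows). Default scaling is centring plus unit variance; `"center"`
#' centres only. Component signs are fixed by making each loading
#' vector's largest-magnitude element positive. Constant (zero-variance)
#' variables are dropped with a warning under unit-variance scaling.
#'
#' @param mat Samples x variables numeric matrix (e.g. accessions x
#'   peptides, log10 areas), no missing values.
#' @param scaling `"uv"` (unit variance, default) or `"center"`.
#' @return List with `scores` (samples x components), `loadings`
#'   (variables x components), `var_percent` (summing to 100).
#' @export
pca_profiles <- function(mat, scaling = c("uv", "center")) {
  scaling <- match.arg(scaling)
  if (nrow(mat) < 2) stop("PCA needs at least 2 samples")
  if (anyNA(mat)) stop("missing values; apply impute_matrix() first")
  v <- apply(mat, 2, sd)
  if (scaling == "uv" && any(v == 0)) {
    warning("dropping ", sum(v == 0), " zero-variance variables")
    mat <- mat[, v > 0, drop = FALSE]
  }
  x <- scale(mat, center = TRUE, scale = scaling == "uv")
  s <- svd(x)
  k <- sum(s$d > max(s$d) * 1e-12)
  scores <- s$u[, seq_len(k), drop = FALSE] %*%
    diag(s$d[seq_len(k)], k, k)
  loadings <- s$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- rownames(mat)
  rownames(loadings) <- colnames(mat)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  var_percent <- 100 * s$d[seq_len(k)]^2 / sum(s$d^2)
  list(scores = scores, loadings = loadings, var_percent = var_percent)
}

#' Hierarchical clustering on one-minus-Pearson distance
#'
#' Distance `d(a, b) = 1 - cor(a, b)` between sample profiles (range
#' `[0, 2]`), average linkage. Zero-variance samples are an error, named
#' in the message. `stats::hclust` breaks ties by input order, so leaf
#' order is deterministic.
#'
#' @param mat Samples x variables numeric matrix.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return List with `hclust` (the tree), `order` (leaf labels in
#'   dendrogram order) and `newick` (the tree in newick form).
#' @export
hca_profiles <- function(mat, linkage = "average") {
  if (nrow(mat) < 2) stop("HCA needs at least 2 samples")
  v <- apply(mat, 1, sd)
  if (any(v == 0))
    stop("zero-variance samples: ",
         paste(rownames(mat)[v == 0], collapse = ", "))
  d <- as.dist(1 - cor(t(mat)))
  hc <- hclust(d, method = linkage)
  ph <- ape::as.phylo(hc)
  list(hclust = hc, order = hc$labels[hc$order],
       newick = ape::write.tree(ph))
}
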