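#' Sample-to-sample distance matrix over the most variable genes
#'
#' Euclidean distances between samples computed on the `n_top_genes` genes
#' with the highest variance across samples, the standard construction
#' behind sample MDS and clustering views.
#'
#' @param lcpm gene x sample log2-CPM matrix.
#' @param n_top_genes number of most-variable genes to use (>= 2); if more
#'   than available, all genes are used with a warning.
#' @return symmetric sample x sample matrix with zero diagonal.
#' @export
sample_distances <- function(lcpm, n_top_genes = 500) {
  lcpm <- as.matrix(lcpm)
  if (n_top_genes < 2) stop("sample_distances: n_top_genes must be >= 2")
  if (n_top_genes > nrow(lcpm)) {
    warning("sample_distances: fewer genes than requested; using all ",
            nrow(lcpm))
    n_top_genes <- nrow(lcpm)
  }
  v <- apply(lcpm, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(n_top_genes)]
  d <- as.matrix(stats::dist(t(lcpm[top, , drop = FALSE]), method = "euclidean"))
  dimnames(d) <- list(colnames(lcpm), colnames(lcpm))
  d
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, eigendecomposes, and returns
#' the top-k coordinates scaled by the square roots of the eigenvalues. Axis
#' signs follow a deterministic convention: on each axis the sample with the
#' largest absolute coordinate is positive.
#'
#' @param d symmetric distance matrix.
#' @param k number of dimensions (`k < nrow(d)`).
#' @return list with `points` (sample x k matrix) and `eigenvalues`.
#' @export
classical_mds <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k >= n) stop("classical_mds: k must be smaller than the sample count")
  if (max(abs(d - t(d))) > 1e-8) stop("classical_mds: matrix not symmetric")
  D2 <- d^2
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% D2 %*% J
  B <- (B + t(B)) / 2
  eg <- eigen(B, symmetric = TRUE)
  vals <- eg$values[seq_len(k)]
  pts <- eg$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(vals, 0)), k, k)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pts[, j]))
    if (pts[i_max, j] < 0) pts[, j] <- -pts[, j]
  }
  rownames(pts) <- rownames(d)
  colnames(pts) <- paste0("dim", seq_len(k))
  list(points = pts, eigenvalues = eg$values)
}

#' Agglomerative hierarchical clustering of samples
#'
#' Average- or complete-linkage agglomeration on a sample distance matrix,
#' with deterministic tie-breaking by the lowest pair index. Merge heights
#' are non-decreasing for both linkages.
#'
#' @param d symmetric sample distance matrix.
#' @param linkage `"average"` or `"complete"`.
#' @return an object of class `hclust` (see [stats::hclust()]); convert to a
#'   Newick string with [cluster_newick()].
#' @export
hierarchical_clustering <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("hierarchical_clustering: need >= 2 samples")
  stats::hclust(stats::as.dist(d), method = linkage)
}

#' Newick string for a sample dendrogram
#'
#' @param hc an `hclust` object from [hierarchical_clustering()].
#' @return single Newick-format character string (with branch lengths).
#' @export
cluster_newick <- function(hc) {
  ape::write.tree(ape::as.phylo(hc))
}

#' Row-relative expression scaling
#'
#' Divides each gene's expression values by that gene's maximum across
#' tissues, the display convention of tissue-expression heatmaps: values in
#' `[0, 1]` with each row's maximum equal to 1. These relative values
#' compare one gene across tissues and are not comparable between genes.
#'
#' @param x non-negative gene x tissue matrix (e.g. RPKM).
#' @return matrix of the same shape; rows that are entirely zero are
#'   returned as `NA` (the ratio is undefined), with a warning.
#' @export
relative_heatmap <- function(x) {
  x <- as.matrix(x)
  if (any(x < 0, na.rm = TRUE)) {
    stop("relative_heatmap: expression values must be non-negative")
  }
  mx <- apply(x, 1, max)
  zero <- mx == 0
  if (any(zero)) {
    warning("relative_heatmap: ", sum(zero),
            " all-zero row(s) returned as NA")
    mx[zero] <- NA_real_
  }
  x / mx
}
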