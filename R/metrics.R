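# Evaluation metrics for imputation benchmarks: reconstruction error against
# a known ground truth (RMSE, Pearson correlation on the flattened matrices)
# and clustering-based measures against known cell labels (ARI, NMI,
# silhouette width, with Ward hierarchical clustering used to produce the
# inferred partition).

#' Root mean square error between two matrices
#'
#' @param a,b Matrices of identical shape.
#' @return `sqrt(mean((a - b)^2))`.
#' @export
rmse <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrices must have identical shape")
  sqrt(mean((a - b)^2))
}

#' Pearson correlation between flattened matrices
#'
#' @param a,b Matrices of identical shape, neither constant.
#' @return Pearson correlation coefficient of the flattened entries.
#' @export
pearson_flat <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop("matrices must have identical shape")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation undefined for a constant matrix")
  }
  stats::cor(as.vector(a), as.vector(b))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' 1 for identical partitions (up to label renaming), about 0 for random
#' labelings.
#'
#' @param labels_a,labels_b Label vectors of equal length (at least 2).
#' @return The ARI, at most 1.
#' @export
ari <- function(labels_a, labels_b) {
  check_labels(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- length(labels_a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Normalized mutual information
#'
#' Mutual information between two partitions normalized by the arithmetic
#' mean of their entropies; 1 for identical partitions, 0 for independent
#' ones.
#'
#' @param labels_a,labels_b Label vectors of equal length (at least 2).
#' @return The NMI, in `[0, 1]`.
#' @export
nmi <- function(labels_a, labels_b) {
  check_labels(labels_a, labels_b)
  tab <- table(labels_a, labels_b)
  n <- sum(tab)
  pij <- tab / n
  pa <- rowSums(pij)
  pb <- colSums(pij)
  mi <- sum(ifelse(pij > 0, pij * log(pij / outer(pa, pb)), 0))
  ha <- -sum(ifelse(pa > 0, pa * log(pa), 0))
  hb <- -sum(ifelse(pb > 0, pb * log(pb), 0))
  if (ha + hb == 0) return(1)  # both partitions are a single cluster
  max(0, min(1, mi / ((ha + hb) / 2)))
}

check_labels <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  if (length(a) < 2) stop("need at least 2 observations")
  invisible(TRUE)
}

#' Mean silhouette width of a labelled expression matrix
#'
#' For each cell, `a` is its mean Euclidean distance to the other cells of
#' its own cluster and `b` the smallest mean distance to any other cluster;
#' the silhouette is `(b - a) / max(a, b)`, and the mean over cells is
#' returned. Values near 1 indicate compact, well-separated clusters; values
#' near 0 overlapping clusters; negative values misassigned cells. Cells in
#' singleton clusters contribute 0 (the usual convention).
#'
#' @param x Matrix with cells in columns (e.g. processed expression, genes x
#'   cells).
#' @param labels Cluster label per cell; at least two distinct clusters.
#' @return Mean silhouette width, in `[-1, 1]`.
#' @export
silhouette_width <- function(x, labels) {
  stopifnot(is.matrix(x), length(labels) == ncol(x))
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette width requires at least 2 clusters")
  }
  d <- as.matrix(stats::dist(t(x)))
  n <- ncol(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    own[i] <- FALSE
    if (!any(own)) {
      s[i] <- 0
      next
    }
    a_i <- mean(d[i, own])
    b_i <- min(vapply(setdiff(unique(labels), labels[i]), function(cl) {
      mean(d[i, labels == cl])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  mean(s)
}

#' Hierarchical clustering of cells
#'
#' Agglomerative clustering of the cell columns with Ward linkage on
#' Euclidean distances, cut at `k` clusters. Deterministic.
#'
#' @param x Matrix with cells in columns.
#' @param k Number of clusters, `1 <= k <= N`.
#' @return Integer label per cell.
#' @export
hierarchical_cluster <- function(x, k) {
  stopifnot(is.matrix(x))
  n <- ncol(x)
  if (k > n) stop("'k' cannot exceed the number of cells (", n, ")")
  if (k < 1) stop("'k' must be at least 1")
  hc <- stats::hclust(stats::dist(t(x)), method = "ward.D2")
  stats::cutree(hc, k = k)
}

#' Full evaluation report against ground truth
#'
#' Computes RMSE and Pearson correlation of the imputed matrix against the
#' ground-truth matrix (both on the same processed scale), plus
#' clustering-based measures against the true labels: ARI and NMI of Ward
#' hierarchical clustering at `k = `number of true groups, and the
#' silhouette width of the true labels on the imputed matrix.
#'
#' @param imputed,truth Matrices of identical shape (genes x cells).
#' @param labels True group label per cell.
#' @param k Number of clusters for hierarchical clustering; defaults to the
#'   number of distinct labels.
#' @return A list of class `evaluation_report` with fields `rmse`, `pearson`,
#'   `ari`, `nmi`, `silhouette` and `cluster_labels`.
#' @export
evaluate_imputation <- function(imputed, truth, labels,
                                k = length(unique(labels))) {
  cl <- hierarchical_cluster(imputed, k)
  structure(list(
    rmse = rmse(imputed, truth),
    pearson = pearson_flat(imputed, truth),
    ari = ari(cl, labels),
    nmi = nmi(cl, labels),
    silhouette = silhouette_width(imputed, labels),
    cluster_labels = cl
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "evaluation_report: RMSE %.4f | Pearson %.4f | ARI %.4f | NMI %.4f | SW %.4f\n",
    x$rmse, x$pearson, x$ari, x$nmi, x$silhouette))
  invisible(x)
}
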