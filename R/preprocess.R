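#' Normalize a count matrix to log-scale expression
#'
#' Scales each cell (column) so that all cells share the median library size,
#' then applies `log10(value + pseudo)` elementwise. Zeros are mapped to the
#' small positive constant `log10(pseudo)`, which keeps dropout candidates
#' distinguishable from truly low expression after the log transform.
#'
#' @param counts Numeric matrix, genes in rows and cells in columns, all
#'   entries non-negative. Row and column names are carried through.
#' @param pseudo Pseudo-count added before the log; must exceed
#'   `1 - .Machine$double.eps` so the output is non-negative. Default 1.01.
#' @return Numeric matrix of the same shape with non-negative log-scale
#'   expression values (minimum `log10(pseudo)`).
#' @examples
#' m <- matrix(c(0, 9, 99), nrow = 3, dimnames = list(paste0("g", 1:3), "c1"))
#' normalize_counts(m)
#' @export
normalize_counts <- function(counts, pseudo = 1.01) {
  counts <- as_count_matrix(counts)
  if (pseudo <= 1 - .Machine$double.eps) {
    stop("'pseudo' must be at least 1 so that log10(x + pseudo) is non-negative")
  }
  lib <- colSums(counts)
  if (any(lib == 0)) {
    bad <- colnames(counts)[lib == 0]
    stop("cell(s) with zero library size: ", paste(bad, collapse = ", "))
  }
  target <- stats::median(lib)
  scaled <- sweep(counts, 2, target / lib, "*")
  log10(scaled + pseudo)
}

#' Reduce cells to principal-component coordinates
#'
#' Computes principal components of cells over gene dimensions (genes are
#' centred and, where non-constant, scaled to unit variance) and keeps the
#' smallest number of components whose cumulative explained variance reaches
#' `variance_kept`. The retained coordinates ("metagenes") are the substrate
#' for all cell-cell distance computations.
#'
#' @param x Numeric matrix of processed expression, genes x cells; all values
#'   finite.
#' @param variance_kept Fraction of total variance to retain, in (0, 1].
#'   Default 0.4.
#' @return A list with `z` (K x N matrix of component scores, cells in
#'   columns), `k` (number of retained components) and `explained` (cumulative
#'   explained-variance fractions for all components).
#' @export
reduce_dimension <- function(x, variance_kept = 0.4) {
  stopifnot(is.matrix(x), all(is.finite(x)))
  if (variance_kept <= 0 || variance_kept > 1) {
    stop("'variance_kept' must be in (0, 1]")
  }
  gene_sd <- apply(x, 1, stats::sd)
  keep <- gene_sd > 0
  if (!any(keep)) stop("matrix has zero total variance; cannot reduce dimension")
  pc <- stats::prcomp(t(x[keep, , drop = FALSE]), center = TRUE, scale. = TRUE)
  var_frac <- pc$sdev^2 / sum(pc$sdev^2)
  cum <- cumsum(var_frac)
  k <- which(cum >= variance_kept - 1e-12)[1]
  if (is.na(k)) k <- length(cum)
  k <- min(k, ncol(x) - 1L)
  k <- max(k, 1L)
  z <- t(pc$x[, seq_len(k), drop = FALSE])
  colnames(z) <- colnames(x)
  list(z = z, k = k, explained = cum)
}

#' Flag outlier cells in a latent representation
#'
#' A cell is an outlier when the log of its Euclidean distance to its
#' `n_neighbors`-th nearest neighbour exceeds Q3 + 3 IQR of that statistic
#' over all cells (a far-out Tukey fence; the log tames the right skew that
#' nearest-neighbour distances always carry, so ordinary cells in the bulk
#' are not flagged). The rule is parameter-free and scale-invariant and
#' flags only genuinely isolated cells. Outlier cells are excluded from the
#' affinity graph and from the imputation regressions, and are passed
#' through to the final output unimputed.
#'
#' @param z Latent matrix, components x cells.
#' @param n_neighbors Which nearest-neighbour distance to use. Default 5;
#'   capped at N - 1.
#' @return Integer vector of outlier cell indices (possibly empty). With two
#'   or fewer cells no outlier can be defined and the empty set is returned.
#' @export
detect_outlier_cells <- function(z, n_neighbors = 5) {
  stopifnot(is.matrix(z))
  n <- ncol(z)
  if (n <= 2) return(integer(0))
  n_neighbors <- min(as.integer(n_neighbors), n - 1L)
  if (n_neighbors < 1) stop("'n_neighbors' must be at least 1")
  d <- as.matrix(stats::dist(t(z)))
  knn_dist <- vapply(seq_len(n), function(i) {
    sort(d[i, -i])[n_neighbors]
  }, numeric(1))
  log_knn <- log(pmax(knn_dist, 1e-300))
  q <- stats::quantile(log_knn, c(0.25, 0.75), names = FALSE)
  fence <- q[2] + 3 * (q[2] - q[1])
  which(log_knn > fence)
}

#' Preprocess a raw count matrix for imputation
#'
#' Runs the standard pipeline ahead of imputation: drop all-zero genes,
#' normalize to log-scale expression (optional), project cells onto principal
#' components, and flag outlier cells. Outlier cells are removed from the
#' working matrix and reported so they can be appended, unimputed, to the
#' final result.
#'
#' @param counts Raw count matrix, genes x cells.
#' @param normalize If `TRUE` (default) apply library-size scaling and the
#'   log transform via [normalize_counts()]. If `FALSE` the input is treated
#'   as already processed (no scaling, no log); use this when feeding back a
#'   matrix that is already on the log scale.
#' @param pseudo Pseudo-count for [normalize_counts()].
#' @param variance_kept Fraction of variance kept by [reduce_dimension()].
#' @param outlier_neighbors Neighbour order for [detect_outlier_cells()].
#' @param drop_empty_genes Drop genes whose counts are zero in every cell
#'   (default `TRUE`); no other gene filtering is performed.
#' @return A list with components
#'   \describe{
#'     \item{x}{processed matrix over retained (non-outlier) cells}
#'     \item{z}{latent coordinates of retained cells}
#'     \item{x_full}{processed matrix over all cells, outliers included}
#'     \item{outliers}{integer indices (into the columns of `x_full`) of
#'       outlier cells}
#'     \item{kept_genes, kept_cells}{character vectors of retained ids}
#'   }
#' @export
preprocess_counts <- function(counts, normalize = TRUE, pseudo = 1.01,
                              variance_kept = 0.4, outlier_neighbors = 5,
                              drop_empty_genes = TRUE) {
  counts <- as_count_matrix(counts, require_nonneg = normalize)
  if (drop_empty_genes) {
    nonzero <- rowSums(counts != 0) > 0
    counts <- counts[nonzero, , drop = FALSE]
  }
  x_full <- if (normalize) normalize_counts(counts, pseudo) else counts
  red <- reduce_dimension(x_full, variance_kept)
  out <- detect_outlier_cells(red$z, outlier_neighbors)
  if (length(out) > 0) {
    x <- x_full[, -out, drop = FALSE]
    red <- reduce_dimension(x, variance_kept)
  } else {
    x <- x_full
  }
  list(
    x = x, z = red$z, x_full = x_full, outliers = out,
    kept_genes = rownames(x_full), kept_cells = colnames(x)
  )
}

# Coerce input to a dense named numeric matrix and validate the count-matrix
# contract (finite, optionally non-negative, unique ids).
as_count_matrix <- function(counts, require_nonneg = TRUE) {
  if (inherits(counts, "Matrix")) counts <- as.matrix(counts)
  if (is.data.frame(counts)) counts <- as.matrix(counts)
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("'counts' must be a numeric matrix (genes x cells)")
  }
  if (anyNA(counts) || any(!is.finite(counts))) {
    stop("'counts' contains missing or non-finite entries")
  }
  if (require_nonneg && any(counts < 0)) stop("'counts' contains negative entries")
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("gene", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("cell", seq_len(ncol(counts)))
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell ids")
  storage.mode(counts) <- "double"
  counts
}
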