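#' Squared Euclidean distances between cells
#'
#' @param z Latent matrix, components x cells (cells in columns).
#' @return Symmetric N x N matrix of squared Euclidean distances between cell
#'   columns, zero on the diagonal.
#' @export
pairwise_distance <- function(z) {
  stopifnot(is.matrix(z), all(is.finite(z)))
  d <- as.matrix(stats::dist(t(z)))^2
  diag(d) <- 0
  d
}

#' Adaptive per-cell kernel bandwidth
#'
#' The bandwidth of cell `i` is its distance to its `n`-th nearest neighbour:
#' the `n`-th smallest entry of row `i` of the distance matrix, excluding the
#' self-distance. Duplicated cells can legitimately give a zero bandwidth,
#' which [build_affinity()] handles as the kernel's limit.
#'
#' @param dist N x N distance matrix (as from [pairwise_distance()]).
#' @param i Cell index.
#' @param n Neighbour order, `1 <= n <= N - 1`.
#' @return The bandwidth (a distance on the same scale as `dist`).
#' @export
neighbor_bandwidth <- function(dist, i, n) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist))
  n_cells <- nrow(dist)
  if (n < 1 || n >= n_cells) {
    stop("'n' must satisfy 1 <= n <= N - 1 (N = ", n_cells, ")")
  }
  unname(sort(dist[i, -i])[n])
}

#' Build the cell affinity matrix
#'
#' Computes the N x N affinity `A` over latent coordinates with an adaptive
#' truncated Gaussian kernel: with `Dist` the squared Euclidean distance and
#' `sigma_i` the distance from cell `i` to its `n`-th nearest neighbour,
#'
#' \deqn{A_{ij} = \exp(-Dist(i,j) / (2 \sigma_i^2)) \textrm{ if } Dist(i,j)
#'   \le \sigma_i, \textrm{ else } 0.}
#'
#' Rows are adaptive, so `A` is generally not symmetric: each row keeps (at
#' least) the `n` nearest neighbours of its cell and zeroes everything
#' farther, which restricts the imputation regression of each cell to its own
#' neighbourhood. Ties at the `n`-th order statistic are included (the kernel
#' support is closed). When `sigma_i = 0` (cell `i` has `n` or more exact
#' duplicates) the kernel degenerates to its limit: affinity 1 to cells at
#' distance zero and 0 elsewhere.
#'
#' @param z Latent matrix, components x cells.
#' @param n_neighbor Neighbour order used for the adaptive bandwidth.
#'   Default 40.
#' @return Object of class `cell_affinity`: a list with `a` (N x N affinity
#'   matrix, entries in `[0, 1]`), `bandwidths` (per-cell sigma) and
#'   `n_neighbor`.
#' @export
build_affinity <- function(z, n_neighbor = 40) {
  stopifnot(is.matrix(z))
  n_cells <- ncol(z)
  if (n_cells < 2) stop("need at least 2 cells to build an affinity matrix")
  if (n_neighbor < 1 || n_neighbor >= n_cells) {
    stop("'n_neighbor' must satisfy 1 <= n_neighbor <= N - 1 (N = ", n_cells, ")")
  }
  d <- pairwise_distance(z)
  sig <- vapply(seq_len(n_cells), function(i) sort(d[i, -i])[n_neighbor],
                numeric(1))
  a <- matrix(0, n_cells, n_cells, dimnames = list(colnames(z), colnames(z)))
  for (i in seq_len(n_cells)) {
    if (sig[i] > 0) {
      inside <- d[i, ] <= sig[i]
      a[i, inside] <- exp(-d[i, inside] / (2 * sig[i]^2))
    } else {
      a[i, d[i, ] == 0] <- 1
    }
  }
  structure(list(a = a, bandwidths = sig, n_neighbor = n_neighbor),
            class = "cell_affinity")
}

#' @export
print.cell_affinity <- function(x, ...) {
  cat("cell_affinity:", nrow(x$a), "cells, n_neighbor =", x$n_neighbor, "\n")
  cat("  bandwidth range:", format(range(x$bandwidths), digits = 4), "\n")
  invisible(x)
}
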