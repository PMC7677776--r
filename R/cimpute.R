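# Single-pass imputation core: per cell, a non-negative lasso regression of
# the cell's (dropout-downweighted) expression on all other cells, with each
# candidate cell's column downweighted by its own dropout probabilities and
# scaled by its affinity to the target cell. Entries whose dropout
# probability crosses the threshold t are replaced by the regression
# prediction; everything else is kept bit-identical.

#' Imputation configuration
#'
#' @param t Dropout-probability threshold in `[0, 1]`; entries with
#'   probability at or above `t` are imputed, all others retained. Default
#'   0.5.
#' @param lam Lasso penalty `lambda >= 0`, or `NULL` (default) for the
#'   automatic per-cell choice `0.01 * max |design' target|` — a fixed
#'   fraction of the smallest penalty that shrinks every weight to zero, so
#'   the penalty is scale-free across cells.
#' @param n_neighbor Neighbour order for the affinity kernel. Default 40.
#' @param max_sweeps Maximum full coordinate-descent sweeps. Default 1000.
#' @param tol Stop when the largest coordinate change in a sweep falls below
#'   this. Default 1e-6.
#' @return A list of class `impute_config`.
#' @export
impute_config <- function(t = 0.5, lam = NULL, n_neighbor = 40,
                          max_sweeps = 1000, tol = 1e-6) {
  stopifnot(t >= 0, t <= 1, is.null(lam) || lam >= 0)
  structure(list(t = t, lam = lam, n_neighbor = n_neighbor,
                 max_sweeps = max_sweeps, tol = tol),
            class = "impute_config")
}

#' Assemble the per-cell regression problem
#'
#' For target cell `j`, the response is the cell's expression downweighted by
#' its dropout probabilities, `target_g = (1 - D_gj) X_gj`, so genes that are
#' probably dropped out in cell `j` contribute nothing to the fit. The design
#' column for each other cell `c` is `(1 - D_gc) A_jc X_gc`: information is
#' only borrowed from trusted (low-dropout) genes of cells similar to `j`,
#' and cells outside `j`'s kernel support (`A_jc = 0`) contribute an all-zero
#' column, which the solver keeps at weight zero.
#'
#' @param x Processed matrix, genes x cells.
#' @param d Dropout-probability matrix, same shape.
#' @param a N x N affinity matrix (or a `cell_affinity` object).
#' @param j Target cell index.
#' @return List with `design` (M x (N-1) matrix), `target` (length-M vector)
#'   and `others` (column indices of the remaining cells, in order).
#' @export
build_regression_problem <- function(x, d, a, j) {
  if (inherits(a, "cell_affinity")) a <- a$a
  stopifnot(is.matrix(x), all(dim(x) == dim(d)),
            nrow(a) == ncol(x), ncol(a) == ncol(x),
            j >= 1, j <= ncol(x))
  others <- setdiff(seq_len(ncol(x)), j)
  p <- (1 - d) * x
  design <- sweep(p[, others, drop = FALSE], 2, a[j, others], "*")
  list(design = design, target = p[, j], others = others)
}

#' Non-negative lasso by coordinate descent
#'
#' Minimizes `0.5 * ||y - X b||^2 + lam * sum(b)` subject to `b >= 0` by
#' cyclic coordinate descent on the Gram matrix: each coordinate update is
#' `b_c <- max(0, (g_c - lam) / h_c)` with `g_c` the partial residual
#' correlation and `h_c` the squared column norm. All-zero columns keep
#' weight zero. The objective is non-increasing per sweep and the objective
#' trace is recorded.
#'
#' @param design M x P design matrix (finite entries).
#' @param target Length-M response vector.
#' @param lam Penalty `lambda >= 0`.
#' @param max_sweeps Maximum number of full sweeps. Default 1000.
#' @param tol Stop when the largest coordinate change in a sweep is below
#'   this. Default 1e-6.
#' @return List of class `cell_weights` with `b` (non-negative weights),
#'   `objective_trace` (objective after each sweep), `sweeps` and `converged`.
#' @export
nnlasso <- function(design, target, lam, max_sweeps = 1000, tol = 1e-6) {
  stopifnot(is.matrix(design), length(target) == nrow(design),
            all(is.finite(design)), all(is.finite(target)), lam >= 0)
  gram <- crossprod(design)
  q <- drop(crossprod(design, target))
  fit <- .nnlasso_cd(gram, q, sum(target^2), lam, as.integer(max_sweeps), tol)
  b <- fit$b
  names(b) <- colnames(design)
  structure(list(b = b, objective_trace = fit$objective_trace,
                 sweeps = fit$sweeps, converged = fit$converged),
            class = "cell_weights")
}

#' Single-pass dropout imputation
#'
#' For each cell, solves the affinity- and dropout-weighted non-negative
#' lasso of [build_regression_problem()] and [nnlasso()], then replaces
#' exactly the entries with dropout probability `>= t` by the regression
#' prediction (clipped at zero). All other entries are returned bit-identical
#' to the input. A cell with zero affinity to every other cell cannot borrow
#' information; its entries are left unchanged with a warning.
#'
#' @param x Processed matrix, genes x cells.
#' @param d Dropout-probability matrix (or a `dropout_model`).
#' @param a Affinity matrix (or a `cell_affinity`).
#' @param config An [impute_config()].
#' @return Object of class `imputed_matrix`: list with `values` (imputed
#'   matrix, all entries `>= 0` given non-negative input), `imputed_mask`
#'   (logical matrix, `TRUE` where `d >= t`) and `weights` (per-cell
#'   `cell_weights`, `NULL` where no regression was needed).
#' @export
impute_once <- function(x, d, a, config = impute_config()) {
  if (inherits(d, "dropout_model")) d <- d$d
  if (inherits(a, "cell_affinity")) a <- a$a
  stopifnot(is.matrix(x), all(dim(x) == dim(d)),
            nrow(a) == ncol(x), ncol(a) == ncol(x))
  n <- ncol(x)
  out <- x
  mask <- d >= config$t
  weights <- vector("list", n)
  p <- (1 - d) * x
  for (j in seq_len(n)) {
    need <- which(mask[, j])
    if (length(need) == 0) next
    aj <- a[j, -j]
    if (all(aj == 0)) {
      warning("cell ", colnames(x)[j] %||% j,
              " has zero affinity to every other cell; left unimputed")
      mask[, j] <- FALSE
      next
    }
    design <- sweep(p[, -j, drop = FALSE], 2, aj, "*")
    target <- p[, j]
    lam <- config$lam
    if (is.null(lam)) {
      lam <- 0.01 * max(abs(crossprod(design, target)))
    }
    w <- nnlasso(design, target, lam, config$max_sweeps, config$tol)
    weights[[j]] <- w
    pred <- drop(design %*% w$b)
    out[need, j] <- pmax(pred[need], 0)
  }
  structure(list(values = out, imputed_mask = mask, weights = weights),
            class = "imputed_matrix")
}

#' @export
print.imputed_matrix <- function(x, ...) {
  cat("imputed_matrix:", nrow(x$values), "genes x", ncol(x$values), "cells;",
      sum(x$imputed_mask), "entries imputed",
      sprintf("(%.1f%%)\n", 100 * mean(x$imputed_mask)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
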