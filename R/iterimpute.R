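#' Self-consistency distance between two matrices
#'
#' The self-consistency of an imputation mapping `f` at a matrix `X` is the
#' discrepancy between `f`'s output and `f` applied to that output,
#' `||X_out - f(X_out)||_F^2 / (M N)` — a mean squared elementwise
#' difference. By default the square root (an RMSE, on the same scale as the
#' expression values) is returned, which is the scale on which the
#' convergence threshold `theta` is interpreted; set `squared = TRUE` for the
#' raw mean squared difference.
#'
#' @param x_out,f_x_out Two matrices of identical shape.
#' @param squared Return the mean squared difference instead of its square
#'   root. Default `FALSE`.
#' @return A non-negative scalar.
#' @export
self_consistency <- function(x_out, f_x_out, squared = FALSE) {
  if (!all(dim(x_out) == dim(f_x_out))) {
    stop("matrices must have identical shape")
  }
  mse <- mean((x_out - f_x_out)^2)
  if (squared) mse else sqrt(mse)
}

#' Gene-wise empirical-Bayes shrinkage pre-smoother
#'
#' A lightweight stand-in for the heavy Bayesian pre-smoothers sometimes run
#' ahead of iterative imputation: each entry is shrunk toward its gene's
#' expression-component mean by its posterior dropout probability,
#' `x_s = (1 - D) x + D mu_g`, with `D` and `mu_g` from the Gamma-Normal
#' mixture of [fit_dropout_model()]. Trusted entries are untouched; likely
#' dropouts are pulled to the gene's typical expression level. Pass it as
#' the `presmooth` hook of [iterimpute()].
#'
#' Note that after this fill the suspected dropouts sit at their gene means
#' and are no longer identifiable to a refitted mixture, so the subsequent
#' imputation loop typically finds little left to impute and converges
#' almost immediately — the smoother, not the regression, then dominates the
#' output. It is therefore off by default.
#'
#' @param x Processed matrix, genes x cells.
#' @return Matrix of the same shape.
#' @export
presmooth_shrink <- function(x) {
  stopifnot(is.matrix(x))
  model <- fit_dropout_model(x)
  mu <- expression_means(x, model$params)
  x * (1 - model$d) + model$d * mu
}

# Per-gene typical expression level: the Normal-component mean where the
# mixture was fitted, the gene mean where it was skipped.
expression_means <- function(x, params) {
  vapply(seq_len(nrow(x)), function(i) {
    p <- params[[i]]
    if (is.null(p)) mean(x[i, ]) else p$mu
  }, numeric(1))
}

#' Iterative self-consistent imputation
#'
#' The full pipeline: preprocess the counts, optionally pre-smooth, then
#' repeatedly apply the single-pass imputation core — refitting the dropout
#' model and the cell affinity on the current matrix each round — until the
#' between-iteration RMSE falls below `theta` (self-consistency) or
#' `max_outer` rounds are exhausted. Outlier cells detected during
#' preprocessing are excluded from model fitting and regression and appended
#' to the output unimputed, in their original column positions.
#'
#' @param counts Raw count matrix, genes x cells (or a processed matrix with
#'   `normalize = FALSE`).
#' @param config An [impute_config()] (threshold `t`, penalty, neighbour
#'   order, solver controls).
#' @param theta Self-consistency threshold on the between-iteration RMSE.
#'   Default 0.1.
#' @param max_outer Maximum outer iterations. Default 10.
#' @param iterate If `FALSE`, run a single imputation pass and stop (no
#'   self-consistency refinement). Default `TRUE`.
#' @param presmooth Optional function `matrix -> matrix` applied to the
#'   processed matrix before the first imputation pass (e.g.
#'   [presmooth_shrink()]). Default `NULL` (none).
#' @param affinity_on Matrix on which the latent space for the cell affinity
#'   is computed each round: `"completed"` (default) replaces each entry by
#'   its expected value under the fitted dropout model,
#'   `(1 - D) x + D mu_g`, before the principal-component projection, so
#'   that suspected dropouts — which carry no information about cell
#'   identity — do not dominate the Euclidean distances; `"current"` uses
#'   the current matrix as-is. The dropout model and the imputation
#'   regressions always operate on the current (uncompleted) matrix.
#' @param normalize,pseudo,variance_kept,outlier_neighbors Passed to
#'   [preprocess_counts()].
#' @param verbose Print per-iteration progress. Default `FALSE`.
#' @return Object of class `iterimpute_result`: list with
#'   \describe{
#'     \item{imputed}{final log-scale matrix over all cells (outliers
#'       unimputed)}
#'     \item{imputed_retained}{final matrix over retained cells only}
#'     \item{report}{list with `rmse_trace`, `theta`, `iterations_run`,
#'       `self_consistent`}
#'     \item{preprocess}{the [preprocess_counts()] result}
#'     \item{last_model}{the dropout model of the final iteration}
#'   }
#' @examples
#' sim <- simulate_counts(sim_params(n_genes = 120, n_cells = 40,
#'                                   dropout_mid = 1, seed = 7))
#' res <- iterimpute(sim$observed_counts,
#'                   config = impute_config(n_neighbor = 10), max_outer = 3)
#' res$report$rmse_trace
#' @export
iterimpute <- function(counts, config = impute_config(), theta = 0.1,
                       max_outer = 10, iterate = TRUE, presmooth = NULL,
                       affinity_on = c("completed", "current"),
                       normalize = TRUE, pseudo = 1.01, variance_kept = 0.4,
                       outlier_neighbors = 5, verbose = FALSE) {
  affinity_on <- match.arg(affinity_on)
  stopifnot(theta > 0, max_outer >= 1)
  pre <- preprocess_counts(counts, normalize = normalize, pseudo = pseudo,
                           variance_kept = variance_kept,
                           outlier_neighbors = outlier_neighbors)
  cur <- pre$x
  if (!is.null(presmooth)) cur <- presmooth(cur)
  if (config$n_neighbor >= ncol(cur)) {
    stop("n_neighbor (", config$n_neighbor, ") must be smaller than the ",
         "number of retained cells (", ncol(cur), ")")
  }
  low_cut <- if (normalize) log10(pseudo) + 0.1 else log10(1.01) + 0.1
  trace <- numeric(0)
  model <- NULL
  for (it in seq_len(max_outer)) {
    model <- fit_dropout_model(cur, low_cut = low_cut)
    x_aff <- if (affinity_on == "completed") {
      cur * (1 - model$d) + model$d * expression_means(cur, model$params)
    } else {
      cur
    }
    z <- reduce_dimension(x_aff, variance_kept)$z
    aff <- build_affinity(z, config$n_neighbor)
    step <- impute_once(cur, model$d, aff, config)
    trace[it] <- self_consistency(cur, step$values)
    if (verbose) {
      message(sprintf("iteration %d: self-consistency RMSE %.4f (%d entries imputed)",
                      it, trace[it], sum(step$imputed_mask)))
    }
    cur <- step$values
    if (!iterate) break
    if (trace[it] < theta) break
  }
  self_consistent <- trace[length(trace)] < theta
  if (iterate && !self_consistent) {
    warning("not self-consistent after ", max_outer,
            " iterations (final RMSE ", format(trace[length(trace)], digits = 4),
            " >= theta = ", theta, ")")
  }
  full <- pre$x_full
  full[, pre$kept_cells] <- cur
  structure(list(
    imputed = full,
    imputed_retained = cur,
    report = list(rmse_trace = trace, theta = theta,
                  iterations_run = length(trace),
                  self_consistent = self_consistent),
    preprocess = pre,
    last_model = model
  ), class = "iterimpute_result")
}

#' @export
print.iterimpute_result <- function(x, ...) {
  r <- x$report
  cat("iterimpute_result:", nrow(x$imputed), "genes x", ncol(x$imputed), "cells\n")
  cat("  iterations:", r$iterations_run,
      "| final self-consistency RMSE:",
      format(r$rmse_trace[r$iterations_run], digits = 4),
      "| self-consistent:", r$self_consistent, "(theta =", r$theta, ")\n")
  if (length(x$preprocess$outliers) > 0) {
    cat("  outlier cells passed through unimputed:",
        length(x$preprocess$outliers), "\n")
  }
  invisible(x)
}
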