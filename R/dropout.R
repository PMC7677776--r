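# Gamma-Normal mixture dropout model.
#
# On the log-scale processed matrix, each gene's expression across cells is
# modelled as a two-component mixture: a Gamma component absorbing the mass
# near zero created by dropout events, and a Normal component for the actual
# expression level. The posterior weight of the Gamma component at an entry
# is its dropout probability. Raw-count zero-inflated models (ZINB) do not
# apply here because the processed matrix is continuous.

GAMMA_SHAPE_MAX <- 1e4   # caps the dropout spike; keeps the likelihood bounded
SIGMA_FLOOR <- 1e-4
DENSITY_EPS <- 1e-6      # floor for Gamma evaluation (pdf diverges at 0 for shape < 1)

#' Gamma-Normal mixture density
#'
#' Evaluates `pi * dgamma(x; alpha, beta) + (1 - pi) * dnorm(x; mu, sigma)`.
#' `x` is floored at a small epsilon before the Gamma evaluation so that the
#' density is finite even at zero when `alpha < 1`.
#'
#' @param x Numeric vector of non-negative processed expression values.
#' @param params A `gene_mixture` object or list with fields `pi`, `alpha`,
#'   `beta` (Gamma shape/rate), `mu`, `sigma`.
#' @return Numeric vector of mixture densities, all finite.
#' @export
mixture_density <- function(x, params) {
  stopifnot(all(x >= 0))
  p <- params
  xg <- pmax(x, DENSITY_EPS)
  p$pi * stats::dgamma(xg, shape = p$alpha, rate = p$beta) +
    (1 - p$pi) * stats::dnorm(x, mean = p$mu, sd = p$sigma)
}

#' Fit the Gamma-Normal mixture for one gene by EM
#'
#' Expectation-maximization with exact M-steps: the mixing weight is the mean
#' responsibility, the Normal parameters are responsibility-weighted moments,
#' and the Gamma parameters are the responsibility-weighted maximum-likelihood
#' estimates (shape solved by Newton iteration on the profile equation
#' `log(alpha) - digamma(alpha) = log(weighted mean) - weighted mean log`).
#' Because every M-step maximizes its part of the expected complete-data
#' log-likelihood over a constraint set that always contains the previous
#' parameters (shape capped, Normal sd floored), the observed-data
#' log-likelihood is non-decreasing across iterations.
#'
#' Initialization is deterministic: `pi` starts at the fraction of values at
#' or below `low_cut` (by default just above the log-pseudo-count floor, the
#' value dropouts map to); the Gamma component is initialized by moments on
#' the lower half of the data and the Normal component on the upper half.
#'
#' @param values Numeric vector of processed expression for one gene across
#'   cells; at least 10 finite values.
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Convergence tolerance on the change in log-likelihood
#'   (default 1e-4).
#' @param low_cut Threshold under which a value is counted as "low" for
#'   initializing `pi`. Default `log10(1.01) + 0.1`, matching the default
#'   pseudo-count of [normalize_counts()].
#' @return Object of class `gene_mixture`: list with `pi`, `alpha`, `beta`,
#'   `mu`, `sigma`, `loglik`, `loglik_trace`, `iterations`, `converged`.
#' @export
fit_gene_mixture <- function(values, max_iter = 100, tol = 1e-4,
                             low_cut = log10(1.01) + 0.1) {
  x <- values[is.finite(values)]
  if (length(x) < 10) stop("need at least 10 finite values to fit the mixture")
  if (any(x < 0)) stop("processed expression values must be non-negative")

  if (stats::sd(x) < 1e-8) {
    # degenerate gene: nothing to separate
    p <- list(pi = mean(x <= low_cut), alpha = 1, beta = 1,
              mu = mean(x), sigma = SIGMA_FLOOR,
              loglik = NA_real_, loglik_trace = numeric(0),
              iterations = 0L, converged = FALSE)
    class(p) <- "gene_mixture"
    return(p)
  }

  xg <- pmax(x, DENSITY_EPS)
  lxg <- log(xg)

  pi <- mean(x <= low_cut)
  med <- stats::median(x)
  lo <- xg[x <= med]
  hi <- x[x > med]
  if (length(hi) < 2) hi <- x
  m_lo <- mean(lo)
  v_lo <- max(stats::var(lo), 1e-8)
  alpha <- min(max(m_lo^2 / v_lo, 1e-3), GAMMA_SHAPE_MAX)
  beta <- alpha / m_lo
  mu <- mean(hi)
  sigma <- max(stats::sd(hi), SIGMA_FLOOR)

  trace <- numeric(0)
  prev_ll <- -Inf
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    dg <- pi * stats::dgamma(xg, shape = alpha, rate = beta)
    dn <- (1 - pi) * stats::dnorm(x, mean = mu, sd = sigma)
    den <- dg + dn
    ll <- sum(log(pmax(den, .Machine$double.xmin)))
    trace <- c(trace, ll)
    if (is.finite(prev_ll) && abs(ll - prev_ll) < tol) {
      converged <- TRUE
      break
    }
    prev_ll <- ll

    r <- ifelse(den > 0, dg / den, as.numeric(pi > 0.5))
    w <- sum(r)
    pi <- mean(r)
    wn <- sum(1 - r)
    if (wn > 1e-10) {
      mu <- sum((1 - r) * x) / wn
      sigma <- max(sqrt(sum((1 - r) * (x - mu)^2) / wn), SIGMA_FLOOR)
    }
    if (w > 1e-10) {
      mbar <- sum(r * xg) / w
      lbar <- sum(r * lxg) / w
      alpha <- gamma_shape_mle(log(mbar) - lbar)
      beta <- alpha / mbar
    }
  }
  p <- list(pi = pi, alpha = alpha, beta = beta, mu = mu, sigma = sigma,
            loglik = trace[length(trace)], loglik_trace = trace,
            iterations = it, converged = converged)
  class(p) <- "gene_mixture"
  p
}

# Weighted Gamma shape MLE: solves log(a) - digamma(a) = s by Newton's method
# with the Minka closed-form initializer. s >= 0 by Jensen's inequality;
# s -> 0 means a concentrated component, capped at GAMMA_SHAPE_MAX.
gamma_shape_mle <- function(s) {
  if (!is.finite(s) || s <= 1e-12) return(GAMMA_SHAPE_MAX)
  a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
  for (i in 1:50) {
    f <- log(a) - digamma(a) - s
    df <- 1 / a - trigamma(a)
    a_new <- a - f / df
    if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
    if (abs(a_new - a) < 1e-10 * a) {
      a <- a_new
      break
    }
    a <- a_new
  }
  min(max(a, 1e-4), GAMMA_SHAPE_MAX)
}

#' @export
print.gene_mixture <- function(x, ...) {
  cat(sprintf(
    "gene_mixture: pi=%.3f alpha=%.3g beta=%.3g mu=%.3f sigma=%.3f (%s in %d it.)\n",
    x$pi, x$alpha, x$beta, x$mu, x$sigma,
    if (isTRUE(x$converged)) "converged" else "not converged", x$iterations))
  invisible(x)
}

#' Posterior dropout probabilities for a processed matrix
#'
#' For each entry, the posterior probability that it originates from the
#' Gamma (dropout) component of its gene's fitted mixture:
#' `D_ij = pi_i Gamma(X_ij) / (pi_i Gamma(X_ij) + (1 - pi_i) Normal(X_ij))`.
#' Genes whose `params` entry is `NULL` (skipped during fitting) get a zero
#' row: their observed values are treated as real.
#'
#' @param x Processed matrix, genes x cells.
#' @param params List of `gene_mixture` fits, one per row of `x` (entries may
#'   be `NULL` for skipped genes).
#' @return Matrix of dropout probabilities in `[0, 1]`, same shape as `x`.
#' @export
dropout_probability <- function(x, params) {
  stopifnot(is.matrix(x), length(params) == nrow(x))
  d <- matrix(0, nrow(x), ncol(x), dimnames = dimnames(x))
  for (i in seq_len(nrow(x))) {
    p <- params[[i]]
    if (is.null(p)) next
    xi <- x[i, ]
    xg <- pmax(xi, DENSITY_EPS)
    num <- p$pi * stats::dgamma(xg, shape = p$alpha, rate = p$beta)
    den <- num + (1 - p$pi) * stats::dnorm(xi, mean = p$mu, sd = p$sigma)
    d[i, ] <- ifelse(den > 0, num / den, as.numeric(p$pi > 0.5))
  }
  d[d < 0] <- 0
  d[d > 1] <- 1
  d
}

#' Fit the dropout model for every gene of a processed matrix
#'
#' Runs [fit_gene_mixture()] per gene and assembles the dropout-probability
#' matrix. Genes with fewer than 10 finite values or near-constant expression
#' are skipped (their dropout probabilities are 0, i.e. their observed values
#' are kept as-is); this is the conservative choice for unfittable genes.
#'
#' @inheritParams fit_gene_mixture
#' @param x Processed matrix, genes x cells.
#' @return Object of class `dropout_model`: list with `d` (dropout-probability
#'   matrix), `params` (per-gene fits, `NULL` where skipped) and `skipped`
#'   (integer indices of skipped genes).
#' @export
fit_dropout_model <- function(x, max_iter = 100, tol = 1e-4,
                              low_cut = log10(1.01) + 0.1) {
  stopifnot(is.matrix(x))
  m <- nrow(x)
  params <- vector("list", m)
  skipped <- integer(0)
  for (i in seq_len(m)) {
    xi <- x[i, ]
    xi_f <- xi[is.finite(xi)]
    if (length(xi_f) < 10 || stats::sd(xi_f) < 1e-6) {
      skipped <- c(skipped, i)
      next
    }
    params[[i]] <- fit_gene_mixture(xi, max_iter = max_iter, tol = tol,
                                    low_cut = low_cut)
  }
  structure(
    list(d = dropout_probability(x, params), params = params, skipped = skipped),
    class = "dropout_model")
}

#' @export
print.dropout_model <- function(x, ...) {
  cat("dropout_model:", nrow(x$d), "genes x", ncol(x$d), "cells;",
      length(x$skipped), "genes skipped\n")
  cat(sprintf("  mean dropout probability: %.3f\n", mean(x$d)))
  invisible(x)
}

#' Write per-gene mixture parameters to a TSV file
#'
#' @param model A `dropout_model`.
#' @param path Output file path.
#' @param gene_ids Optional gene ids (defaults to rownames of `model$d`).
#' @return Invisibly, the table written.
#' @export
write_mixture_params <- function(model, path, gene_ids = rownames(model$d)) {
  rows <- lapply(seq_along(model$params), function(i) {
    p <- model$params[[i]]
    if (is.null(p)) {
      data.frame(gene = gene_ids[i], pi = 0, alpha = NA_real_, beta = NA_real_,
                 mu = NA_real_, sigma = NA_real_, loglik = NA_real_,
                 converged = NA)
    } else {
      data.frame(gene = gene_ids[i], pi = p$pi, alpha = p$alpha, beta = p$beta,
                 mu = p$mu, sigma = p$sigma, loglik = p$loglik,
                 converged = p$converged)
    }
  })
  tab <- do.call(rbind, rows)
  data.table::fwrite(tab, path, sep = "\t")
  invisible(tab)
}
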