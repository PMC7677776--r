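# Small programmatic fixtures shared across test files.

# Random count matrix with Poisson entries and a fraction of zeros.
random_counts <- function(genes = 30, cells = 12, lambda = 5, zero_frac = 0.3,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(rpois(genes * cells, lambda), genes, cells,
              dimnames = list(paste0("g", seq_len(genes)),
                              paste0("c", seq_len(cells))))
  m[matrix(runif(genes * cells) < zero_frac, genes, cells)] <- 0
  # keep the count-matrix contract satisfied
  m[1, colSums(m) == 0] <- 1
  m[rowSums(m) == 0, 1] <- 1
  m
}

# Two well-separated cell populations in a processed (log-scale) matrix.
two_blob_matrix <- function(genes = 40, per_group = 8, gap = 5, noise = 0.1,
                            seed = 1) {
  set.seed(seed)
  base <- matrix(runif(genes, 0.5, 2), genes, 1)
  g1 <- base %*% t(rep(1, per_group))
  g2 <- (base + gap) %*% t(rep(1, per_group))
  x <- cbind(g1, g2) + matrix(rnorm(genes * 2 * per_group, sd = noise),
                              genes, 2 * per_group)
  x <- pmax(x, 0)
  dimnames(x) <- list(paste0("g", seq_len(genes)),
                      paste0("c", seq_len(2 * per_group)))
  list(x = x, labels = rep(1:2, each = per_group))
}

# Reference objective of the non-negative lasso problem.
nnlasso_objective <- function(design, target, b, lam) {
  0.5 * sum((target - design %*% b)^2) + lam * sum(b)
}

# Independent oracle for the non-negative lasso: box-constrained quasi-Newton
# on the objective, which is smooth on b >= 0.
nnlasso_oracle <- function(design, target, lam, start = NULL) {
  p <- ncol(design)
  if (is.null(start)) start <- rep(0.01, p)
  fn <- function(b) nnlasso_objective(design, target, b, lam)
  gr <- function(b) drop(crossprod(design, design %*% b - target)) + lam
  o <- optim(start, fn, gr, method = "L-BFGS-B", lower = rep(0, p),
             control = list(maxit = 2000, factr = 1e4))
  o
}
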