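test_that("mixture_density matches independently coded pdfs", {
  p <- list(pi = 0.5, alpha = 2, beta = 2, mu = 3, sigma = 1)
  x <- c(0.2, 1, 2.5, 4)
  manual <- 0.5 * (x^(2 - 1) * 2^2 * exp(-2 * x) / gamma(2)) +
    0.5 * exp(-(x - 3)^2 / 2) / sqrt(2 * pi)
  expect_equal(mixture_density(x, p), manual, tolerance = 1e-12)

  # degenerate mixtures
  pn <- list(pi = 0, alpha = 1, beta = 1, mu = 2, sigma = 0.5)
  expect_equal(mixture_density(x, pn), dnorm(x, 2, 0.5), tolerance = 1e-14)
  pg <- list(pi = 1, alpha = 1, beta = 1, mu = 0, sigma = 1)
  expect_equal(mixture_density(0, pg), dgamma(1e-6, 1, 1), tolerance = 1e-12)
  # finite even at zero with a diverging Gamma pdf (alpha < 1)
  pd <- list(pi = 1, alpha = 0.3, beta = 1, mu = 0, sigma = 1)
  expect_true(is.finite(mixture_density(0, pd)))
})

test_that("fit_gene_mixture recovers parameters of a planted mixture", {
  set.seed(42)
  n <- 5000
  truth <- list(pi = 0.5, shape = 2, rate = 4, mu = 4, sigma = 0.5)
  z <- runif(n) < truth$pi
  x <- ifelse(z, rgamma(n, truth$shape, truth$rate),
              rnorm(n, truth$mu, truth$sigma))
  x <- pmax(x, 0)
  fit <- fit_gene_mixture(x)
  expect_true(fit$converged)
  expect_lt(abs(fit$pi - truth$pi), 0.05)
  expect_lt(abs(fit$mu - truth$mu), 0.1)
})

test_that("a tight high Normal gene gets a near-zero dropout weight", {
  set.seed(7)
  x <- rnorm(500, mean = 6, sd = 0.3)
  fit <- fit_gene_mixture(x)
  expect_lt(fit$pi, 0.05)
})

test_that("EM log-likelihood trace is non-decreasing on arbitrary genes", {
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(20:200, 1)
    pi_t <- runif(1, 0.05, 0.9)
    x <- ifelse(runif(n) < pi_t,
                rgamma(n, runif(1, 0.5, 3), runif(1, 1, 8)),
                rnorm(n, runif(1, 1, 6), runif(1, 0.2, 1.5)))
    x <- pmax(x, 0)
    fit <- fit_gene_mixture(x)
    expect_true(all(diff(fit$loglik_trace) >= -1e-8))
  }
})

test_that("degenerate genes are handled without crashing", {
  expect_error(fit_gene_mixture(rep(1, 5)), "at least 10")
  fit <- fit_gene_mixture(rep(2, 50))
  expect_false(fit$converged)
  expect_gte(fit$sigma, 1e-4)
})

test_that("dropout_probability implements the posterior of the Gamma component", {
  x <- matrix(seq(0.1, 3, length.out = 12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:4)))
  mk <- function(pi) list(pi = pi, alpha = 1.2, beta = 3, mu = 2.5, sigma = 0.4)
  params <- list(mk(0), mk(1), mk(0.5))
  d <- dropout_probability(x, params)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(d[1, ]), rep(0, 4))   # pi = 0: no dropout mass
  expect_equal(unname(d[2, ]), rep(1, 4))   # pi = 1: everything is dropout
  # pi = 0.5 at a point where the two pdfs coincide: posterior exactly 1/2
  p <- mk(0.5)
  f <- function(v) dgamma(v, p$alpha, p$beta) - dnorm(v, p$mu, p$sigma)
  x_eq <- uniroot(f, c(0.5, 2.5), tol = 1e-12)$root
  xm <- matrix(x_eq, 1, 1, dimnames = list("g", "c"))
  expect_equal(unname(dropout_probability(xm, list(p))[1, 1]), 0.5,
               tolerance = 1e-6)
})

test_that("dropout probability decreases with expression for a low Gamma / high Normal gene", {
  p <- list(pi = 0.4, alpha = 0.8, beta = 5, mu = 3, sigma = 0.6)
  x <- matrix(seq(0, 3, length.out = 50), 1, 50,
              dimnames = list("g", paste0("c", 1:50)))
  d <- dropout_probability(x, list(p))
  expect_true(all(diff(d[1, ]) <= 1e-12))
})

test_that("fitted dropout probabilities equal the E-step responsibilities", {
  set.seed(3)
  x <- pmax(c(rgamma(60, 1, 6), rnorm(60, 3, 0.5)), 0)
  fit <- fit_gene_mixture(x, tol = 1e-10, max_iter = 500)
  xm <- matrix(x, 1, length(x),
               dimnames = list("g", paste0("c", seq_along(x))))
  d <- dropout_probability(xm, list(fit))[1, ]
  xg <- pmax(x, 1e-6)
  num <- fit$pi * dgamma(xg, fit$alpha, fit$beta)
  den <- num + (1 - fit$pi) * dnorm(x, fit$mu, fit$sigma)
  expect_equal(unname(d), num / den, tolerance = 1e-10)
})

test_that("fit_dropout_model skips unfittable genes conservatively", {
  set.seed(31)
  x <- normalize_counts(random_counts(25, 30, seed = 31))
  x[4, ] <- x[4, 1]  # constant gene
  model <- fit_dropout_model(x)
  expect_true(4 %in% model$skipped)
  expect_equal(unname(model$d[4, ]), rep(0, 30))
  expect_true(all(model$d >= 0 & model$d <= 1))
  # deterministic given identical input
  model2 <- fit_dropout_model(x)
  expect_identical(model$d, model2$d)
})
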