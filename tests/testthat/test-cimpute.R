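test_that("build_regression_problem weights the design and target as specified", {
  set.seed(1)
  x <- matrix(runif(9, 0.5, 3), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  # unweighted limit: D = 0 and unit affinities reduce to plain columns
  d0 <- matrix(0, 3, 3)
  a1 <- matrix(1, 3, 3)
  pr <- build_regression_problem(x, d0, a1, j = 2)
  expect_equal(pr$design, x[, c(1, 3)], ignore_attr = TRUE)
  expect_equal(unname(pr$target), unname(x[, 2]))

  # hand-set weights: entry-by-entry arithmetic oracle
  d <- matrix(c(0.1, 1, 0, 1, 0.5, 0.2, 0, 0, 0.7), 3, 3)
  a <- matrix(c(1, 0.5, 0.2, 0.5, 1, 0, 0.2, 0.4, 1), 3, 3, byrow = TRUE)
  pr2 <- build_regression_problem(x, d, a, j = 1)
  for (g in 1:3) {
    expect_equal(unname(pr2$target[g]), (1 - d[g, 1]) * x[g, 1])
    expect_equal(unname(pr2$design[g, 1]), (1 - d[g, 2]) * a[1, 2] * x[g, 2])
    expect_equal(unname(pr2$design[g, 2]), (1 - d[g, 3]) * a[1, 3] * x[g, 3])
  }
  # a gene fully dropped out in the target cell contributes nothing
  expect_equal(unname(pr2$target[2]), 0)
  # zero-affinity cells give all-zero design columns
  pr3 <- build_regression_problem(x, d, a, j = 2)
  expect_equal(unname(pr3$design[, 2]), rep(0, 3))  # a[2,3] = 0
})

test_that("nnlasso shrinks fully at the null-threshold penalty", {
  set.seed(2)
  design <- matrix(rnorm(40), 10, 4)
  target <- rnorm(10)
  lam_max <- max(abs(crossprod(design, target)))
  w <- nnlasso(design, target, lam = lam_max)
  expect_equal(unname(w$b), rep(0, 4))
  expect_true(w$converged)
})

test_that("nnlasso solves the orthonormal case in closed form", {
  q <- qr.Q(qr(matrix(rnorm(36), 6, 6)))[, 1:4]
  target <- c(2, -1, 0.5, 3, 0, 0)
  w <- nnlasso(q, target, lam = 0)
  proj <- drop(crossprod(q, target))
  expect_equal(unname(w$b), pmax(proj, 0), tolerance = 1e-8)
})

test_that("nnlasso matches a constrained-optimizer oracle and keeps zero columns at zero", {
  set.seed(5)
  design <- matrix(rnorm(240), 30, 8)
  design[, 3] <- 0
  target <- rnorm(30)
  lam <- 0.1
  w <- nnlasso(design, target, lam, tol = 1e-10)
  expect_equal(unname(w$b[3]), 0)
  expect_true(all(w$b >= 0))
  expect_true(all(diff(w$objective_trace) <= 1e-10))
  oracle <- nnlasso_oracle(design, target, lam)
  obj_cd <- nnlasso_objective(design, target, w$b, lam)
  expect_lte(obj_cd, oracle$value + 1e-6 * max(1, abs(oracle$value)))
})

test_that("impute_once preserves confident entries exactly and stays non-negative", {
  set.seed(6)
  x <- normalize_counts(random_counts(20, 10, seed = 6))
  model <- fit_dropout_model(x)
  aff <- build_affinity(reduce_dimension(x)$z, 4)
  res <- impute_once(x, model, aff)
  keep <- !res$imputed_mask
  expect_identical(res$values[keep], x[keep])
  expect_true(all(res$values >= 0))

  # D == 0: nothing crosses the threshold, output identical to input
  d0 <- matrix(0, nrow(x), ncol(x))
  res0 <- impute_once(x, d0, aff)
  expect_identical(res0$values, x)
  expect_false(any(res0$imputed_mask))

  # t = 0: every entry is replaced by its regression prediction
  rt <- impute_once(x, d0, aff, impute_config(t = 0))
  expect_true(all(rt$imputed_mask))
})

test_that("duplicate cell populations let dropouts be recovered from the duplicates", {
  set.seed(9)
  profile_a <- runif(15, 1, 3)
  profile_b <- runif(15, 0.2, 2)
  x <- cbind(profile_a, profile_a, profile_a, profile_b, profile_b, profile_b)
  dimnames(x) <- list(paste0("g", 1:15), paste0("c", 1:6))
  d <- matrix(0, 15, 6, dimnames = dimnames(x))
  x_missing <- x
  x_missing[4, 1] <- 0
  d[4, 1] <- 1
  aff <- build_affinity(reduce_dimension(x_missing, 0.95)$z, 2)
  res <- impute_once(x_missing, d, aff, impute_config(lam = 1e-8))
  expect_equal(unname(res$values[4, 1]), unname(profile_a[4]), tolerance = 0.05)
})

test_that("the active set shrinks along the penalty path", {
  set.seed(12)
  design <- abs(matrix(rnorm(200), 25, 8))
  target <- abs(rnorm(25))
  nnz <- sapply(c(0.001, 0.01, 0.1, 1, 10), function(lam) {
    sum(nnlasso(design, target, lam)$b > 1e-10)
  })
  expect_true(all(diff(nnz) <= 0))
})

test_that("coordinate descent agrees with the oracle on many small problems", {
  set.seed(20)
  for (rep in 1:10) {
    m <- sample(10:30, 1)
    p <- sample(3:9, 1)
    design <- matrix(rnorm(m * p), m, p)
    target <- rnorm(m)
    lam <- runif(1, 0, 0.5)
    w <- nnlasso(design, target, lam, tol = 1e-10)
    oracle <- nnlasso_oracle(design, target, lam)
    obj_cd <- nnlasso_objective(design, target, w$b, lam)
    expect_lte(obj_cd, oracle$value + 1e-6 * max(1, abs(oracle$value)))
  }
})
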