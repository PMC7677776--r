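test_that("rmse and pearson_flat match their definitions", {
  a <- matrix(rnorm(60), 6, 10)
  expect_equal(rmse(a, a), 0)
  expect_equal(rmse(a, a + 2), 2, tolerance = 1e-12)
  set.seed(1)
  b <- matrix(rnorm(60), 6, 10)
  expect_equal(rmse(a, b), sqrt(sum((a - b)^2) / 60), tolerance = 1e-12)

  expect_equal(pearson_flat(a, 2 * a + 3), 1, tolerance = 1e-12)
  expect_equal(pearson_flat(a, -a), -1, tolerance = 1e-12)
  # textbook-formula oracle
  av <- as.vector(a); bv <- as.vector(b)
  r_manual <- sum((av - mean(av)) * (bv - mean(bv))) /
    sqrt(sum((av - mean(av))^2) * sum((bv - mean(bv))^2))
  expect_equal(pearson_flat(a, b), r_manual, tolerance = 1e-12)
  expect_error(pearson_flat(matrix(1, 2, 2), matrix(rnorm(4), 2, 2)), "constant")
  expect_error(rmse(a, matrix(0, 2, 2)), "shape")
})

test_that("ari follows the pair-counting formula and its invariances", {
  la <- c("a", "a", "b", "b")
  lb <- c("a", "b", "a", "b")
  # hand enumeration: every pair disagrees between the partitions ->
  # sum_ij C(n_ij,2) = 0; sums over margins are 2 and 2; n = 4
  expected <- (0 - 2 * 2 / 6) / ((2 + 2) / 2 - 2 * 2 / 6)
  expect_equal(ari(la, lb), expected)
  expect_equal(ari(la, la), 1)
  # invariance to label renaming
  expect_equal(ari(la, c("x", "x", "y", "y")), 1)
  set.seed(2)
  l1 <- sample(1:3, 40, replace = TRUE)
  l2 <- sample(1:4, 40, replace = TRUE)
  perm <- sample(40)
  expect_equal(ari(l1, l2), ari(l1[perm], l2[perm]), tolerance = 1e-12)
  expect_error(ari(l1, l2[1:10]), "length")
})

test_that("ari and nmi agree with an independent implementation", {
  set.seed(3)
  for (rep in 1:5) {
    l1 <- sample(1:4, 60, replace = TRUE)
    l2 <- sample(1:3, 60, replace = TRUE)
    expect_equal(ari(l1, l2),
                 igraph::compare(l1, l2, method = "adjusted.rand"),
                 tolerance = 1e-10)
    expect_equal(nmi(l1, l2),
                 igraph::compare(l1, l2, method = "nmi"),
                 tolerance = 1e-10)
  }
  expect_equal(nmi(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
})

test_that("silhouette width reflects cluster geometry", {
  blobs <- two_blob_matrix(gap = 8, noise = 0.05)
  sw <- silhouette_width(blobs$x, blobs$labels)
  expect_gt(sw, 0.9)
  # random labels on one blob: near zero
  set.seed(4)
  one <- two_blob_matrix(gap = 0, noise = 1)$x
  sw0 <- silhouette_width(one, sample(1:2, ncol(one), replace = TRUE))
  expect_lt(abs(sw0), 0.2)
  # cross-assigned labels on two separated pairs: clearly negative
  pairs <- cbind(c(0, 0), c(0.1, 0), c(10, 0), c(10.1, 0))
  rownames(pairs) <- c("d1", "d2")
  colnames(pairs) <- paste0("c", 1:4)
  sw_neg <- silhouette_width(pairs, c(1, 2, 2, 1))
  expect_lt(sw_neg, 0)
  expect_error(silhouette_width(blobs$x, rep(1, ncol(blobs$x))), "2 clusters")
  expect_true(sw >= -1 && sw <= 1)
})

test_that("silhouette agrees with the cluster package oracle", {
  set.seed(5)
  x <- matrix(rnorm(20 * 18), 20, 18)
  labels <- rep(1:3, each = 6)
  mine <- silhouette_width(x, labels)
  ref <- mean(cluster::silhouette(labels, dist(t(x)))[, "sil_width"])
  expect_equal(mine, ref, tolerance = 1e-10)
})

test_that("hierarchical clustering splits separated populations and honors k", {
  blobs <- two_blob_matrix(gap = 6, noise = 0.1)
  cl <- hierarchical_cluster(blobs$x, 2)
  expect_equal(ari(cl, blobs$labels), 1)
  n <- ncol(blobs$x)
  expect_equal(length(unique(hierarchical_cluster(blobs$x, n))), n)
  expect_equal(unique(hierarchical_cluster(blobs$x, 1)), 1L)
  expect_error(hierarchical_cluster(blobs$x, n + 1), "exceed")
})

test_that("evaluate_imputation assembles all metrics consistently", {
  blobs <- two_blob_matrix(gap = 6, noise = 0.1)
  truth <- blobs$x
  imputed <- truth + matrix(rnorm(length(truth), sd = 0.05), nrow(truth))
  rep <- evaluate_imputation(imputed, truth, blobs$labels)
  expect_equal(rep$rmse, rmse(imputed, truth))
  expect_equal(rep$pearson, pearson_flat(imputed, truth))
  expect_equal(rep$ari, 1)
  expect_equal(rep$nmi, 1)
})
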