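# Partition clustering under Pearson dissimilarity: distance contract,
# Lloyd behaviour, and equivalence with the exhaustive oracle.

test_that("pearson_dissimilarity matches hand computation", {
  expect_equal(pearson_dissimilarity(c(1, 5, 3, 4), c(1, 5, 3, 4)), 0)
  expect_equal(pearson_dissimilarity(c(1, 2, 3), -c(1, 2, 3)), 2)
  expect_equal(pearson_dissimilarity(c(1, 2, 3), c(1, 2, 4)),
               1 - 0.9819805, tolerance = 1e-6)
  expect_error(pearson_dissimilarity(c(1, 1, 1), c(1, 2, 3)),
               "zero-variance")
  expect_error(pearson_dissimilarity(c(1, 2), c(3, 4)), "length")
})

test_that("exactly separable groups are recovered with objective 0", {
  up <- c(1, 2, 3, 4, 5)
  x <- rbind(up, up, up, -up, -up, -up)
  rownames(x) <- sprintf("S%d", 1:6)
  res <- kmeans_partition(x, cluster_config(n_restarts = 10, seed = 1))
  expect_equal(res$objective, 0, tolerance = 1e-12)
  expect_equal(unname(res$assignments), c(1, 1, 1, 2, 2, 2))
})

test_that("kmeans with restarts matches the exhaustive oracle", {
  set.seed(99)
  agree <- 0L
  for (i in 1:20) {
    n <- sample(5:10, 1)
    x <- matrix(rnorm(n * 6), n, 6)
    bf <- brute_force_best_partition(x)
    km <- kmeans_partition(x, cluster_config(n_restarts = 100, seed = i))
    agree <- agree + (abs(km$objective - bf$objective) < 1e-8)
  }
  expect_gte(agree, 19)
})

test_that("brute force agrees with an independent objective on tiny inputs", {
  x <- matrix(c(1, 2, 3, 5,
                2, 4, 6, 9,
                9, 5, 3, 1), nrow = 3, byrow = TRUE)
  rownames(x) <- c("a", "b", "c")
  # independent enumeration of the 3 bipartitions via plain stats::cor
  parts <- list(c(1, 2, 2), c(1, 2, 1), c(1, 1, 2))
  objs <- vapply(parts, function(p) objective_by_cor(x, p), numeric(1))
  bf <- brute_force_best_partition(x)
  expect_equal(bf$objective, min(objs), tolerance = 1e-10)
  expect_equal(unname(bf$assignments), parts[[which.min(objs)]])
})

test_that("brute force handles the smallest and largest allowed inputs", {
  x2 <- matrix(c(1, 2, 3, 3, 1, 2), nrow = 2, byrow = TRUE)
  bf <- brute_force_best_partition(x2)
  expect_equal(unname(bf$assignments), c(1, 2))
  expect_equal(bf$objective, 0, tolerance = 1e-12)
  expect_equal(bf$n_evaluated, 1L)
  expect_error(brute_force_best_partition(matrix(rnorm(15 * 4), 15, 4)),
               "n = 15")
})

test_that("reported objective is recomputable from the assignments", {
  set.seed(12)
  x <- matrix(rnorm(12 * 8), 12, 8)
  res <- kmeans_partition(x, cluster_config(n_restarts = 20, seed = 2))
  expect_equal(res$objective, objective_by_cor(x, res$assignments),
               tolerance = 1e-10)
})

test_that("the objective trace is non-increasing under the default config", {
  set.seed(4)
  for (i in 1:10) {
    x <- matrix(rnorm(15 * 10), 15, 10)
    res <- kmeans_partition(x, cluster_config(n_restarts = 5, seed = i))
    expect_false(res$non_monotone)
    expect_true(all(diff(res$objective_trace) <= 1e-12))
  }
})

test_that("the final assignment is a Lloyd fixed point", {
  set.seed(8)
  x <- matrix(rnorm(14 * 6), 14, 6)
  res <- kmeans_partition(x, cluster_config(n_restarts = 30, seed = 3))
  z <- t(apply(x, 1, function(r) (r - mean(r)) / sd(r)))
  for (cl in 1:2) {
    cent <- colMeans(z[res$assignments == cl, , drop = FALSE])
    d_own <- sapply(which(res$assignments == cl), function(i)
      1 - cor(x[i, ], cent))
    other <- colMeans(z[res$assignments == (3 - cl), , drop = FALSE])
    d_other <- sapply(which(res$assignments == cl), function(i)
      1 - cor(x[i, ], other))
    expect_true(all(d_own <= d_other + 1e-10))
  }
})

test_that("results are invariant to profile scaling and shifts", {
  set.seed(6)
  x <- matrix(rnorm(8 * 6), 8, 6)
  base <- kmeans_partition(x, cluster_config(n_restarts = 50, seed = 7))
  y <- x
  y[3, ] <- 4 * y[3, ] + 10  # positive affine change to one profile
  scaled <- kmeans_partition(y, cluster_config(n_restarts = 50, seed = 7))
  expect_equal(base$assignments, scaled$assignments)
  expect_equal(base$objective, scaled$objective, tolerance = 1e-10)
})

test_that("permuting sample order yields the same partition up to labels", {
  set.seed(14)
  x <- matrix(rnorm(8 * 5), 8, 5)
  rownames(x) <- sprintf("S%d", 1:8)
  perm <- sample(8)
  r1 <- kmeans_partition(x, cluster_config(n_restarts = 100, seed = 9))
  r2 <- kmeans_partition(x[perm, ], cluster_config(n_restarts = 100,
                                                   seed = 10))
  a1 <- r1$assignments[rownames(x)]
  a2 <- r2$assignments[rownames(x)]
  same <- identical(unname(a1), unname(a2)) ||
    identical(unname(a1), unname(3L - a2))
  expect_true(same)
  expect_equal(r1$objective, r2$objective, tolerance = 1e-10)
})

test_that("degenerate clustering inputs error informatively", {
  x <- matrix(rnorm(12), 4, 3)
  x[2, ] <- 7
  rownames(x) <- sprintf("S%d", 1:4)
  expect_error(kmeans_partition(x), "S2")
  expect_error(kmeans_partition(matrix(rnorm(4), 2, 2)), "3 genes")
  expect_error(kmeans_partition(matrix(rnorm(3), 1, 3)), "samples")
})

test_that("plusplus initialisation reaches the same optimum on easy data", {
  set.seed(20)
  x <- rbind(matrix(rnorm(20, mean = rep(c(0, 5), each = 10)), 4, 5),
             matrix(rnorm(20, mean = rep(c(5, 0), each = 10)), 4, 5))
  r1 <- kmeans_partition(x, cluster_config(n_restarts = 20, seed = 1))
  r2 <- kmeans_partition(x, cluster_config(n_restarts = 20, seed = 1,
                                           init = "plusplus"))
  expect_equal(r1$objective, r2$objective, tolerance = 1e-8)
})
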