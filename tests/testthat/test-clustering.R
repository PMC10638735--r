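two_clouds <- function(n_per = 10, gap = 20, seed = 42) {
  set.seed(seed)
  rbind(cbind(rnorm(n_per), rnorm(n_per)),
        cbind(rnorm(n_per) + gap, rnorm(n_per)))
}

test_that("z-scoring yields mean-0, SD-1 columns and keeps constants", {
  expect_equal(zscore_features(cbind(c(1, 3), c(5, 9)))$X[, 1],
               c(-1, 1) / sqrt(2))
  set.seed(9)
  raw <- cbind(runif(40, 2, 9), rnorm(40, 5))
  f <- zscore_features(raw)
  expect_lt(max(abs(colMeans(f$X))), 1e-10)
  expect_equal(unname(apply(f$X, 2, sd)), c(1, 1))
  # inverse mapping recovers the raw scale
  back <- sweep(sweep(f$X, 2, f$column_sds, "*"), 2, f$column_means, "+")
  expect_equal(unname(back), unname(raw))
  expect_error(zscore_features(cbind(rep(2, 5), 1:5)), "zero-variance")
})

test_that("k-means separates well-separated clouds exactly", {
  X <- two_clouds()
  fit <- pifm_kmeans(X, 2, n_restarts = 20, seed = 1)
  expect_equal(length(unique(fit$assignments[1:10])), 1)
  expect_equal(length(unique(fit$assignments[11:20])), 1)
  expect_false(fit$assignments[1] == fit$assignments[11])
  within_ss <- sum(sweep(X[1:10, ], 2, colMeans(X[1:10, ]))^2) +
    sum(sweep(X[11:20, ], 2, colMeans(X[11:20, ]))^2)
  expect_equal(fit$wcss, within_ss)
})

test_that("degenerate k are handled: k = 1 is the grand mean, k > n errors", {
  X <- two_clouds(n_per = 5)
  fit1 <- pifm_kmeans(X, 1, n_restarts = 5, seed = 3)
  expect_equal(unname(fit1$centroids[1, ]), unname(colMeans(X)))
  expect_equal(fit1$wcss, sum(sweep(X, 2, colMeans(X))^2))
  expect_error(pifm_kmeans(X, 11, seed = 1), "exceeds")
  expect_error(pifm_kmeans(X, 0, seed = 1), ">= 1")
})

test_that("k-means is deterministic given a seed and restart-monotone", {
  set.seed(14)
  X <- cbind(rnorm(40), rnorm(40))
  a <- pifm_kmeans(X, 3, n_restarts = 10, seed = 99)
  b <- pifm_kmeans(X, 3, n_restarts = 10, seed = 99)
  expect_identical(a$assignments, b$assignments)
  expect_identical(a$wcss, b$wcss)
  # more restarts can only improve (restart set is nested by construction)
  more <- pifm_kmeans(X, 3, n_restarts = 40, seed = 99)
  expect_lte(more$wcss, a$wcss)
  # WCSS is internally consistent with assignments and centroids
  recomputed <- sum((X - more$centroids[more$assignments, ])^2)
  expect_equal(more$wcss, recomputed)
  expect_true(all(tabulate(more$assignments, 3) > 0))
})

test_that("multi-restart k-means attains the exhaustive-partition optimum", {
  set.seed(7)
  hits <- 0L
  for (i in 1:30) {
    n <- sample(5:8, 1)
    k <- sample(2:3, 1)
    X <- cbind(runif(n), runif(n))
    fit <- pifm_kmeans(X, k, n_restarts = 200, seed = i)
    oracle <- best_partition_wcss(X, k)
    expect_gte(fit$wcss, oracle - 1e-9)
    if (fit$wcss <= oracle + 1e-9) hits <- hits + 1L
  }
  expect_equal(hits, 30L) # always, at 200 restarts
})

test_that("clustering is invariant to row order and raw-scale affine maps", {
  X <- two_clouds(n_per = 8, gap = 12, seed = 5)
  fit <- pifm_kmeans(X, 2, n_restarts = 50, seed = 2)
  perm <- sample(nrow(X))
  fit_p <- pifm_kmeans(X[perm, ], 2, n_restarts = 50, seed = 77)
  expect_equal(fit_p$wcss, fit$wcss)
  # same partition up to label names
  expect_equal(table(fit$assignments[perm], fit_p$assignments) > 0,
               diag(2) > 0, ignore_attr = TRUE)
  # z-scoring absorbs affine rescaling of the raw columns
  raw <- cbind(rexp(30, 1 / 5), rnorm(30, 10, 2))
  f1 <- zscore_features(raw)
  f2 <- zscore_features(sweep(sweep(raw, 2, c(3, 0.2), "*"), 2, c(-7, 11), "+"))
  expect_equal(f2$X, f1$X)
  expect_identical(pifm_kmeans(f1$X, 3, 20, seed = 4)$assignments,
                   pifm_kmeans(f2$X, 3, 20, seed = 4)$assignments)
})

test_that("the WCSS curve is monotone, additive, and hits 0 at k = n", {
  set.seed(31)
  X <- cbind(rnorm(12), rnorm(12))
  wc <- wcss_curve(X, k_max = 12, n_restarts = 15, seed = 8)
  expect_true(all(diff(wc$curve$wcss) <= 1e-9))
  expect_equal(wc$curve$wcss[12], 0)
  expect_equal(wc$curve$wcss[1], sum(sweep(X, 2, colMeans(X))^2))
  expect_error(wcss_curve(X, k_max = 1), ">= 2")
  # duplicated dataset doubles every WCSS value (same optimal partitions);
  # both runs need enough restarts to land on the optimum
  wc_ref <- wcss_curve(X, k_max = 6, n_restarts = 200, seed = 8)
  X2 <- rbind(X, X)
  wc2 <- wcss_curve(X2, k_max = 6, n_restarts = 200, seed = 8)
  expect_equal(wc2$curve$wcss[1:6], 2 * wc_ref$curve$wcss[1:6],
               tolerance = 1e-6)
})

test_that("the elbow rule picks the knee and breaks ties to smaller k", {
  curve <- data.frame(k = 1:5, wcss = c(100, 20, 18, 16, 14))
  expect_equal(select_k_elbow(curve), 2)
  expect_equal(elbow_direct(curve$k, curve$wcss), 2) # frozen oracle value
  # exactly linear curve: all distances ~0, tie broken to smallest k
  lin <- data.frame(k = 1:6, wcss = seq(60, 10, by = -10))
  expect_equal(select_k_elbow(lin), 1)
  expect_error(select_k_elbow(data.frame(k = 1:2, wcss = c(2, 1))),
               "3 points")
  # agreement with the direct computation on random convex-ish curves
  set.seed(2)
  for (i in 1:15) {
    wv <- sort(rexp(8, 0.1), decreasing = TRUE)
    expect_equal(select_k_elbow(data.frame(k = 1:8, wcss = wv)),
                 elbow_direct(1:8, wv))
  }
})

test_that("four well-separated blobs give a sharp elbow at k = 4", {
  set.seed(77)
  centres <- rbind(c(0, 0), c(10, 0), c(0, 10), c(10, 10))
  X <- do.call(rbind, lapply(1:4, function(i) {
    cbind(rnorm(15, centres[i, 1], 0.4), rnorm(15, centres[i, 2], 0.4))
  }))
  wc <- wcss_curve(X, k_max = 8, n_restarts = 20, seed = 6)
  expect_equal(select_k_elbow(wc), 4)
})

test_that("independent implementation agrees on the optimal objective", {
  # stats::kmeans as cross-check: same data, many starts, same best WCSS
  set.seed(55)
  X <- rbind(cbind(rnorm(20), rnorm(20)), cbind(rnorm(20, 6), rnorm(20, 6)),
             cbind(rnorm(20, -6), rnorm(20, 6)))
  ours <- pifm_kmeans(X, 3, n_restarts = 50, seed = 10)
  ref <- stats::kmeans(X, 3, nstart = 50, iter.max = 100,
                       algorithm = "Lloyd")
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 1e-8)
})

test_that("cluster numbering follows descending PCSA centroids", {
  set.seed(12)
  X <- rbind(cbind(rnorm(10, 5), rnorm(10, 0)),
             cbind(rnorm(10, 0), rnorm(10, 2)),
             cbind(rnorm(10, -5), rnorm(10, 0)))
  fit <- pifm_kmeans(X, 3, n_restarts = 30, seed = 1)
  expect_true(all(diff(fit$centroids[, 1]) < 0))
  expect_equal(unique(fit$assignments[1:10]), 1L)
  expect_equal(unique(fit$assignments[21:30]), 3L)
})
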