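test_that("kmeans_single handles the degenerate and closed-form cases", {
  set.seed(1)
  X <- matrix(rnorm(20), nrow = 10)
  # k = n: every point its own centroid
  fit <- kmeans_single(X, 10)
  expect_equal(fit$sse, 0)
  expect_length(unique(fit$labels), 10L)
  # k = 1: grand mean, total sum of squared deviations
  fit1 <- kmeans_single(X, 1)
  expect_equal(fit1$sse, sum(sweep(X, 2, colMeans(X))^2), tolerance = 1e-12)
  expect_error(kmeans_single(X, 11), "k_exceeds_n")
  expect_error(kmeans_single(matrix(c(1, NA, 2, 3), 2), 2), "nonfinite_data")
})

test_that("kmeans recovers well-separated pairs with the analytic SSE", {
  pairs <- rbind(c(0, 0), c(1, 0), c(100, 0), c(101, 0))
  set.seed(2)
  fit <- kmeans_restarts(pairs, 2, n_restarts = 10)
  expect_equal(unname(sort(table(fit$labels))[1]), 2L)
  expect_identical(fit$labels[1], fit$labels[2])
  expect_identical(fit$labels[3], fit$labels[4])
  # each pair contributes |a-b|^2 / 2
  expect_equal(fit$sse, 0.5 + 0.5, tolerance = 1e-12)
})

test_that("within-run SSE is non-increasing and the restart minimum is returned", {
  set.seed(3)
  X <- matrix(rnorm(60 * 5), nrow = 60)
  for (i in 1:20) {
    fit <- kmeans_single(X, 4)
    expect_true(all(diff(fit$sse_trace) <= 1e-9))
  }
  fit <- kmeans_restarts(X, 4, n_restarts = 25)
  expect_equal(fit$sse, min(fit$restart_sse))
  expect_equal(fit$sse, label_sse(X, fit$labels), tolerance = 1e-9)
  # n_restarts = 1 equals a single run on the same stream
  set.seed(7); a <- kmeans_restarts(X, 3, n_restarts = 1)
  set.seed(7); b <- kmeans_single(X, 3)
  expect_identical(a$labels, b$labels)
  expect_equal(a$sse, b$sse)
})

test_that("50-restart k-means attains the exhaustive optimum on a 12-point set", {
  set.seed(11)
  X <- matrix(rnorm(12 * 2, sd = 2), nrow = 12)
  best <- brute_best_sse(X, 3)
  fit <- kmeans_restarts(X, 3, n_restarts = 50)
  expect_equal(fit$sse, best, tolerance = 1e-8)
})

test_that("silhouette matches the brute-force double loop and its limits", {
  # tight, far-apart clusters: s near 1
  set.seed(4)
  X <- rbind(matrix(rnorm(10, sd = 0.01), 5),
             matrix(rnorm(10, sd = 0.01) + 50, 5))
  s <- silhouette_values(X, rep(1:2, each = 5))
  expect_true(all(s$s_values > 0.99))

  # a(i) = b(i) gives s(i) = 0 exactly
  Y <- matrix(c(0, 2, 4, 6), ncol = 1)
  Z <- matrix(c(0, 1, 2), ncol = 1)
  sz <- silhouette_values(Z, c(1, 1, 2))
  expect_equal(sz$s_values[2], 0)   # a = 1, b = 1

  # randomized oracle checks, squared and plain distances
  for (rep in 1:10) {
    set.seed(100 + rep)
    n <- sample(6:12, 1)
    Xr <- matrix(rnorm(n * 2), nrow = n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) lab[1] <- setdiff(1:3, lab)[1]
    expect_equal(silhouette_values(Xr, lab)$s_values,
                 brute_silhouette(Xr, lab, squared = TRUE),
                 tolerance = 1e-12)
    expect_equal(silhouette_values(Xr, lab, distance = "euclidean")$s_values,
                 brute_silhouette(Xr, lab, squared = FALSE),
                 tolerance = 1e-12)
  }
  expect_error(silhouette_values(Y, rep(1, 4)), "single_cluster")
})

test_that("plain-Euclidean silhouette agrees with cluster::silhouette", {
  set.seed(9)
  X <- matrix(rnorm(30 * 3), nrow = 30)
  lab <- sample(1:3, 30, replace = TRUE)
  mine <- silhouette_values(X, lab, distance = "euclidean")
  ref <- cluster::silhouette(lab, dist(X))
  expect_equal(mine$s_values, unname(ref[, "sil_width"]), tolerance = 1e-10)
})

test_that("silhouette and SSE are invariant under label permutation", {
  set.seed(10)
  X <- matrix(rnorm(20 * 4), nrow = 20)
  lab <- sample(1:4, 20, replace = TRUE)
  lab[1:4] <- 1:4
  perm <- c(3L, 1L, 4L, 2L)
  s1 <- silhouette_values(X, lab)
  s2 <- silhouette_values(X, perm[lab])
  expect_equal(s1$s_values, s2$s_values, tolerance = 1e-12)
  expect_equal(label_sse(X, lab), label_sse(X, perm[lab]), tolerance = 1e-12)
})

test_that("singleton clusters get s = 0", {
  X <- rbind(c(0, 0), c(0.1, 0), c(10, 10))
  s <- silhouette_values(X, c(1, 1, 2))
  expect_equal(s$s_values[3], 0)
})

test_that("run_ensemble is reproducible and covers the full design", {
  co <- tiny_cohort(seed = 5)
  M <- cohort_matrix(co)
  e1 <- run_ensemble(M, k_range = 2:4, n_restarts = 5, R = 3, master_seed = 31)
  e2 <- run_ensemble(M, k_range = 2:4, n_restarts = 5, R = 3, master_seed = 31)
  expect_identical(e1, e2)
  expect_length(e1$runs[["3"]], 3L)
  expect_length(e1$runs[["3"]][[2]]$kmeans$labels, nrow(M))
  # one repetition only
  e3 <- run_ensemble(M, k_range = 2:3, n_restarts = 3, R = 1, master_seed = 1)
  expect_length(e3$runs[["2"]], 1L)
  expect_error(run_ensemble(M, k_range = 2:20), "bad_k_range")
})

test_that("ensemble JSON serialization round-trips labels, SSE and silhouettes", {
  co <- tiny_cohort(seed = 6)
  M <- cohort_matrix(co)
  ens <- run_ensemble(M, k_range = 2:3, n_restarts = 3, R = 2, master_seed = 2)
  f <- tempfile(fileext = ".json")
  write_ensemble_json(ens, f)
  back <- read_ensemble_json(f)
  expect_identical(back$k_range, ens$k_range)
  for (k in c("2", "3")) for (r in 1:2) {
    expect_identical(back$runs[[k]][[r]]$kmeans$labels,
                     ens$runs[[k]][[r]]$kmeans$labels)
    expect_equal(back$runs[[k]][[r]]$kmeans$sse, ens$runs[[k]][[r]]$kmeans$sse)
    expect_equal(back$runs[[k]][[r]]$silhouette$s_values,
                 ens$runs[[k]][[r]]$silhouette$s_values)
  }
})
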