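test_that("standardization centers, scales, applies and inverts", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 0, 5))
  z <- standardize(x)
  expect_equal(unname(colMeans(z$x)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z$x, 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unstandardize(z$x, z$params), x, tolerance = 1e-10)
  # supplied parameters are applied unchanged: a subsample need not center
  sub <- standardize(x[1:2, ], params = z$params)
  expect_false(isTRUE(all.equal(unname(colMeans(sub$x)), c(0, 0))))
  const <- cbind(a = c(1, 1, 1), b = 1:3)
  expect_error(standardize(const), "zero-variance.*a")
})

test_that("kmeans_lloyd solves the 1-D worked example and k = 1 exactly", {
  x <- matrix(c(0, 1, 10, 11), ncol = 1)
  fit <- kmeans_lloyd(x, 2, n_starts = 10, seed = 1)
  expect_equal(sort(fit$centers[, 1]), c(0.5, 10.5))
  expect_equal(fit$wcss, 1.0)
  expect_equal(fit$cluster[1], fit$cluster[2])
  expect_equal(fit$cluster[3], fit$cluster[4])
  one <- kmeans_lloyd(x, 1, n_starts = 3, seed = 1)
  expect_equal(unname(one$centers[1, 1]), mean(x))
  expect_equal(one$wcss, sum((x - mean(x))^2))
  expect_error(kmeans_lloyd(x, 4, seed = 1), "smaller")
})

test_that("centers are member means and wcss is internally consistent", {
  set.seed(3)
  x <- matrix(rnorm(600), ncol = 3)
  fit <- kmeans_lloyd(x, 4, n_starts = 20, seed = 7)
  for (j in seq_len(4)) {
    expect_equal(unname(fit$centers[j, ]),
                 unname(colMeans(x[fit$cluster == j, , drop = FALSE])),
                 tolerance = 1e-8)
  }
  recomputed <- sum(vapply(seq_len(4), function(j) {
    sum(sweep(x[fit$cluster == j, , drop = FALSE], 2,
              fit$centers[j, ])^2)
  }, numeric(1)))
  expect_equal(fit$wcss, recomputed, tolerance = 1e-8)
  expect_equal(sort(unique(fit$cluster)), 1:4)  # no empty cluster
})

test_that("best-of-starts objective matches the exhaustive optimum (1-D)", {
  set.seed(11)
  instances <- list(
    list(x = rnorm(10), k = 2), list(x = rnorm(12), k = 3),
    list(x = runif(11) * 10, k = 3), list(x = c(rnorm(6), rnorm(6, 8)),
                                          k = 2))
  for (ins in instances) {
    fit <- kmeans_lloyd(matrix(ins$x, ncol = 1), ins$k, n_starts = 50,
                        seed = 123)
    expect_equal(fit$wcss, brute_force_wcss_1d(ins$x, ins$k),
                 tolerance = 1e-8)
  }
})

test_that("solutions agree with the reference Lloyd implementation", {
  # independent cross-check: same objective value as stats::kmeans with
  # many restarts on a moderate instance
  set.seed(5)
  x <- matrix(rnorm(500 * 4), ncol = 4)
  ours <- kmeans_lloyd(x, 3, n_starts = 30, seed = 2)
  ref <- stats::kmeans(x, 3, nstart = 30, algorithm = "Lloyd",
                       iter.max = 300)
  expect_equal(ours$wcss, ref$tot.withinss, tolerance = 0.01)
})

test_that("best-of-starts wcss is non-increasing in the number of starts", {
  set.seed(8)
  x <- matrix(rnorm(200 * 2), ncol = 2)
  w <- vapply(c(1, 5, 20, 50), function(ns) {
    kmeans_lloyd(x, 5, n_starts = ns, seed = 99)$wcss
  }, numeric(1))
  expect_true(all(diff(w) <= 1e-10))
})

test_that("wcss and profiles are invariant to label permutation", {
  set.seed(13)
  b <- make_blobs(50, blob_centers(3, 4, 8), seed = 13)
  fit <- kmeans_lloyd(b$x, 3, n_starts = 10, seed = 4)
  perm <- c(3, 1, 2)
  permuted <- perm[fit$cluster]
  w2 <- sum(vapply(1:3, function(j) {
    xi <- b$x[permuted == j, , drop = FALSE]
    sum(sweep(xi, 2, colMeans(xi))^2)
  }, numeric(1)))
  expect_equal(w2, fit$wcss, tolerance = 1e-8)
})

test_that("silhouette diagnostics peak at the true number of blobs", {
  b <- make_blobs(80, blob_centers(2, 3, 10), seed = 21)
  d <- k_diagnostics(b$x, k_range = 2:4, n_starts = 10, seed = 6)
  expect_equal(d$k[which.max(d$silhouette)], 2)
  expect_true(all(diff(d$wcss) <= 1e-8))  # elbow curve non-increasing
  skip_if_not_installed("cluster")
  # cross-check mean silhouette against the reference implementation
  fit <- kmeans_lloyd(b$x, 3, n_starts = 10, seed = 8)
  sil <- cluster::silhouette(fit$cluster, dist(b$x))
  ours <- cmrpheno:::mean_silhouette(b$x, fit$cluster, 3)
  expect_equal(ours, mean(sil[, "sil_width"]), tolerance = 1e-10)
})

test_that("profiles report medians, percentile positions and shares", {
  co <- generate_cohort(cohort_config(n_per_round = 400, seed = 37))
  cl <- clean_cohort(co$records)
  feats <- assemble_feature_matrix(cl$records)
  # cluster = whole sample: every percentile position is ~50
  prof1 <- cluster_profile(feats, rep(1L, nrow(feats)))
  expect_true(all(abs(prof1$position - 50) < 2))
  expect_equal(prof1$share, 1)
  fit <- kmeans_lloyd(standardize(feats)$x, 6, n_starts = 10, seed = 9)
  prof <- cluster_profile(feats, fit$cluster)
  expect_equal(sum(prof$share), 1, tolerance = 1e-12)
  expect_true(all(prof$position >= 0 & prof$position <= 100))
  for (j in seq_len(6)) {
    expect_equal(unname(prof$medians[j, "bmi"]),
                 median(feats[fit$cluster == j, "bmi"]))
  }
  expect_error(cluster_profile(feats, c(rep(1L, nrow(feats) - 1), 3L)),
               "empty")
})

test_that("naming rules fire on constructed archetypal clusters", {
  set.seed(41)
  n <- 2000
  base <- list(height = rnorm(n, 163, 6), bmi = rnorm(n, 27, 4),
               whtr = rnorm(n, 0.55, 0.06), sbp = rnorm(n, 120, 15),
               dbp = rnorm(n, 72, 9), rhr = rnorm(n, 72, 9),
               hdl = rnorm(n, 1.5, 0.3), non_hdl = rnorm(n, 3.5, 0.8),
               hba1c = rnorm(n, 5.5, 0.5), egfr = rnorm(n, 95, 15))
  feats <- do.call(cbind, base)
  cl <- rep(1L, n)
  cl[1:100] <- 2L
  feats[1:100, "hba1c"] <- rnorm(100, 10, 0.4)  # far above P95
  prof <- cluster_profile(feats, cl)
  expect_equal(prof$name[2], "severe hyperglycemia")
  # severe obesity rule
  cl2 <- rep(1L, n); cl2[101:200] <- 2L
  f2 <- feats; f2[101:200, "bmi"] <- rnorm(100, 45, 1)
  expect_equal(cluster_profile(f2, cl2)$name[2], "severe obesity")
  # low DBP low eGFR rule
  cl3 <- rep(1L, n); cl3[201:300] <- 2L
  f3 <- feats
  f3[201:300, "dbp"] <- rnorm(100, 55, 2)
  f3[201:300, "egfr"] <- rnorm(100, 55, 4)
  expect_equal(cluster_profile(f3, cl3)$name[2], "low DBP, low eGFR")
})

test_that("cluster matching recovers identity, permutations and the
           exhaustive optimum", {
  a <- c(1, 1, 2, 2, 3, 3)
  m <- match_clusters(a, a)
  expect_equal(m$matching$cluster_b, 1:3)
  expect_true(all(m$matching$jaccard == 1))
  perm <- c(2, 3, 1)
  m2 <- match_clusters(a, perm[a])
  expect_equal(m2$matching$cluster_b[m2$matching$cluster_a], perm)
  expect_true(all(m2$matching$jaccard == 1))
  # 3 x 2: compare with brute-force enumeration of all injections
  b3 <- c(1, 2, 2, 1, 1, 2)
  m3 <- match_clusters(a, b3)
  jac <- m3$jaccard
  # enumerate which two of the three reference clusters get matched
  best <- -Inf
  for (rows in list(c(1, 2), c(1, 3), c(2, 3))) {
    for (cols in list(c(1, 2), c(2, 1))) {
      best <- max(best, jac[rows[1], cols[1]] + jac[rows[2], cols[2]])
    }
  }
  expect_equal(sum(m3$matching$jaccard), best, tolerance = 1e-12)
  expect_length(m3$unmatched_a, 1)
  expect_error(match_clusters(a, b3, ids_a = 1:6, ids_b = 7:12), "shared")
})

test_that("cluster flow conserves counts and localizes a split", {
  b <- make_blobs(100, blob_centers(2, 2, 12), seed = 31)
  k2 <- kmeans_lloyd(b$x, 2, n_starts = 10, seed = 1)
  k3 <- kmeans_lloyd(b$x, 3, n_starts = 10, seed = 2)
  fl <- cluster_flow(k2$cluster, k3$cluster)
  expect_equal(sum(fl), 200)
  expect_equal(unname(rowSums(fl)), unname(tabulate(k2$cluster, 2)))
  # one blob splits: exactly one row spreads over two cells
  expect_equal(sum(fl > 0), 4 - 1)
  one <- cluster_flow(rep(1L, 200), k3$cluster)
  expect_equal(unname(one[1, ]), unname(tabulate(k3$cluster, 3)))
})

test_that("intra/inter distances match brute force and order correctly", {
  set.seed(17)
  x <- matrix(rnorm(200 * 3), ncol = 3)
  cl <- sample(1:3, 200, replace = TRUE)
  fast <- intra_inter_distances(x, cl)
  expect_equal(fast, brute_force_pair_means(x, cl), tolerance = 1e-8)
  # two singleton 1-D clusters
  y <- matrix(c(0, 1), ncol = 1)
  expect_warning(dd <- intra_inter_distances(y, c(1L, 2L)), "singleton")
  expect_equal(dd, matrix(c(0, 1, 1, 0), 2), tolerance = 1e-12)
  # separated blobs: diagonal below every off-diagonal in its row
  b <- make_blobs(60, blob_centers(3, 4, 8), seed = 3)
  fit <- kmeans_lloyd(b$x, 3, n_starts = 10, seed = 4)
  m <- intra_inter_distances(b$x, fit$cluster)
  for (j in 1:3) expect_true(all(m[j, j] < m[j, -j]))
})
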