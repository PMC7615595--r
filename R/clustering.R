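#' Center and scale a feature matrix
#'
#' Subtracts the per-feature mean and divides by the per-feature standard
#' deviation. When `params` is supplied (e.g. full-sample parameters for a
#' subsample), it is applied unchanged instead of being re-estimated.
#'
#' @param x Numeric matrix, no missing entries.
#' @param params Optional list with `mean` and `sd` vectors.
#' @return List with `x` (standardized matrix) and `params`
#'   (`mean`, `sd`, `n`).
#' @export
standardize <- function(x, params = NULL) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("standardize requires a complete matrix")
  if (is.null(params)) {
    if (nrow(x) < 2) stop("need at least two rows to estimate parameters")
    mu <- colMeans(x)
    sdev <- apply(x, 2, sd)
    zero <- sdev == 0
    if (any(zero)) {
      nm <- colnames(x) %||% as.character(which(zero))
      stop("zero-variance feature(s): ",
           paste(nm[zero], collapse = ", "))
    }
    params <- list(mean = mu, sd = sdev, n = nrow(x))
  }
  z <- sweep(sweep(x, 2, params$mean, "-"), 2, params$sd, "/")
  list(x = z, params = params)
}

#' Invert a standardization
#'
#' @param z Standardized matrix.
#' @param params Parameters from [standardize()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(z, params) {
  sweep(sweep(as.matrix(z), 2, params$sd, "*"), 2, params$mean, "+")
}

#' Lloyd k-means with repeated random starts
#'
#' Partitions the rows of a (standardized) matrix into `k` clusters by
#' Lloyd's algorithm under squared Euclidean distance, taking the
#' lowest-objective solution over `n_starts` random initializations. Each
#' start seeds its centers at `k` distinct data points (or by the
#' k-means++ rule when `init = "kmeans++"`). Iteration stops when
#' assignments are unchanged or the largest center shift falls below
#' `tol`; an empty cluster is reseeded at the point farthest from its own
#' center so `k` stays fixed. Assignment ties go to the lowest cluster
#' index. Deterministic given `seed`, with a nested per-start seed stream
#' so the best objective is non-increasing in `n_starts`.
#'
#' @param x Numeric matrix (rows = participants).
#' @param k Number of clusters, `1 <= k < nrow(x)`.
#' @param n_starts Number of random starts (default 50).
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @param max_iter,tol Convergence controls.
#' @param init `"random"` or `"kmeans++"`.
#' @return Object of class `phenotype_km`: `k`, `centers` (k x p),
#'   `cluster` (1..k per row), `wcss`, `n_starts`, `seed`, `iterations`,
#'   `converged`, `start_wcss`.
#' @export
kmeans_lloyd <- function(x, k, n_starts = 50, seed = NULL, max_iter = 300,
                         tol = 1e-6, init = c("random", "kmeans++")) {
  init <- match.arg(init)
  x <- as.matrix(x)
  n <- nrow(x)
  if (k < 1) stop("k must be at least 1")
  if (k >= n && k > 1) stop("k must be smaller than the number of rows")
  start_seeds <- if (is.null(seed)) {
    floor(runif(n_starts) * 2147483646) + 1
  } else {
    local_seed(seed, floor(runif(n_starts) * 2147483646) + 1)
  }
  best <- NULL
  start_wcss <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    centers0 <- local_seed(start_seeds[s], init_centers(x, k, init))
    fit <- cpp_lloyd(x, centers0, max_iter, tol)
    start_wcss[s] <- fit$wcss
    if (is.null(best) || fit$wcss < best$wcss - 1e-12) best <- fit
  }
  colnames(best$centers) <- colnames(x)
  structure(list(k = k, centers = best$centers, cluster = best$cluster,
                 wcss = best$wcss, n_starts = n_starts, seed = seed,
                 iterations = best$iterations, converged = best$converged,
                 start_wcss = start_wcss),
            class = "phenotype_km")
}

init_centers <- function(x, k, init) {
  n <- nrow(x)
  if (init == "random" || k == 1) {
    return(x[sample.int(n, k), , drop = FALSE])
  }
  # k-means++: subsequent centers drawn with probability proportional to
  # squared distance from the nearest existing center
  idx <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[idx, ], "-")^2)
  for (j in 2:k) {
    nxt <- sample.int(n, 1, prob = pmax(d2, 1e-300))
    idx <- c(idx, nxt)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[nxt, ], "-")^2))
  }
  x[idx, , drop = FALSE]
}

#' @export
print.phenotype_km <- function(x, ...) {
  cat("k-means phenotype model: k =", x$k, ", n =", length(x$cluster),
      ", wcss =", format(x$wcss), "\n")
  cat("best of", x$n_starts, "starts; cluster sizes:\n")
  print(tabulate(x$cluster, x$k))
  invisible(x)
}

#' Assign points to the nearest of a set of centers
#'
#' @param x Matrix of points.
#' @param centers Matrix of centers (same number of columns).
#' @return Integer cluster index per row (ties to the lowest index).
#' @export
assign_to_centers <- function(x, centers) {
  x <- as.matrix(x); centers <- as.matrix(centers)
  d2 <- outer(rowSums(x^2), rep(1, nrow(centers))) -
    2 * x %*% t(centers) +
    outer(rep(1, nrow(x)), rowSums(centers^2))
  max.col(-d2, ties.method = "first")
}

#' Elbow and silhouette diagnostics over a range of k
#'
#' Fits [kmeans_lloyd()] for each `k` and records the total within-cluster
#' sum of squares (elbow curve) and the mean silhouette width, where the
#' silhouette of point i is `(b - a) / max(a, b)` with `a` its mean
#' distance to its own cluster and `b` the smallest mean distance to
#' another cluster; a point in a singleton cluster contributes 0. For
#' samples larger than `silhouette_max_n` the silhouette is evaluated on a
#' random subsample of that size (the all-pairs computation is quadratic).
#'
#' @param x Standardized feature matrix.
#' @param k_range Integer vector of cluster counts (default 5:12).
#' @param n_starts,seed,max_iter,tol Passed to [kmeans_lloyd()].
#' @param silhouette_max_n Subsample cap for the silhouette computation.
#' @return Data frame with columns `k`, `wcss`, `silhouette`.
#' @export
k_diagnostics <- function(x, k_range = 5:12, n_starts = 50, seed = NULL,
                          max_iter = 300, tol = 1e-6,
                          silhouette_max_n = 5000) {
  x <- as.matrix(x)
  seeds <- spawn_seeds(seed %||% floor(runif(1) * 2^30), length(k_range) + 1)
  sil_rows <- if (nrow(x) > silhouette_max_n) {
    local_seed(seeds[length(seeds)],
               sort(sample.int(nrow(x), silhouette_max_n)))
  } else seq_len(nrow(x))
  out <- data.frame(k = k_range, wcss = NA_real_, silhouette = NA_real_)
  for (i in seq_along(k_range)) {
    fit <- kmeans_lloyd(x, k_range[i], n_starts = n_starts,
                        seed = seeds[i], max_iter = max_iter, tol = tol)
    out$wcss[i] <- fit$wcss
    out$silhouette[i] <- mean_silhouette(x[sil_rows, , drop = FALSE],
                                         fit$cluster[sil_rows], fit$k)
  }
  out
}

mean_silhouette <- function(x, cluster, k) {
  md <- cpp_mean_dist_to_clusters(x, as.integer(cluster), as.integer(k))
  s <- vapply(seq_len(nrow(x)), function(i) {
    a <- md[i, cluster[i]]
    if (is.na(a)) return(0)  # singleton cluster convention
    b <- min(md[i, -cluster[i]], na.rm = TRUE)
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Default cluster-naming thresholds
#'
#' Percentile-position thresholds (0-100 scale) for the deterministic
#' naming rules used by [cluster_profile()]; see that function. The
#' obesity severity threshold (`severe_bmi`) is lower than the glycemia
#' one (`severe`) because a severe-obesity cluster typically holds around
#' a tenth of the sample, which caps its median near the 95th percentile.
#'
#' @return Named list of thresholds.
#' @export
default_naming_rules <- function() {
  list(severe = 95, severe_bmi = 90, high = 90, low = 25, low_risk_max = 40)
}

#' Profile and name clusters
#'
#' Summarizes each cluster by the per-feature median on the natural scale,
#' the percentile position of that median within the whole-sample empirical
#' distribution (0-100), and the cluster's share of the sample. Positions
#' are also expressed risk-oriented: reversed for height, HDL and eGFR,
#' for which lower values indicate higher risk. Names are assigned by
#' priority-ordered rules on the positions of the cluster medians (the
#' first matching rule wins): severe hyperglycemia (HbA1c at or above the
#' 95th position), severe obesity (BMI >= 90), high blood pressure
#' (SBP >= 90), high cholesterol (non-HDL >= 90), high heart rate
#' (RHR >= 90), low DBP low eGFR (both <= 25), low risk (every
#' risk-oriented position <= 40), low BMI high HDL (BMI <= 25 and HDL
#' risk-position <= 25), otherwise mid risk, split into tall/short by the cluster median
#' height against the sample median.
#'
#' @param features Natural-scale feature matrix or data frame holding the
#'   ten risk factors.
#' @param cluster Integer cluster assignment per row.
#' @param rules Thresholds from [default_naming_rules()].
#' @return Object of class `phenotype_profile`: list with `medians`,
#'   `position`, `risk_position` (k x 10 matrices), `share`, `name`.
#' @export
cluster_profile <- function(features, cluster, rules = default_naming_rules()) {
  feats <- risk_factors()
  if (is.data.frame(features)) features <- as.matrix(features[, feats])
  if (is.null(colnames(features))) colnames(features) <- feats
  k <- max(cluster)
  sizes <- tabulate(cluster, k)
  if (any(sizes == 0)) stop("empty cluster in profile")
  ecdfs <- lapply(feats, function(v) ecdf(features[, v]))
  names(ecdfs) <- feats
  med <- t(vapply(seq_len(k), function(j) {
    apply(features[cluster == j, , drop = FALSE], 2, median)
  }, numeric(length(feats))))
  pos <- med
  for (v in feats) pos[, v] <- 100 * ecdfs[[v]](med[, v])
  rp <- pos
  for (v in reversed_risk_factors()) rp[, v] <- 100 - pos[, v]
  sample_med_height <- median(features[, "height"])
  name <- vapply(seq_len(k), function(j) {
    p <- pos[j, ]; r <- rp[j, ]
    if (p["hba1c"] >= rules$severe) "severe hyperglycemia"
    else if (p["bmi"] >= rules$severe_bmi) "severe obesity"
    else if (p["sbp"] >= rules$high) "high blood pressure"
    else if (p["non_hdl"] >= rules$high) "high cholesterol"
    else if (p["rhr"] >= rules$high) "high heart rate"
    else if (p["dbp"] <= rules$low && p["egfr"] <= rules$low)
      "low DBP, low eGFR"
    else if (all(r <= rules$low_risk_max)) "low risk"
    else if (p["bmi"] <= rules$low && r["hdl"] <= rules$low)
      "low BMI, high HDL"
    else if (med[j, "height"] > sample_med_height) "mid risk tall"
    else "mid risk short"
  }, character(1))
  structure(list(medians = med, position = pos, risk_position = rp,
                 share = sizes / length(cluster),
                 name = make.unique(name, sep = " #")),
            class = "phenotype_profile")
}

#' @export
print.phenotype_profile <- function(x, ...) {
  df <- data.frame(name = x$name, share = round(x$share, 3),
                   round(x$medians, 2))
  print(df, row.names = FALSE)
  invisible(x)
}

# Maximum-sum one-to-one assignment of rows to columns of `mat`
# (rows <= cols), by exact dynamic programming over column subsets.
assign_rectangular <- function(mat) {
  nr <- nrow(mat); nc <- ncol(mat)
  stopifnot(nr <= nc, nc <= 24)
  nmask <- bitwShiftL(1L, nc)
  dp <- matrix(-Inf, nr + 1, nmask)
  dp[1, 1] <- 0
  choice <- matrix(NA_integer_, nr + 1, nmask)
  for (r in seq_len(nr)) {
    for (mask in 0:(nmask - 1)) {
      base <- dp[r, mask + 1]
      if (!is.finite(base)) next
      for (c in seq_len(nc)) {
        bit <- bitwShiftL(1L, c - 1L)
        if (bitwAnd(mask, bit) > 0) next
        nm <- bitwOr(mask, bit)
        val <- base + mat[r, c]
        if (val > dp[r + 1, nm + 1]) {
          dp[r + 1, nm + 1] <- val
          choice[r + 1, nm + 1] <- c
        }
      }
    }
  }
  best_mask <- which.max(dp[nr + 1, ]) - 1L
  cols <- integer(nr)
  mask <- best_mask
  for (r in rev(seq_len(nr))) {
    c <- choice[r + 1, mask + 1]
    cols[r] <- c
    mask <- bitwAnd(mask, bitwNot(bitwShiftL(1L, c - 1L)))
  }
  cols
}

#' Match two clusterings by Jaccard similarity
#'
#' Computes the pairwise Jaccard matrix between the clusters of two
#' assignments over their shared ids and finds the one-to-one matching
#' that maximizes the total Jaccard similarity (exact rectangular
#' assignment). Clusters of the larger solution left unmatched are
#' reported.
#'
#' @param assignments_a,assignments_b Integer cluster vectors.
#' @param ids_a,ids_b Ids aligned with the assignments; defaults assume
#'   both assignments cover the same records in the same order.
#' @return List with `jaccard` (k_a x k_b matrix), `matching` (data frame
#'   `cluster_a`, `cluster_b`, `jaccard`), `unmatched_a`, `unmatched_b`.
#' @export
match_clusters <- function(assignments_a, assignments_b,
                           ids_a = NULL, ids_b = NULL) {
  ids_a <- ids_a %||% seq_along(assignments_a)
  ids_b <- ids_b %||% seq_along(assignments_b)
  shared <- intersect(ids_a, ids_b)
  if (length(shared) == 0) stop("no shared ids between assignments")
  a <- assignments_a[match(shared, ids_a)]
  b <- assignments_b[match(shared, ids_b)]
  ka <- max(a); kb <- max(b)
  inter <- as.matrix(table(factor(a, 1:ka), factor(b, 1:kb)))
  na <- tabulate(a, ka); nb <- tabulate(b, kb)
  uni <- outer(na, nb, "+") - inter
  jac <- ifelse(uni > 0, inter / uni, 0)
  dimnames(jac) <- NULL
  if (ka <= kb) {
    cols <- assign_rectangular(jac)
    matching <- data.frame(cluster_a = seq_len(ka), cluster_b = cols,
                           jaccard = jac[cbind(seq_len(ka), cols)])
  } else {
    rows <- assign_rectangular(t(jac))
    matching <- data.frame(cluster_a = rows, cluster_b = seq_len(kb),
                           jaccard = jac[cbind(rows, seq_len(kb))])
  }
  list(jaccard = jac, matching = matching,
       unmatched_a = setdiff(seq_len(ka), matching$cluster_a),
       unmatched_b = setdiff(seq_len(kb), matching$cluster_b))
}

#' Flow of participants between two clusterings
#'
#' Contingency table of joint membership, e.g. between the solutions at
#' `k` and `k + 1` clusters, showing how clusters split and merge.
#'
#' @param assignments_a,assignments_b Cluster vectors over the same
#'   participants in the same order.
#' @return Integer matrix: rows = clusters of `a`, columns = clusters of
#'   `b`; row sums equal the source cluster sizes.
#' @export
cluster_flow <- function(assignments_a, assignments_b) {
  if (length(assignments_a) != length(assignments_b)) {
    stop("assignments must cover the same participants")
  }
  as.matrix(table(factor(assignments_a, 1:max(assignments_a)),
                  factor(assignments_b, 1:max(assignments_b))))
}

#' Average intra- and inter-cluster distances
#'
#' The diagonal holds, for each cluster, the average Euclidean distance
#' between all pairs of points inside it; off-diagonal entries hold the
#' average distance between all pairs of points taken one from each
#' cluster. Computed in a single exact pass (no distance matrix is
#' materialized). A singleton cluster has intra-distance 0, with a
#' warning.
#'
#' @param x Standardized feature matrix.
#' @param cluster Integer assignment per row.
#' @return k x k symmetric matrix.
#' @export
intra_inter_distances <- function(x, cluster) {
  x <- as.matrix(x)
  k <- max(cluster)
  sizes <- tabulate(cluster, k)
  if (any(sizes == 0)) stop("empty cluster")
  if (any(sizes == 1)) {
    warning("singleton cluster(s): intra-cluster distance reported as 0")
  }
  cpp_pair_dist_means(x, as.integer(cluster), as.integer(k))
}
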