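# Gaussian blob mixture: k well-separated spherical clusters in `dim`
# dimensions, centers `sep` apart along coordinate axes, unit within-blob SD.
make_blobs <- function(n_per, centers, sd = 1, seed = 1) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  set.seed(seed)
  x <- do.call(rbind, lapply(seq_len(k), function(j) {
    matrix(rnorm(n_per * ncol(centers), sd = sd), n_per) +
      matrix(centers[j, ], n_per, ncol(centers), byrow = TRUE)
  }))
  list(x = x, labels = rep(seq_len(k), each = n_per))
}

# Axis-aligned separated centers for k blobs in `dim` dimensions.
blob_centers <- function(k, dim, sep) {
  m <- matrix(0, k, dim)
  for (j in seq_len(k)) m[j, ((j - 1) %% dim) + 1] <- sep * ((j + 1) %/% 2)
  m * rep(c(1, -1), length.out = k)
}

# Global minimum wcss over all partitions of 1-D data into exactly k
# nonempty clusters, by exhaustive (vectorized) enumeration of assignments.
brute_force_wcss_1d <- function(x, k) {
  n <- length(x)
  stopifnot(n <= 12, k <= 3)
  a <- as.matrix(expand.grid(rep(list(seq_len(k)), n)))
  total <- numeric(nrow(a))
  nonempty <- rep(TRUE, nrow(a))
  for (j in seq_len(k)) {
    m <- (a == j) * 1
    cnt <- rowSums(m)
    nonempty <- nonempty & cnt > 0
    sx <- as.vector(m %*% x)
    sxx <- as.vector(m %*% x^2)
    total <- total + ifelse(cnt > 0, sxx - sx^2 / pmax(cnt, 1), 0)
  }
  min(total[nonempty])
}

# Brute-force average pairwise Euclidean distances within/between clusters.
brute_force_pair_means <- function(x, cluster) {
  k <- max(cluster)
  d <- as.matrix(dist(x))
  out <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in a:k) {
      ia <- which(cluster == a); ib <- which(cluster == b)
      if (a == b) {
        if (length(ia) < 2) { out[a, a] <- 0; next }
        pair <- d[ia, ia]
        out[a, a] <- mean(pair[upper.tri(pair)])
      } else {
        out[a, b] <- out[b, a] <- mean(d[ia, ib])
      }
    }
  }
  out
}

# Tiny four-archetype library with >= 6 within-SD separation on several
# features, for parameter-recovery checks.
separated_archetypes <- function(sex = "female") {
  sds <- c(height = 2, bmi = 1, whtr = 0.02, sbp = 3, dbp = 2, rhr = 3,
           hdl = 0.1, non_hdl = 0.3, hba1c = 0.2, egfr = 4)
  mk <- function(name, height, bmi, whtr, sbp, dbp, rhr, hdl, non_hdl,
                 hba1c, egfr, w, trend = 0, age = 45) {
    archetype_spec(name,
                   c(height = height, bmi = bmi, whtr = whtr, sbp = sbp,
                     dbp = dbp, rhr = rhr, hdl = hdl, non_hdl = non_hdl,
                     hba1c = hba1c, egfr = egfr),
                   sd = sds, base_weight = w, weight_trend = trend,
                   age_mean = age, age_sd = 10)
  }
  list(
    mk("low_risk", 163, 22, 0.44, 104, 64, 66, 1.8, 2.6, 5.0, 112, 0.3),
    mk("severe_obesity", 163, 42, 0.74, 122, 74, 76, 1.2, 3.6, 5.6, 95,
       0.25),
    mk("high_blood_pressure", 160, 28, 0.56, 165, 90, 72, 1.4, 3.8, 5.6,
       80, 0.25, age = 60),
    mk("severe_hyperglycemia", 161, 30, 0.60, 126, 74, 80, 1.1, 4.2, 10.2,
       92, 0.2, age = 55))
}
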