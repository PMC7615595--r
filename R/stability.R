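#' Jaccard index of two id sets
#'
#' `|A intersect B| / |A union B|`, ranging from 0 (no overlap) to 1
#' (identical sets). Defined as 0 when both sets are empty.
#'
#' @param set_a,set_b Vectors of ids (duplicates ignored).
#' @return Scalar in `[0, 1]`.
#' @export
jaccard_index <- function(set_a, set_b) {
  u <- length(union(set_a, set_b))
  if (u == 0) return(0)
  length(intersect(set_a, set_b)) / u
}

#' Bootstrap cluster stability by half-sample Jaccard
#'
#' For each of `B` replicates, draws `floor(fraction * n)` rows without
#' replacement, re-clusters them with the same `k`, and records, for every
#' reference cluster restricted to the subsample, its Jaccard index with
#' the best-matching replicate cluster — either the maximum over replicate
#' clusters (default, standard clusterwise-stability practice) or under a
#' global one-to-one assignment. The per-cluster average over replicates
#' is the stability index.
#'
#' Replicates reuse the coordinate system of the reference fit (the
#' subsample is a view of the same standardized space); per-replicate
#' seeds are spawned from `seed` so runs are reproducible and replicates
#' independent.
#'
#' @param x Standardized matrix the reference model was fitted on.
#' @param model Reference [kmeans_lloyd()] fit on `x`.
#' @param B Number of subsample replicates (1,000 for a full analysis).
#' @param fraction Subsample proportion (default 0.5).
#' @param n_starts Random starts for each replicate refit (default 10).
#' @param seed Master seed.
#' @param match `"max"` or `"assignment"`.
#' @return Object of class `stability_report`: `average` (per-cluster mean
#'   Jaccard), `replicates` (B x k matrix), `B`, `fraction`, `seed`.
#' @export
subsample_stability <- function(x, model, B = 1000, fraction = 0.5,
                                n_starts = 10, seed = NULL,
                                match = c("max", "assignment")) {
  match <- match.arg(match)
  x <- as.matrix(x)
  n <- nrow(x)
  m <- floor(fraction * n)
  if (m < model$k) stop("subsample smaller than the number of clusters")
  seed <- seed %||% floor(runif(1) * 2^30)
  rep_seeds <- spawn_seeds(seed, 2L * B)
  ref_sets <- split(seq_len(n), model$cluster)
  jac <- matrix(NA_real_, B, model$k)
  for (b in seq_len(B)) {
    idx <- local_seed(rep_seeds[b], sample.int(n, m))
    fit <- kmeans_lloyd(x[idx, , drop = FALSE], model$k,
                        n_starts = n_starts, seed = rep_seeds[B + b])
    sub_sets <- split(idx, fit$cluster)
    for (j in seq_len(model$k)) {
      ref_j <- intersect(ref_sets[[j]], idx)
      jac[b, j] <- max(vapply(sub_sets, jaccard_index, numeric(1),
                              set_b = ref_j))
    }
    if (match == "assignment") {
      jm <- match_clusters(model$cluster[idx], fit$cluster,
                           ids_a = idx, ids_b = idx)
      jac[b, jm$matching$cluster_a] <- jm$matching$jaccard
    }
  }
  structure(list(average = colMeans(jac), replicates = jac, B = B,
                 fraction = fraction, k = model$k, seed = seed,
                 match = match),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Cluster stability over", x$B, "subsamples of",
      paste0(round(100 * x$fraction), "%"), "\n")
  cat("Per-cluster average Jaccard:\n")
  print(round(x$average, 3))
  invisible(x)
}

#' Stability under an uncorrelated Gaussian null
#'
#' Calibrates the stability index on data with no cluster structure:
#' `n` points drawn iid from a `dim`-dimensional uncorrelated standard
#' normal are clustered with `k` groups and assessed with
#' [subsample_stability()]. Clusters carved out of a featureless Gaussian
#' are highly unstable, so their average Jaccard indices stay low; real
#' phenotype structure should clear this bar by a wide margin.
#'
#' @param n Number of null points (the headline calibration uses 30,180,
#'   matching a pooled single-sex analysis sample).
#' @param dim Dimension (default 10, one per risk factor).
#' @param k Clusters to force (default 10).
#' @param B Subsample replicates.
#' @param seed Master seed.
#' @param n_starts_ref Starts for the reference fit.
#' @param n_starts_sub Starts per replicate refit.
#' @param fraction Subsample proportion.
#' @return A `stability_report` (see [subsample_stability()]).
#' @export
null_calibration <- function(n = 30180, dim = 10, k = 10, B = 50,
                             seed = NULL, n_starts_ref = 10,
                             n_starts_sub = 10, fraction = 0.5) {
  if (n <= k) stop("n must exceed k")
  seed <- seed %||% floor(runif(1) * 2^30)
  seeds <- spawn_seeds(seed, 3)
  x <- generate_null_matrix(n, dim, seed = seeds[1])
  model <- kmeans_lloyd(x, k, n_starts = n_starts_ref, seed = seeds[2])
  subsample_stability(x, model, B = B, fraction = fraction,
                      n_starts = n_starts_sub, seed = seeds[3])
}

#' Subperiod consistency of the phenotype solution
#'
#' Re-runs clustering within each calendar subperiod (with its own
#' standardization), profiles the period clusters, and matches them to a
#' pooled reference profile by Euclidean distance over risk-factor
#' percentile positions under an exact one-to-one assignment. A reference
#' phenotype whose best match is farther than `max_distance` is reported
#' as unmatched in that period.
#'
#' @param records Analysis-set data frame (cleaned, derived, one sex).
#' @param reference_profile A [cluster_profile()] of the pooled solution.
#' @param periods List of numeric `c(start, end)` mid-year ranges
#'   (inclusive).
#' @param k Number of clusters.
#' @param n_starts,seed Clustering controls.
#' @param min_per_cluster Minimum records per cluster for a period to be
#'   analyzed (periods below `min_per_cluster * k` are skipped).
#' @param max_distance Matching distance cutoff on the percentile-position
#'   scale.
#' @return List per period: `profile`, `matching` (data frame of reference
#'   cluster, period cluster, distance, matched names), `skipped`.
#' @export
subperiod_consistency <- function(records, reference_profile, periods, k,
                                  n_starts = 50, seed = NULL,
                                  min_per_cluster = 10,
                                  max_distance = 60) {
  seeds <- spawn_seeds(seed %||% floor(runif(1) * 2^30), length(periods))
  out <- list()
  for (p in seq_along(periods)) {
    pr <- periods[[p]]
    label <- paste0(pr[1], "-", pr[2])
    sub <- records[records$mid_year >= pr[1] & records$mid_year <= pr[2], ]
    if (nrow(sub) < min_per_cluster * k) {
      warning("period ", label, " below minimum size; skipped")
      out[[label]] <- list(skipped = TRUE)
      next
    }
    feats <- assemble_feature_matrix(sub)
    z <- standardize(feats)
    fit <- kmeans_lloyd(z$x, k, n_starts = n_starts, seed = seeds[p])
    prof <- cluster_profile(feats, fit$cluster)
    d <- outer(seq_len(nrow(reference_profile$position)),
               seq_len(nrow(prof$position)),
               Vectorize(function(i, j) {
                 sqrt(sum((reference_profile$position[i, ] -
                             prof$position[j, ])^2))
               }))
    cols <- assign_rectangular(-d)
    matching <- data.frame(
      reference = seq_len(nrow(d)),
      period_cluster = cols,
      distance = d[cbind(seq_len(nrow(d)), cols)],
      reference_name = reference_profile$name,
      period_name = prof$name[cols])
    matching$matched <- matching$distance <= max_distance
    out[[label]] <- list(skipped = FALSE, profile = prof,
                         matching = matching, model = fit)
  }
  out
}
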