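#' Five-year age bands
#'
#' Cuts ages 20+ into the bands 20-24, 25-29, ..., 80-84, 85+.
#'
#' @param age Numeric ages (>= 20).
#' @return Factor of band labels.
#' @export
age_band5 <- function(age) {
  b <- age_bands()
  cut(age, breaks = c(b$low, Inf), labels = b$band, right = FALSE)
}

#' Prepare survey weights: per-round rescaling and age post-stratification
#'
#' Two steps. (1) Within each round, weights are multiplied so every round
#' sums to the same total — by default the mean per-round sample size — so
#' each round contributes the same effective sample size to pooled
#' regressions. (2) Within each round, band-level multipliers are applied
#' so the weighted 5-year age-band shares match a reference age
#' distribution (e.g. a census population). The default reference is
#' uniform over the observed bands; a table of band proportions can be
#' supplied.
#'
#' @param records Data frame with `age`, `round` and `weight_sample`.
#' @param reference Named numeric vector of band proportions (names as in
#'   [age_band5()] levels); `NULL` for uniform over observed bands.
#' @param common_total Target per-round weight total; default mean round
#'   sample size.
#' @return Object of class `weight_scheme`: data frame columns `band`,
#'   `w_raw`, `w_rescaled`, `w_adj` aligned with `records`, plus the
#'   reference used.
#' @export
prepare_weights <- function(records, reference = NULL, common_total = NULL) {
  stopifnot(all(c("age", "round", "weight_sample") %in% names(records)))
  if (any(records$weight_sample <= 0, na.rm = TRUE)) {
    stop("survey weights must be positive")
  }
  band <- age_band5(records$age)
  w_raw <- records$weight_sample
  round_id <- as.character(records$round)
  common_total <- common_total %||% mean(table(round_id))
  round_sums <- tapply(w_raw, round_id, sum)
  w_res <- w_raw * common_total / round_sums[round_id]

  bands_present <- levels(droplevels(band))
  if (is.null(reference)) {
    reference <- setNames(rep(1 / length(bands_present),
                              length(bands_present)), bands_present)
  }
  reference <- reference / sum(reference)
  zero_mass <- vapply(names(reference)[reference > 0], function(bb) {
    sum(w_res[band == bb]) == 0
  }, logical(1))
  if (any(zero_mass)) {
    stop("no weighted mass in band(s) with nonzero reference mass: ",
         paste(names(which(zero_mass)), collapse = ", "))
  }
  w_adj <- w_res
  for (r in unique(round_id)) {
    in_r <- round_id == r
    tot_r <- sum(w_res[in_r])
    for (bb in names(reference)) {
      sel <- in_r & band == bb
      s <- sum(w_res[sel])
      if (s > 0) w_adj[sel] <- w_res[sel] * reference[[bb]] * tot_r / s
      else if (reference[[bb]] > 0 && any(band[in_r] == bb, na.rm = TRUE)) {
        stop("zero weighted mass in round ", r, ", band ", bb)
      }
    }
  }
  structure(list(band = band, w_raw = w_raw, w_rescaled = as.numeric(w_res),
                 w_adj = as.numeric(w_adj), reference = reference,
                 round = round_id, common_total = common_total),
            class = "weight_scheme")
}

#' Weighted per-round cluster prevalence series
#'
#' The weighted share of each cluster in each round, using the
#' age-post-stratified weights (`standardized = TRUE`, the default) or the
#' per-round rescaled weights only (crude prevalence).
#'
#' @param cluster Cluster label per participant (any atomic type).
#' @param scheme A [prepare_weights()] result aligned with `cluster`.
#' @param standardized Use age-adjusted weights.
#' @return Data frame `round`, `cluster`, `prevalence`; shares sum to 1
#'   within each round.
#' @export
weighted_prevalence_series <- function(cluster, scheme,
                                       standardized = TRUE) {
  w <- if (standardized) scheme$w_adj else scheme$w_rescaled
  agg <- aggregate(w, list(round = scheme$round, cluster = cluster), sum)
  tot <- tapply(agg$x, agg$round, sum)
  agg$prevalence <- as.numeric(agg$x / tot[agg$round])
  agg$x <- NULL
  agg[order(agg$round, agg$cluster), ]
}

#' Age-adjusted logistic trend test for one cluster
#'
#' Fits a weighted logistic regression of cluster membership on calendar
#' time (continuous mid-year) with 5-year age-band indicators, restricted
#' to a period (boundary years inclusive). Weights are the age-adjusted
#' weights of the scheme, treated as frequency-style weights in the IRLS
#' fit; the p value is the two-sided t test on the time coefficient.
#'
#' @param member Logical/0-1 membership indicator per participant.
#' @param mid_year Survey mid-year per participant.
#' @param scheme A [prepare_weights()] result.
#' @param period `c(start, end)` years, inclusive; `NULL` for all years.
#' @return One-row data frame of class `trend_result`: `period`,
#'   `coef_per_year` (log-odds change per year), `pct_change_per_year`
#'   (`100 * (exp(coef) - 1)`), `se`, `p`, `converged`, `n`.
#' @export
trend_regression <- function(member, mid_year, scheme, period = NULL) {
  keep <- rep(TRUE, length(member))
  if (!is.null(period)) {
    keep <- mid_year >= period[1] & mid_year <= period[2]
  }
  y <- as.numeric(member[keep])
  yr <- mid_year[keep]
  if (length(unique(yr)) < 2) stop("period needs at least two distinct years")
  if (length(unique(y)) < 2) stop("membership must include both classes")
  band <- droplevels(scheme$band[keep])
  w <- scheme$w_adj[keep]
  dat <- data.frame(y = y, year = yr - min(yr), band = band, w = w)
  fit <- suppressWarnings(
    glm(y ~ year + band, family = quasibinomial(), data = dat, weights = w))
  sm <- summary(fit)$coefficients
  co <- sm["year", "Estimate"]
  se <- sm["year", "Std. Error"]
  p <- sm["year", 4]
  sep_flag <- !fit$converged || abs(co) > 20
  structure(data.frame(
    period_start = if (is.null(period)) min(yr) else period[1],
    period_end = if (is.null(period)) max(yr) else period[2],
    coef_per_year = co,
    pct_change_per_year = 100 * (exp(co) - 1),
    se = se, p = p, converged = !sep_flag, n = length(y)),
    class = c("trend_result", "data.frame"))
}

#' Per-cluster trend tests over pre-specified periods
#'
#' Runs [trend_regression()] for every cluster and every period.
#'
#' @param cluster Cluster label per participant.
#' @param mid_year Survey mid-year per participant.
#' @param scheme A [prepare_weights()] result.
#' @param periods List of `c(start, end)` pairs; the default mirrors a
#'   1988-2018 analysis split at 2000 and 2010, boundary years inclusive
#'   on both ends, plus the entire period.
#' @return Data frame with one row per cluster x period.
#' @export
trend_table <- function(cluster, mid_year, scheme,
                        periods = list(c(1988, 2000), c(2000, 2010),
                                       c(2010, 2018), c(1988, 2018))) {
  cl <- sort(unique(cluster))
  do.call(rbind, lapply(cl, function(cc) {
    do.call(rbind, lapply(periods, function(p) {
      res <- trend_regression(cluster == cc, mid_year, scheme, p)
      cbind(cluster = cc, res)
    }))
  }))
}

#' Predictors of cluster membership
#'
#' One weighted multivariate logistic regression per cluster: membership
#' on survey year (scaled per decade), age band, ethnicity, education,
#' smoking, medication use and disease history, with declared reference
#' levels (youngest age band, non-Hispanic White, below high school,
#' never-smoker). Coefficients are log odds ratios against the reference
#' level; p values are two-sided t tests.
#'
#' @param records Analysis-set data frame with covariate columns
#'   `ethnicity`, `education`, `smoking`, `med_*`, `hist_*`, `mid_year`.
#' @param cluster Cluster label per participant.
#' @param scheme A [prepare_weights()] result.
#' @param covariates Character vector of covariate columns to include.
#' @return Named list (per cluster) of coefficient data frames
#'   (`term`, `estimate`, `se`, `p`).
#' @export
membership_predictors <- function(records, cluster, scheme,
                                  covariates = c("ethnicity", "education",
                                                 "smoking",
                                                 "med_antihypertensive",
                                                 "med_statin",
                                                 "med_oral_hypoglycemic",
                                                 "med_insulin", "hist_mi",
                                                 "hist_stroke",
                                                 "hist_chf")) {
  dat <- data.frame(
    decade = (records$mid_year - min(records$mid_year)) / 10,
    band = droplevels(scheme$band),
    w = scheme$w_adj)
  for (v in covariates) {
    col <- records[[v]]
    if (is.null(col)) stop("covariate column missing: ", v)
    if (is.character(col) || is.factor(col)) {
      ref <- switch(v, ethnicity = "non-Hispanic White",
                    education = "below high school", smoking = "never",
                    levels(factor(col))[1])
      dat[[v]] <- stats::relevel(factor(col), ref = ref)
    } else dat[[v]] <- col
  }
  form <- stats::as.formula(paste(
    "y ~ decade + band +", paste(covariates, collapse = " + ")))
  out <- list()
  for (cc in sort(unique(cluster))) {
    dat$y <- as.numeric(cluster == cc)
    mm <- stats::model.matrix(form, dat)
    qq <- qr(mm)
    if (qq$rank < ncol(mm)) {
      alias <- colnames(mm)[qq$pivot[(qq$rank + 1):ncol(mm)]]
      stop("rank-deficient design for cluster ", cc, "; aliased: ",
           paste(alias, collapse = ", "))
    }
    fit <- suppressWarnings(
      glm(form, family = quasibinomial(), data = dat, weights = w))
    sm <- summary(fit)$coefficients
    out[[as.character(cc)]] <- data.frame(
      term = rownames(sm), estimate = sm[, 1], se = sm[, 2], p = sm[, 4],
      row.names = NULL)
  }
  out
}

#' Wilson score confidence interval for a proportion
#'
#' `(p + z^2/2n +/- z * sqrt(p(1-p)/n + z^2/4n^2)) / (1 + z^2/n)` with `z`
#' the standard normal quantile at `(1 + level) / 2`. Always contained in
#' `[0, 1]` and containing the point estimate.
#'
#' @param count Number of successes (vectorized).
#' @param n Number of trials.
#' @param level Confidence level (default 0.95).
#' @return Data frame `estimate`, `lower`, `upper` (proportions).
#' @export
wilson_ci <- function(count, n, level = 0.95) {
  if (any(n < 1)) stop("n must be at least 1")
  if (any(count < 0 | count > n)) stop("count must lie in [0, n]")
  z <- qnorm((1 + level) / 2)
  p <- count / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  data.frame(estimate = p, lower = pmax(0, center - half),
             upper = pmin(1, center + half))
}

#' Weighted prevalence by age group and round
#'
#' Binned (unsmoothed) weighted prevalence of each cluster within each
#' age group and survey round. Empty (age group, round) cells are
#' reported as missing rather than zero.
#'
#' @param cluster Cluster label per participant.
#' @param age_group Age-group label per participant (any partition of
#'   ages 20+).
#' @param round Round label per participant.
#' @param weights Analysis weights (default equal).
#' @return Data frame `round`, `age_group`, `cluster`, `prevalence`.
#' @export
age_pattern_table <- function(cluster, age_group, round,
                              weights = NULL) {
  weights <- weights %||% rep(1, length(cluster))
  cl <- sort(unique(cluster))
  grid <- expand.grid(round = sort(unique(round)),
                      age_group = sort(unique(age_group)),
                      cluster = cl, stringsAsFactors = FALSE)
  grid$prevalence <- mapply(function(r, g, cc) {
    sel <- round == r & age_group == g
    tot <- sum(weights[sel])
    if (tot == 0) return(NA_real_)
    sum(weights[sel & cluster == cc]) / tot
  }, grid$round, grid$age_group, grid$cluster)
  grid
}
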