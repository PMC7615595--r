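#' Define a phenotype archetype
#'
#' An archetype is one component of the sex-specific mixture from which the
#' synthetic cohort is drawn: a multivariate-normal profile over the ten
#' risk factors (natural scales, canonical order of [risk_factors()]),
#' a base mixture weight, a per-round additive trend on the mixture
#' log-odds, an age distribution over 5-year bands, and per-flag
#' probabilities for medications and disease history.
#'
#' @param name Archetype label.
#' @param mean Named or ordered numeric vector of 10 feature means.
#' @param sd Per-feature standard deviations (used to build a diagonal
#'   covariance) — ignored when `cov` is given.
#' @param cov Optional full 10x10 symmetric positive-semidefinite covariance.
#' @param base_weight Nonnegative base mixture weight.
#' @param weight_trend Additive change in mixture log-odds per round.
#' @param age_mean,age_sd Mean and SD of the age distribution, discretized
#'   over 5-year bands from 20-24 to 85+.
#' @param flag_probs Named list of probabilities for binary covariates
#'   (medication use, disease history); missing entries use defaults.
#' @return Object of class `archetype_spec`.
#' @export
archetype_spec <- function(name, mean, sd = NULL, cov = NULL,
                           base_weight = 1, weight_trend = 0,
                           age_mean = 45, age_sd = 14,
                           flag_probs = list()) {
  feats <- risk_factors()
  if (!is.null(names(mean))) mean <- mean[feats]
  mean <- as.numeric(mean)
  if (length(mean) != 10 || any(!is.finite(mean))) {
    stop("mean must be 10 finite values")
  }
  if (is.null(cov)) {
    if (is.null(sd)) stop("supply either sd or cov")
    cov <- diag(as.numeric(sd)^2, 10)
  }
  cov <- as.matrix(cov)
  if (!isTRUE(all.equal(cov, t(cov), tolerance = 1e-8))) {
    stop("covariance must be symmetric")
  }
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev), 1)) {
    stop("covariance must be positive semi-definite")
  }
  if (base_weight < 0) stop("base_weight must be nonnegative")
  structure(list(name = name, mean = setNames(mean, feats), cov = cov,
                 base_weight = base_weight, weight_trend = weight_trend,
                 age_dist = discretize_age(age_mean, age_sd),
                 flag_probs = flag_probs),
            class = "archetype_spec")
}

age_bands <- function() {
  lower <- seq(20, 85, by = 5)
  data.frame(band = paste0(lower, "-", ifelse(lower == 85, "+", lower + 4)),
             low = lower,
             high = c(lower[-1] - 1, 94))
}

discretize_age <- function(age_mean, age_sd) {
  b <- age_bands()
  p <- pnorm(b$high + 1, age_mean, age_sd) - pnorm(b$low, age_mean, age_sd)
  p[1] <- p[1] + pnorm(b$low[1], age_mean, age_sd)
  p[nrow(b)] <- p[nrow(b)] + pnorm(b$high[nrow(b)] + 1, age_mean, age_sd,
                                   lower.tail = FALSE)
  setNames(p / sum(p), b$band)
}

default_flag_probs <- function() {
  list(med_antihypertensive = 0.15, med_statin = 0.10,
       med_oral_hypoglycemic = 0.05, med_insulin = 0.02,
       hist_mi = 0.03, hist_stroke = 0.03, hist_chf = 0.02)
}

#' Default archetype library
#'
#' Ten sex-specific archetypes spanning the phenotypes this style of
#' analysis typically uncovers in an adult examination survey: a low-risk
#' group, two mid-risk groups differing by height, a low-BMI/high-HDL
#' group, five groups elevated in one or two related factors (heart rate,
#' cholesterol, blood pressure, adiposity, glycemia), and an older group
#' with low DBP and poor kidney function. The means are illustrative
#' round-number profiles for each phenotype, not estimates from any survey;
#' within-archetype covariances are diagonal with documented SDs.
#'
#' @param sex `"female"` or `"male"`.
#' @return List of [archetype_spec()] objects.
#' @export
default_archetypes <- function(sex = c("female", "male")) {
  sex <- match.arg(sex)
  sds <- c(height = 6, bmi = 2.5, whtr = 0.04, sbp = 9, dbp = 6, rhr = 7,
           hdl = 0.22, non_hdl = 0.6, hba1c = 0.45, egfr = 10)
  # within-archetype correlations of physiologically coupled pairs
  corr <- diag(10)
  dimnames(corr) <- list(names(sds), names(sds))
  corr["bmi", "whtr"] <- corr["whtr", "bmi"] <- 0.75
  corr["sbp", "dbp"] <- corr["dbp", "sbp"] <- 0.70
  arch_cov <- diag(sds) %*% corr %*% diag(sds)
  f <- sex == "female"
  m <- function(height, bmi, whtr, sbp, dbp, rhr, hdl, non_hdl, hba1c, egfr) {
    c(height = height, bmi = bmi, whtr = whtr, sbp = sbp, dbp = dbp,
      rhr = rhr, hdl = hdl, non_hdl = non_hdl, hba1c = hba1c, egfr = egfr)
  }
  # per-archetype (base weight, log-odds trend per round) tuned so pooled
  # shares approximate published cluster sizes and stated directions of
  # change (rising severe adiposity and renal phenotypes, falling blood
  # pressure and cholesterol ones, low risk falling for women only)
  specs <- list(
    list("low_risk",
         if (f) m(164, 22.0, 0.45, 104, 64, 68, 1.70, 2.60, 5.0, 112)
         else   m(178, 23.0, 0.46, 110, 66, 64, 1.40, 2.80, 5.1, 110),
         if (f) 0.17 else 0.13, if (f) -0.02 else 0, 31),
    list("mid_risk_short",
         if (f) m(155, 27.0, 0.55, 111, 70, 72, 1.45, 3.30, 5.4, 102)
         else   m(168, 26.5, 0.53, 118, 73, 70, 1.20, 3.50, 5.4, 101),
         if (f) 0.13 else 0.14, 0.00, 37),
    list("mid_risk_tall",
         if (f) m(167, 27.5, 0.53, 119, 74, 70, 1.40, 3.50, 5.4, 92)
         else   m(182, 27.0, 0.51, 123, 75, 68, 1.15, 3.60, 5.4, 93),
         if (f) 0.12 else 0.14, 0.00, 45),
    list("low_bmi_high_hdl",
         if (f) m(162, 21.5, 0.46, 117, 70, 69, 2.30, 3.00, 5.4, 90)
         else   m(176, 22.5, 0.47, 121, 72, 66, 1.90, 3.20, 5.4, 89),
         if (f) 0.10 else 0.08, 0.00, 54),
    list("high_heart_rate",
         if (f) m(162, 26.0, 0.52, 112, 71, 94, 1.45, 3.30, 5.4, 104)
         else   m(175, 26.5, 0.52, 122, 75, 92, 1.20, 3.60, 5.6, 96),
         0.09, 0.00, if (f) 31 else 45),
    list("high_cholesterol",
         if (f) m(161, 28.0, 0.57, 124, 76, 72, 1.40, 5.50, 5.6, 86)
         else   m(175, 27.5, 0.55, 125, 78, 71, 1.10, 5.50, 5.6, 90),
         if (f) 0.12 else 0.13, -0.08, if (f) 58 else 48),
    list("high_blood_pressure",
         if (f) m(160, 28.5, 0.58, 159, 86, 73, 1.45, 3.80, 5.7, 80)
         else   m(174, 27.5, 0.55, 159, 88, 70, 1.20, 3.90, 5.7, 82),
         0.11, -0.08, 64),
    list("severe_obesity",
         if (f) m(162, 41.1, 0.72, 122, 74, 76, 1.15, 3.60, 5.8, 96)
         else   m(176, 38.2, 0.68, 126, 77, 74, 1.00, 3.80, 5.8, 94),
         if (f) 0.065 else 0.055, 0.10, 46),
    list("severe_hyperglycemia",
         if (f) m(161, 31.8, 0.62, 126, 74, 78, 1.15, 4.00, 9.9, 92)
         else   m(174, 29.7, 0.58, 128, 76, 76, 1.00, 4.20, 9.8, 90),
         if (f) 0.029 else 0.035, 0.00, 57),
    list("low_dbp_low_egfr",
         if (f) m(158, 27.0, 0.57, 136, 61, 68, 1.40, 3.60, 5.9, 63)
         else   m(172, 26.5, 0.55, 137, 62, 66, 1.15, 3.70, 5.9, 63),
         if (f) 0.075 else 0.085, 0.06, 74)
  )
  flag_tweaks <- list(
    high_blood_pressure = list(med_antihypertensive = 0.45),
    high_cholesterol = list(med_statin = 0.12),
    severe_hyperglycemia = list(med_oral_hypoglycemic = 0.54,
                                med_insulin = 0.33,
                                med_antihypertensive = 0.40),
    severe_obesity = list(med_antihypertensive = 0.35,
                          med_oral_hypoglycemic = 0.13),
    low_dbp_low_egfr = list(med_antihypertensive = 0.55, med_statin = 0.38,
                            hist_mi = 0.12, hist_stroke = 0.09,
                            hist_chf = 0.10),
    low_risk = list(med_antihypertensive = 0.02, med_statin = 0.02)
  )
  lapply(specs, function(s) {
    archetype_spec(s[[1]], s[[2]], cov = arch_cov, base_weight = s[[3]],
                   weight_trend = s[[4]], age_mean = s[[5]], age_sd = 13,
                   flag_probs = flag_tweaks[[s[[1]]]] %||% list())
  })
}

#' Default survey rounds
#'
#' Eleven rounds: one 1988-1994 examination round (mid-year 1991) and ten
#' continuous two-year rounds from 1999-2000 to 2017-2018.
#'
#' @return Data frame with columns `round` and `mid_year`.
#' @export
default_rounds <- function() {
  data.frame(
    round = c("1988-1994", paste(seq(1999, 2017, 2), seq(2000, 2018, 2),
                                 sep = "-")),
    mid_year = c(1991, seq(2000, 2018, 2)))
}

#' Build a cohort generator configuration
#'
#' @param n_per_round Participants drawn per survey round. The default of
#'   2,744 yields roughly 30,000 participants over the 11 default rounds,
#'   the order of magnitude of a pooled single-sex national examination
#'   survey sample.
#' @param rounds Data frame of rounds and mid-years, as [default_rounds()].
#' @param sex `"female"` or `"male"`.
#' @param archetypes List of [archetype_spec()]s; default library for `sex`.
#' @param weight_sigma Log-scale SD of the log-normal survey weights.
#' @param error_rates Named list of injected-error fractions
#'   (`implausible`, `discordant`, `consistency`, `missing`), all zero by
#'   default.
#' @param seed Integer seed driving every draw.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_per_round = 2744,
                          rounds = default_rounds(),
                          sex = c("female", "male"),
                          archetypes = NULL,
                          weight_sigma = 0.5,
                          error_rates = list(),
                          seed = 1L) {
  sex <- match.arg(sex)
  if (is.null(archetypes)) archetypes <- default_archetypes(sex)
  if (length(archetypes) == 0) stop("at least one archetype is required")
  stopifnot(n_per_round >= 1, all(c("round", "mid_year") %in% names(rounds)))
  rates <- modifyList(list(implausible = 0, discordant = 0,
                           consistency = 0, missing = 0), error_rates)
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop("error rates must lie in [0, 1]")
  }
  structure(list(n_per_round = as.integer(n_per_round), rounds = rounds,
                 sex = sex, archetypes = archetypes,
                 weight_sigma = weight_sigma, error_rates = rates,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# Draw from one archetype, resampling rows that fall outside the
# plausibility ranges so raw records round-trip through cleaning.
draw_features <- function(n, spec, ranges_list) {
  feats <- risk_factors()
  x <- MASS::mvrnorm(n, spec$mean, spec$cov)
  if (n == 1) x <- matrix(x, nrow = 1)
  colnames(x) <- feats
  in_range <- function(m) {
    ok <- rep(TRUE, nrow(m))
    for (v in feats) {
      r <- ranges_list[[v]]
      if (!is.null(r)) ok <- ok & m[, v] >= r[1] & m[, v] <= r[2]
    }
    ok
  }
  for (tries in 1:50) {
    bad <- which(!in_range(x))
    if (!length(bad)) break
    redraw <- MASS::mvrnorm(length(bad), spec$mean, spec$cov)
    if (length(bad) == 1) redraw <- matrix(redraw, nrow = 1)
    x[bad, ] <- redraw
  }
  x
}

#' Generate a synthetic cohort
#'
#' Draws participants round by round from the archetype mixture (weights
#' evolved on the log-odds scale by each archetype's trend), samples the
#' ten risk factors from the archetype's truncated multivariate normal,
#' and back-derives internally consistent raw fields: body weight from BMI
#' and height, waist from WHtR and height, total cholesterol from non-HDL
#' plus HDL, serum creatinine by numerically inverting the CKD-EPI equation
#' at the drawn age and sex, and three blood-pressure readings equal to the
#' drawn value plus independent noise (SD 2 mmHg) with the first reading
#' biased +3 mmHg so the discard-first averaging rule matters. Survey
#' weights are log-normal; sociodemographic covariates and binary flags are
#' drawn from per-archetype probabilities. Deterministic given
#' `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return Object of class `synthetic_cohort`: list with `records` (data
#'   frame, one row per participant), `true_labels` (archetype name per
#'   record) and `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  rl <- ranges_as_list(default_plausibility_ranges())
  specs <- config$archetypes
  n_arch <- length(specs)
  bands <- age_bands()

  local_seed(config$seed, {
    out <- vector("list", nrow(config$rounds))
    labels <- vector("list", nrow(config$rounds))
    for (r in seq_len(nrow(config$rounds))) {
      logw <- vapply(specs, function(s) {
        log(s$base_weight) + s$weight_trend * (r - 1)
      }, numeric(1))
      w <- exp(logw - max(logw)); w <- w / sum(w)
      counts <- as.vector(rmultinom(1, config$n_per_round, w))
      per_arch <- vector("list", n_arch)
      for (a in seq_len(n_arch)) {
        n <- counts[a]
        if (n == 0) next
        spec <- specs[[a]]
        feat <- draw_features(n, spec, rl)
        band_idx <- sample.int(nrow(bands), n, replace = TRUE,
                               prob = spec$age_dist)
        age <- bands$low[band_idx] +
          floor(runif(n) * (bands$high[band_idx] - bands$low[band_idx] + 1))
        fp <- modifyList(default_flag_probs(), spec$flag_probs)
        rec <- data.frame(
          sex = config$sex,
          age = age,
          round = config$rounds$round[r],
          mid_year = config$rounds$mid_year[r],
          weight_sample = rlnorm(n, 0, config$weight_sigma),
          height = feat[, "height"],
          body_weight = feat[, "bmi"] * (feat[, "height"] / 100)^2,
          waist = feat[, "whtr"] * feat[, "height"],
          sbp_1 = feat[, "sbp"] + 3 + rnorm(n, 0, 2),
          sbp_2 = feat[, "sbp"] + rnorm(n, 0, 2),
          sbp_3 = feat[, "sbp"] + rnorm(n, 0, 2),
          dbp_1 = feat[, "dbp"] + 3 + rnorm(n, 0, 2),
          dbp_2 = feat[, "dbp"] + rnorm(n, 0, 2),
          dbp_3 = feat[, "dbp"] + rnorm(n, 0, 2),
          rhr = feat[, "rhr"],
          tc = feat[, "non_hdl"] + feat[, "hdl"],
          hdl = feat[, "hdl"],
          hba1c = feat[, "hba1c"],
          scr = invert_egfr(feat[, "egfr"], age, config$sex),
          ethnicity = sample(c("non-Hispanic White", "non-Hispanic Black",
                               "Hispanic", "Other"), n, replace = TRUE,
                             prob = c(0.55, 0.20, 0.20, 0.05)),
          education = sample(c("below high school", "high school",
                               "university or college"), n, replace = TRUE,
                             prob = c(0.25, 0.35, 0.40)),
          smoking = sample(c("never", "former", "current"), n,
                           replace = TRUE, prob = c(0.55, 0.25, 0.20)),
          stringsAsFactors = FALSE
        )
        for (flag in names(default_flag_probs())) {
          rec[[flag]] <- rbinom(n, 1, fp[[flag]])
        }
        per_arch[[a]] <- rec
      }
      out[[r]] <- do.call(rbind, per_arch)
      labels[[r]] <- rep(vapply(specs, `[[`, character(1), "name"), counts)
    }
    records <- do.call(rbind, out)
    records <- cbind(id = sprintf("P%06d", seq_len(nrow(records))), records,
                     stringsAsFactors = FALSE)
    rownames(records) <- NULL
    structure(list(records = records,
                   true_labels = unlist(labels),
                   config = config),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic cohort:", nrow(x$records), "participants (",
      x$config$sex, "),", nrow(x$config$rounds), "rounds,",
      length(x$config$archetypes), "archetypes\n")
  print(table(x$true_labels))
  invisible(x)
}

#' Matrix of uncorrelated standard-normal draws
#'
#' The null data for stability calibration: `n` points drawn iid from a
#' `dim`-dimensional standard normal with no correlation structure.
#'
#' @param n Number of rows (points).
#' @param dim Number of columns (features).
#' @param seed Integer seed.
#' @return `n x dim` numeric matrix.
#' @export
generate_null_matrix <- function(n, dim = 10, seed = NULL) {
  if (n < 1 || dim < 1) stop("n and dim must be positive")
  local_seed(seed, matrix(rnorm(n * dim), nrow = n, ncol = dim))
}
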