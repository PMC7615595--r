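#' Default plausibility ranges
#'
#' Per-variable `[low, high]` bounds on natural measurement scales outside
#' which a value is treated as a recording error and set to missing. The
#' defaults are deliberately wide physiological bounds; every bound can be
#' overridden (e.g. from a pipeline configuration file).
#'
#' @return Data frame with columns `variable`, `low`, `high`.
#' @export
default_plausibility_ranges <- function() {
  data.frame(
    variable = c("height", "body_weight", "waist", "bmi", "whtr",
                 "sbp", "dbp", "rhr", "tc", "hdl", "non_hdl",
                 "hba1c", "scr", "egfr"),
    low  = c(100,  25,  40, 10, 0.2,  70,  30,  30, 1.75, 0.4, 0,    3, 0.2,   2),
    high = c(250, 350, 250, 80, 1.5, 270, 150, 200, 20,   5,  19.6, 18, 15,  250),
    stringsAsFactors = FALSE
  )
}

ranges_as_list <- function(ranges) {
  if (is.data.frame(ranges)) {
    stopifnot(all(c("variable", "low", "high") %in% names(ranges)))
    out <- Map(c, ranges$low, ranges$high)
    names(out) <- ranges$variable
  } else {
    out <- ranges
  }
  bad <- vapply(out, function(r) r[1] >= r[2], logical(1))
  if (any(bad)) {
    stop("plausibility range low >= high for: ",
         paste(names(out)[bad], collapse = ", "))
  }
  out
}

#' Summarize repeated blood-pressure readings
#'
#' The first reading is discarded (it is systematically elevated by the
#' measurement context) and the remaining readings are averaged. With fewer
#' than two readings the summary is missing unless `use_single = TRUE`, in
#' which case a lone reading is returned as is.
#'
#' @param readings Numeric vector of readings in acquisition order; `NA`s
#'   are treated as not taken.
#' @param use_single Return a single available reading instead of `NA`.
#' @return Scalar mmHg summary, or `NA`.
#' @export
summarize_blood_pressure <- function(readings, use_single = FALSE) {
  if (!is.numeric(readings)) stop("readings must be numeric")
  readings <- readings[!is.na(readings)]
  if (length(readings) >= 2) return(mean(readings[-1]))
  if (length(readings) == 1 && use_single) return(readings)
  NA_real_
}

# Apply summarize_blood_pressure() row-wise to reading columns
# (sbp_1, sbp_2, ... / dbp_1, dbp_2, ...), producing `sbp` and `dbp`.
summarize_bp_columns <- function(records, use_single = FALSE) {
  for (var in c("sbp", "dbp")) {
    cols <- grep(paste0("^", var, "_[0-9]+$"), names(records), value = TRUE)
    if (length(cols) == 0) next
    cols <- cols[order(as.integer(sub(".*_", "", cols)))]
    m <- as.matrix(records[, cols, drop = FALSE])
    records[[var]] <- apply(m, 1, summarize_blood_pressure,
                            use_single = use_single)
  }
  records
}

#' Plausibility and internal-consistency screen
#'
#' Sets values outside their plausibility range to missing, then enforces
#' SBP > DBP and TC >= HDL by setting the offending pair to missing. A pair
#' such as SBP 248 / DBP 40 passes this rule (it is internally consistent);
#' catching such discordant combinations is the job of
#' [pairwise_mahalanobis_outliers()].
#'
#' @param records Cohort data frame (blood pressure already summarized).
#' @param ranges Plausibility ranges, as from [default_plausibility_ranges()].
#' @return List with `records` (masked values) and `report`: per-variable
#'   masked counts, consistency-violation counts, and flagged row indices.
#' @export
apply_plausibility_and_consistency <- function(records,
                                               ranges = default_plausibility_ranges()) {
  rl <- ranges_as_list(ranges)
  vars <- intersect(names(rl), names(records))
  masked <- setNames(integer(length(vars)), vars)
  flagged_plaus <- logical(nrow(records))
  for (v in vars) {
    x <- records[[v]]
    out <- !is.na(x) & (x < rl[[v]][1] | x > rl[[v]][2])
    masked[v] <- sum(out)
    flagged_plaus <- flagged_plaus | out
    records[[v]][out] <- NA_real_
  }
  flagged_consist <- logical(nrow(records))
  n_bp <- n_lipid <- 0L
  if (all(c("sbp", "dbp") %in% names(records))) {
    bad <- !is.na(records$sbp) & !is.na(records$dbp) &
      records$sbp <= records$dbp
    n_bp <- sum(bad)
    records$sbp[bad] <- NA_real_
    records$dbp[bad] <- NA_real_
    flagged_consist <- flagged_consist | bad
  }
  if (all(c("tc", "hdl") %in% names(records))) {
    bad <- !is.na(records$tc) & !is.na(records$hdl) & records$tc < records$hdl
    n_lipid <- sum(bad)
    records$tc[bad] <- NA_real_
    records$hdl[bad] <- NA_real_
    flagged_consist <- flagged_consist | bad
  }
  list(records = records,
       report = list(masked_by_variable = masked,
                     consistency = c(sbp_le_dbp = n_bp, tc_lt_hdl = n_lipid),
                     flagged_plausibility = which(flagged_plaus),
                     flagged_consistency = which(flagged_consist)))
}

#' Squared-Mahalanobis exclusion threshold
#'
#' Converts a univariate "standard deviations from the mean" criterion into
#' a squared Mahalanobis distance threshold: the chi-square quantile with
#' `df` degrees of freedom at cumulative probability
#' `1 - 2 * (1 - pnorm(sd_equiv))`, i.e. the squared distance whose tail
#' probability under multivariate normality equals a two-sided `sd_equiv`-SD
#' univariate tail. At `sd_equiv = 6`, `df = 2` this is 40.09 (commonly
#' quoted as 40.08), and at `df = 1` it is exactly 36.
#'
#' @param sd_equiv Equivalent univariate distance in standard deviations.
#' @param df Dimension of the variable block (2 for pairwise screening).
#' @return Threshold on the squared Mahalanobis distance scale.
#' @export
mahalanobis_threshold <- function(sd_equiv = 6, df = 2) {
  stopifnot(sd_equiv > 0)
  if (df < 1) stop("df must be >= 1")
  qchisq(1 - 2 * (1 - pnorm(sd_equiv)), df = df)
}

#' Default variable pair groups for outlier screening
#'
#' All pairs of anthropometric variables (height, weight, BMI, waist,
#' waist-to-height ratio), the blood-pressure pair and the lipid pair.
#'
#' @return List of character vectors naming the variables in each group.
#' @export
default_pair_groups <- function() {
  list(anthropometric = c("height", "body_weight", "bmi", "waist", "whtr"),
       blood_pressure = c("sbp", "dbp"),
       lipids = c("tc", "hdl"))
}

# Variables screened on their natural (not log) scale.
unlogged_screen_vars <- function() c("height", "dbp")

#' Pairwise Mahalanobis outlier screen
#'
#' For every variable pair within each group, transforms each member
#' (natural log, except height and DBP, which are roughly symmetric),
#' estimates the bivariate mean and covariance over complete pairs —
#' separately per sex, matching the sex-stratified clustering — and sets
#' both members of a pair to missing where the squared Mahalanobis distance
#' exceeds `threshold`. Flags for all pairs are computed from the input
#' values before any masking, so pair order does not matter.
#'
#' @param records Cohort data frame with derived measures available.
#' @param threshold Squared-distance cutoff, from [mahalanobis_threshold()].
#' @param pair_groups As [default_pair_groups()].
#' @param by_sex Estimate screen parameters separately per sex.
#' @param min_complete Minimum complete pairs needed to screen a pair;
#'   sparser pairs are skipped with a warning.
#' @return List with `records` and `report` (per-pair flagged row indices
#'   and counts, plus the union of flagged rows).
#' @export
pairwise_mahalanobis_outliers <- function(records,
                                          threshold = mahalanobis_threshold(6, 2),
                                          pair_groups = default_pair_groups(),
                                          by_sex = TRUE,
                                          min_complete = 10) {
  pairs <- do.call(rbind, lapply(pair_groups, function(vars) {
    if (length(vars) < 2) return(NULL)
    t(utils::combn(vars, 2))
  }))
  strata <- if (by_sex && !is.null(records$sex)) {
    split(seq_len(nrow(records)), records$sex)
  } else list(all = seq_len(nrow(records)))

  flags <- list()
  for (p in seq_len(nrow(pairs))) {
    v1 <- pairs[p, 1]; v2 <- pairs[p, 2]
    if (!all(c(v1, v2) %in% names(records))) next
    pname <- paste(v1, v2, sep = ":")
    x1 <- records[[v1]]; x2 <- records[[v2]]
    if (!v1 %in% unlogged_screen_vars()) x1 <- log(x1)
    if (!v2 %in% unlogged_screen_vars()) x2 <- log(x2)
    flagged <- integer(0)
    for (idx in strata) {
      m <- cbind(x1[idx], x2[idx])
      ok <- complete.cases(m)
      if (sum(ok) < min_complete) {
        warning("pair ", pname, ": fewer than ", min_complete,
                " complete pairs; skipped")
        next
      }
      mu <- colMeans(m[ok, , drop = FALSE])
      sig <- cov(m[ok, , drop = FALSE])
      if (abs(det(sig)) < .Machine$double.eps) {
        stop("singular covariance for pair ", pname)
      }
      d2 <- rep(NA_real_, length(idx))
      d2[ok] <- mahalanobis(m[ok, , drop = FALSE], mu, sig)
      flagged <- c(flagged, idx[!is.na(d2) & d2 > threshold])
    }
    flags[[pname]] <- sort(flagged)
  }

  all_flagged <- sort(unique(unlist(flags)))
  for (p in seq_len(nrow(pairs))) {
    pname <- paste(pairs[p, 1], pairs[p, 2], sep = ":")
    rows <- flags[[pname]]
    if (length(rows)) {
      records[[pairs[p, 1]]][rows] <- NA_real_
      records[[pairs[p, 2]]][rows] <- NA_real_
    }
  }
  list(records = records,
       report = list(flagged_by_pair = flags,
                     n_by_pair = vapply(flags, length, integer(1)),
                     flagged_rows = all_flagged,
                     threshold = threshold))
}

#' Linear serum-creatinine calibration
#'
#' Applies a linear map `slope * scr + intercept` to serum creatinine to
#' harmonize assay drift across survey rounds. The default is the identity
#' (no recalibration); the coefficients of any published calibration
#' equation can be supplied. Results are floored at a small positive value
#' with a warning, since calibrated creatinine must stay positive.
#'
#' @param values Serum creatinine, mg/dL.
#' @param slope,intercept Calibration coefficients.
#' @param floor Lower bound applied after calibration.
#' @return Calibrated values, same length and order.
#' @export
calibrate_creatinine <- function(values, slope = 1, intercept = 0,
                                 floor = 0.05) {
  out <- slope * values + intercept
  low <- !is.na(out) & out < floor
  if (any(low)) {
    warning(sum(low), " calibrated creatinine value(s) at or below zero; ",
            "set to floor ", floor)
    out[low] <- floor
  }
  out
}

#' Restrict to the analysis set
#'
#' Keeps participants aged `min_age` or older with a complete ten-feature
#' risk-factor vector (see [risk_factors()]).
#'
#' @param records Cohort data frame after cleaning and derivation.
#' @param min_age Minimum age in years (default 20).
#' @return List with `records` and `report` (`n_under_age`, `n_incomplete`).
#' @export
build_analysis_set <- function(records, min_age = 20) {
  adult <- !is.na(records$age) & records$age >= min_age
  n_under <- sum(!adult)
  records <- records[adult, , drop = FALSE]
  have <- complete.cases(records[, risk_factors(), drop = FALSE])
  n_inc <- sum(!have)
  records <- records[have, , drop = FALSE]
  if (nrow(records) == 0) {
    stop("analysis set is empty; review plausibility ranges and inputs")
  }
  list(records = records,
       report = list(n_under_age = n_under, n_incomplete = n_inc))
}

#' Run the full cleaning stack
#'
#' Executes the cleaning procedure in flowchart order: blood-pressure
#' summarization, creatinine calibration, plausibility bounds on raw
#' measurements, SBP/DBP and TC/HDL consistency, derivation of BMI, WHtR,
#' non-HDL and eGFR, plausibility bounds on derived measures, the pairwise
#' Mahalanobis screen, and finally the adult complete-case restriction.
#' Participant removals are attributed to the first failing rule.
#'
#' @param records Raw cohort data frame (reading columns `sbp_1`, ... may
#'   be present; otherwise `sbp`/`dbp` are used as given).
#' @param ranges Plausibility ranges.
#' @param sd_equiv,pair_groups Mahalanobis screen settings.
#' @param scr_slope,scr_intercept Creatinine calibration coefficients.
#' @param egfr_version CKD-EPI variant, `"2009"` or `"2021"`.
#' @param min_age Minimum age for the analysis set.
#' @param bp_use_single Keep a lone blood-pressure reading instead of
#'   treating it as missing.
#' @param mahalanobis_by_sex Estimate screen parameters per sex.
#' @return List with `records` (the analysis set) and `report`
#'   (class `cleaning_report`).
#' @export
clean_cohort <- function(records,
                         ranges = default_plausibility_ranges(),
                         sd_equiv = 6,
                         pair_groups = default_pair_groups(),
                         scr_slope = 1, scr_intercept = 0,
                         egfr_version = "2009",
                         min_age = 20,
                         bp_use_single = FALSE,
                         mahalanobis_by_sex = TRUE) {
  n_in <- nrow(records)
  records <- summarize_bp_columns(records, use_single = bp_use_single)
  if (!is.null(records$scr)) {
    records$scr <- calibrate_creatinine(records$scr, scr_slope, scr_intercept)
  }

  rl <- ranges_as_list(ranges)
  raw_vars <- intersect(names(rl), names(records))
  step1 <- apply_plausibility_and_consistency(
    records, ranges_subset(ranges, raw_vars))
  records <- step1$records

  records <- derive_ratios(records)
  records$egfr <- egfr_ckdepi(records$scr, records$age, records$sex,
                              version = egfr_version)
  derived_vars <- intersect(names(rl), c("bmi", "whtr", "non_hdl", "egfr"))
  step2 <- apply_plausibility_and_consistency(
    records, ranges_subset(ranges, derived_vars))
  records <- step2$records

  thr <- mahalanobis_threshold(sd_equiv, 2)
  step3 <- pairwise_mahalanobis_outliers(records, thr, pair_groups,
                                         by_sex = mahalanobis_by_sex)
  records <- step3$records

  step4 <- build_analysis_set(records, min_age = min_age)

  # first-failing-rule attribution for removed participants
  kept <- rownames(records) %in% rownames(step4$records)
  under_age <- !is.na(records$age) & records$age < min_age |
    is.na(records$age)
  flag_plaus <- seq_len(nrow(records)) %in%
    c(step1$report$flagged_plausibility, step2$report$flagged_plausibility)
  flag_consist <- seq_len(nrow(records)) %in% step1$report$flagged_consistency
  flag_mahal <- seq_len(nrow(records)) %in% step3$report$flagged_rows
  removed <- !kept
  rule <- ifelse(under_age, "under_age",
          ifelse(flag_plaus, "plausibility",
          ifelse(flag_consist, "consistency",
          ifelse(flag_mahal, "mahalanobis", "incomplete"))))
  attribution <- table(factor(rule[removed],
    levels = c("under_age", "plausibility", "consistency",
               "mahalanobis", "incomplete")))

  report <- structure(list(
    n_input = n_in,
    n_output = nrow(step4$records),
    removed_by_rule = as.integer(attribution),
    rule_names = names(attribution),
    masked_by_variable = c(step1$report$masked_by_variable,
                           step2$report$masked_by_variable),
    consistency = step1$report$consistency,
    mahalanobis_by_pair = step3$report$n_by_pair,
    mahalanobis_flagged = step3$report$flagged_rows,
    threshold = thr
  ), class = "cleaning_report")
  list(records = step4$records, report = report)
}

ranges_subset <- function(ranges, vars) {
  if (is.data.frame(ranges)) {
    ranges[ranges$variable %in% vars, , drop = FALSE]
  } else {
    ranges[intersect(names(ranges), vars)]
  }
}

#' @export
print.cleaning_report <- function(x, ...) {
  cat("Cleaning report:", x$n_input, "records in,", x$n_output, "retained\n")
  cat("Removed, attributed to first failing rule:\n")
  for (i in seq_along(x$rule_names)) {
    cat(sprintf("  %-12s %d\n", x$rule_names[i], x$removed_by_rule[i]))
  }
  cat("Values masked by plausibility bounds:",
      sum(x$masked_by_variable), "\n")
  cat("Consistency violations (SBP<=DBP, TC<HDL):",
      paste(x$consistency, collapse = ", "), "\n")
  cat("Pairs flagged by the Mahalanobis screen (d^2 >",
      round(x$threshold, 2), "):", sum(x$mahalanobis_by_pair), "\n")
  invisible(x)
}
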