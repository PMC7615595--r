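#' Derived anthropometric and lipid ratios
#'
#' Adds body-mass index, waist-to-height ratio and non-HDL cholesterol to a
#' cohort table: `bmi = body_weight / (height/100)^2` (kg/m^2),
#' `whtr = waist / height`, `non_hdl = tc - hdl` (mmol/L). Rows with missing
#' inputs get missing outputs.
#'
#' @param records Cohort data frame with columns `height` (cm),
#'   `body_weight` (kg), `waist` (cm), `tc` and `hdl` (mmol/L).
#' @return `records` with columns `bmi`, `whtr`, `non_hdl` added/replaced.
#' @export
derive_ratios <- function(records) {
  h <- records$height
  if (any(!is.na(h) & h <= 0)) stop("non-positive height encountered")
  bad <- !is.na(records$tc) & !is.na(records$hdl) & records$tc < records$hdl
  if (any(bad)) {
    stop("TC < HDL encountered; consistency cleaning must run first (",
         sum(bad), " record(s))")
  }
  records$bmi <- records$body_weight / (h / 100)^2
  records$whtr <- records$waist / h
  records$non_hdl <- records$tc - records$hdl
  records
}

#' Estimated glomerular filtration rate (CKD-EPI creatinine equation)
#'
#' Computes eGFR (ml/min/1.73 m^2) from serum creatinine, age and sex using
#' the piecewise power-law CKD-EPI creatinine equation. The 2009 equation is
#' the default; the 2021 race-free refit is selectable. The optional race
#' multiplier of the 2009 equation is off by default.
#'
#' @param scr Serum creatinine, mg/dL (positive).
#' @param age Age in years.
#' @param sex `"female"` or `"male"` (recycled).
#' @param version `"2009"` (default) or `"2021"`.
#' @param race_multiplier Logical vector; when `TRUE` (and `version` is
#'   `"2009"`) the 1.159 multiplier is applied to that element.
#' @return Numeric vector of eGFR values.
#' @export
egfr_ckdepi <- function(scr, age, sex, version = c("2009", "2021"),
                        race_multiplier = FALSE) {
  version <- match.arg(version)
  if (any(!is.na(scr) & scr <= 0)) stop("serum creatinine must be positive")
  n <- max(length(scr), length(age), length(sex))
  scr <- rep_len(scr, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  race_multiplier <- rep_len(race_multiplier, n)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  if (version == "2009") {
    alpha <- ifelse(female, -0.329, -0.411)
    out <- 141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.209 *
      0.993^age * ifelse(female, 1.018, 1)
    out <- out * ifelse(race_multiplier, 1.159, 1)
  } else {
    alpha <- ifelse(female, -0.241, -0.302)
    out <- 142 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^-1.2 *
      0.9938^age * ifelse(female, 1.012, 1)
  }
  out
}

#' Invert the CKD-EPI equation for serum creatinine
#'
#' Finds the serum creatinine (mg/dL) at which [egfr_ckdepi()] equals a
#' target eGFR, for a given age and sex. Used by the synthetic cohort
#' generator to back-derive raw creatinine from a drawn eGFR. The equation
#' is strictly decreasing in creatinine, so the root is unique.
#'
#' @param egfr Target eGFR values (ml/min/1.73 m^2).
#' @param age,sex,version,race_multiplier As in [egfr_ckdepi()].
#' @return Serum creatinine values, mg/dL.
#' @export
invert_egfr <- function(egfr, age, sex, version = "2009",
                        race_multiplier = FALSE) {
  n <- max(length(egfr), length(age), length(sex))
  egfr <- rep_len(egfr, n); age <- rep_len(age, n)
  sex <- rep_len(as.character(sex), n)
  vapply(seq_len(n), function(i) {
    if (is.na(egfr[i]) || is.na(age[i])) return(NA_real_)
    uniroot(function(s) {
      egfr_ckdepi(s, age[i], sex[i], version, race_multiplier) - egfr[i]
    }, lower = 1e-3, upper = 60, tol = 1e-9)$root
  }, numeric(1))
}

#' Assemble the clustering feature matrix
#'
#' Extracts the ten risk factors in canonical order (see [risk_factors()]).
#' By default only rows with a complete feature vector are kept, mirroring
#' the complete-case restriction of the analysis set.
#'
#' @param records Cohort data frame carrying all ten risk-factor columns.
#' @param complete_only Drop rows with any missing feature (default `TRUE`).
#' @return Numeric matrix with one row per (retained) record; row names are
#'   record ids when an `id` column is present.
#' @export
assemble_feature_matrix <- function(records, complete_only = TRUE) {
  feats <- risk_factors()
  missing_cols <- setdiff(feats, names(records))
  if (length(missing_cols)) {
    stop("missing risk-factor columns: ", paste(missing_cols, collapse = ", "))
  }
  m <- as.matrix(records[, feats, drop = FALSE])
  storage.mode(m) <- "double"
  if (!is.null(records$id)) rownames(m) <- as.character(records$id)
  if (complete_only) m <- m[complete.cases(m), , drop = FALSE]
  m
}
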