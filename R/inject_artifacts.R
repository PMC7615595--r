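#' Inject measurement artifacts into a synthetic cohort
#'
#' Alters a chosen fraction of records to exercise each cleaning rule:
#'
#' * `implausible` — one raw measurement pushed outside its plausibility
#'   range (e.g. height 95 cm, resting heart rate 220 bpm);
#' * `discordant` — one member of a screened variable pair moved about
#'   `offset_sd` conditional standard deviations away from its partner on
#'   the screen's (log) scale while staying inside plausibility ranges and
#'   internal-consistency constraints, emulating combinations such as a
#'   very high BMI with a small waist;
#' * `consistency` — an SBP/DBP swap or an HDL raised above TC, producing
#'   in-range values that violate SBP > DBP or TC >= HDL;
#' * `missing` — one required raw field deleted.
#'
#' Records are altered at most once; the altered ids and artifact types are
#' returned as ground truth in the `injected` element.
#'
#' @param cohort A [generate_cohort()] result.
#' @param error_rates Named list of fractions (`implausible`, `discordant`,
#'   `consistency`, `missing`); defaults to the rates in the cohort config.
#' @param seed Integer seed (defaults to the cohort seed + 1).
#' @param offset_sd Size of the discordant offset in conditional SDs.
#' @return The cohort with altered `records` and a ground-truth `injected`
#'   data frame (`id`, `row`, `type`).
#' @export
inject_artifacts <- function(cohort, error_rates = NULL, seed = NULL,
                             offset_sd = 8) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rates <- modifyList(cohort$config$error_rates, error_rates %||% list())
  if (any(unlist(rates) < 0 | unlist(rates) > 1)) {
    stop("error rates must lie in [0, 1]")
  }
  rec <- cohort$records
  n <- nrow(rec)
  counts <- vapply(rates, function(r) as.integer(round(r * n)), integer(1))
  if (sum(counts) == 0) {
    cohort$injected <- data.frame(id = character(0), row = integer(0),
                                  type = character(0))
    return(cohort)
  }
  if (sum(counts) > n) stop("error rates select more records than exist")
  seed <- seed %||% (cohort$config$seed + 1L)

  local_seed(seed, {
    pool <- sample.int(n)  # disjoint draws across artifact types
    taken <- 0L
    injected <- list()
    for (type in names(counts)) {
      k <- counts[[type]]
      if (k == 0) next
      rows <- pool[taken + seq_len(k)]
      taken <- taken + k
      rec <- switch(type,
        implausible = inject_implausible(rec, rows),
        discordant = inject_discordant(rec, rows, offset_sd),
        consistency = inject_consistency(rec, rows),
        missing = inject_missing(rec, rows))
      injected[[type]] <- data.frame(id = rec$id[rows], row = rows,
                                     type = type)
    }
    cohort$records <- rec
    cohort$injected <- do.call(rbind, injected)
    rownames(cohort$injected) <- NULL
    cohort
  })
}

inject_implausible <- function(rec, rows) {
  choices <- list(height = 95, body_weight = 400, rhr = 220,
                  hba1c = 2.2, scr = 16, tc = 22)
  pick <- sample(names(choices), length(rows), replace = TRUE)
  for (i in seq_along(rows)) rec[[pick[i]]][rows[i]] <- choices[[pick[i]]]
  rec
}

inject_missing <- function(rec, rows) {
  vars <- c("height", "body_weight", "waist", "rhr", "tc", "hdl",
            "hba1c", "scr")
  pick <- sample(vars, length(rows), replace = TRUE)
  for (i in seq_along(rows)) rec[[pick[i]]][rows[i]] <- NA_real_
  rec
}

inject_consistency <- function(rec, rows) {
  sbp <- apply(as.matrix(rec[, c("sbp_1", "sbp_2", "sbp_3")]), 1,
               summarize_blood_pressure)
  dbp <- apply(as.matrix(rec[, c("dbp_1", "dbp_2", "dbp_3")]), 1,
               summarize_blood_pressure)
  for (i in rows) {
    bp_ok <- !is.na(sbp[i]) && !is.na(dbp[i]) &&
      sbp[i] <= 150 && dbp[i] >= 70
    lipid_ok <- !is.na(rec$tc[i]) && rec$tc[i] <= 4.7
    if (bp_ok) {  # swap SBP and DBP readings: in range, SBP < DBP
      tmp <- rec[i, c("sbp_1", "sbp_2", "sbp_3")]
      rec[i, c("sbp_1", "sbp_2", "sbp_3")] <-
        rec[i, c("dbp_1", "dbp_2", "dbp_3")]
      rec[i, c("dbp_1", "dbp_2", "dbp_3")] <- tmp
    } else if (lipid_ok) {
      rec$hdl[i] <- min(rec$tc[i] + 0.2, 5)
    } else if (!is.na(sbp[i]) && !is.na(dbp[i]) && dbp[i] >= 73) {
      # lower SBP readings just below DBP (stays >= 70)
      shift <- (dbp[i] - 2) - sbp[i]
      rec[i, c("sbp_1", "sbp_2", "sbp_3")] <-
        rec[i, c("sbp_1", "sbp_2", "sbp_3")] + shift
    } else if (!is.na(sbp[i]) && !is.na(dbp[i])) {
      # move both into range with SBP below DBP
      rec[i, c("sbp_1", "sbp_2", "sbp_3")] <-
        rec[i, c("sbp_1", "sbp_2", "sbp_3")] + (70.5 - sbp[i])
      rec[i, c("dbp_1", "dbp_2", "dbp_3")] <-
        rec[i, c("dbp_1", "dbp_2", "dbp_3")] + (73 - dbp[i])
    }
  }
  rec
}

# Bivariate mean/covariance and conditional stats of (x, y) pairs.
pair_stats <- function(x, y) {
  ok <- complete.cases(cbind(x, y))
  m <- cbind(x, y)[ok, , drop = FALSE]
  mu <- colMeans(m)
  S <- cov(m)
  list(mu = mu, S = S, slope = S[1, 2] / S[1, 1],
       cond_sd = sqrt(max(S[2, 2] - S[1, 2]^2 / S[1, 1], 1e-12)))
}

inject_discordant <- function(rec, rows, offset_sd) {
  h <- rec$height
  bmi <- rec$body_weight / (h / 100)^2
  sbp <- apply(as.matrix(rec[, c("sbp_1", "sbp_2", "sbp_3")]), 1,
               summarize_blood_pressure)
  dbp <- apply(as.matrix(rec[, c("dbp_1", "dbp_2", "dbp_3")]), 1,
               summarize_blood_pressure)
  st <- list(waist = pair_stats(log(bmi), log(rec$waist)),
             weight = pair_stats(h, log(rec$body_weight)),
             bp = pair_stats(log(sbp), dbp),
             lipid = pair_stats(log(rec$tc), log(rec$hdl)))
  # the injected point must actually sit offset_sd Mahalanobis units out
  # (clamping into plausibility ranges may otherwise soften the offset)
  d2_min <- offset_sd^2

  # shift y by ~offset_sd conditional SDs given x, clamped into [lo, hi];
  # returns NA unless the clamped point is still a clear pairwise outlier
  shifted <- function(s, x0, lo, hi) {
    if (is.na(x0)) return(NA_real_)
    mu_y <- s$mu[2] + s$slope * (x0 - s$mu[1])
    for (cand in c(mu_y - offset_sd * s$cond_sd,
                   mu_y + offset_sd * s$cond_sd)) {
      y <- max(lo, min(hi, cand))
      d2 <- mahalanobis(c(x0, y), s$mu, s$S)
      if (d2 >= d2_min) return(y)
    }
    NA_real_
  }

  for (i in rows) {
    for (kind in sample(c("waist", "bp", "weight", "lipid"))) {
      done <- FALSE
      if (kind == "waist" && !is.na(rec$waist[i])) {
        lo <- log(max(40, 0.2 * h[i])); hi <- log(min(250, 1.5 * h[i]))
        y <- shifted(st$waist, log(bmi[i]), lo, hi)
        if (!is.na(y)) { rec$waist[i] <- exp(y); done <- TRUE }
      } else if (kind == "weight" && !is.na(rec$body_weight[i])) {
        lo <- log(max(25, 10 * (h[i] / 100)^2))
        hi <- log(min(350, 80 * (h[i] / 100)^2))
        y <- shifted(st$weight, h[i], lo, hi)
        if (!is.na(y)) { rec$body_weight[i] <- exp(y); done <- TRUE }
      } else if (kind == "bp" && !is.na(sbp[i]) && !is.na(dbp[i])) {
        y <- shifted(st$bp, log(sbp[i]), 30, min(150, sbp[i] - 2))
        if (!is.na(y)) {
          rec[i, c("dbp_1", "dbp_2", "dbp_3")] <-
            rec[i, c("dbp_1", "dbp_2", "dbp_3")] + (y - dbp[i])
          done <- TRUE
        }
      } else if (kind == "lipid" && !is.na(rec$tc[i]) &&
                 !is.na(rec$hdl[i])) {
        y <- shifted(st$lipid, log(rec$tc[i]), log(0.4),
                     log(min(5, rec$tc[i])))
        if (!is.na(y)) { rec$hdl[i] <- exp(y); done <- TRUE }
      }
      if (done) break
    }
  }
  rec
}
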