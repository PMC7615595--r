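make_epi_frame <- function(n = 2000, rounds = c(2000, 2010), seed = 1,
                           weights = NULL) {
  set.seed(seed)
  data.frame(
    age = sample(20:84, n, replace = TRUE),
    round = sample(paste0("r", rounds), n, replace = TRUE),
    weight_sample = weights %||% rep(1, n))
}

test_that("weight rescaling equalizes round totals; fixed point holds", {
  df <- make_epi_frame(1200, seed = 2)
  df$weight_sample <- runif(1200, 0.5, 4)
  sch <- prepare_weights(df)
  sums <- tapply(sch$w_rescaled, sch$round, sum)
  expect_equal(unname(diff(range(sums))), 0, tolerance = 1e-9)
  expect_equal(unname(sums[1]), sch$common_total, tolerance = 1e-9)

  # equal weights, balanced rounds, reference = empirical distribution:
  # weights unchanged through both steps
  n <- 1000
  df2 <- data.frame(age = rep(rep(c(22, 37, 52), length.out = 500), 2),
                    round = rep(c("a", "b"), each = 500),
                    weight_sample = 1)
  emp <- prop.table(table(age_band5(df2$age)))
  emp <- setNames(as.numeric(emp[emp > 0]), names(emp[emp > 0]))
  sch2 <- prepare_weights(df2, reference = emp)
  expect_equal(sch2$w_adj, rep(1, 1000), tolerance = 1e-9)
})

test_that("post-stratified band shares reproduce the reference", {
  df <- make_epi_frame(3000, seed = 3)
  df$weight_sample <- rlnorm(3000, 0, 0.5)
  sch <- prepare_weights(df)
  for (r in unique(sch$round)) {
    sel <- sch$round == r
    shares <- tapply(sch$w_adj[sel], droplevels(sch$band[sel]), sum) /
      sum(sch$w_adj[sel])
    ref <- sch$reference[names(shares)]
    expect_equal(as.numeric(shares), as.numeric(ref), tolerance = 1e-8)
  }
  # a reference band with no sample mass errors out
  ref_bad <- setNames(rep(1 / 14, 14), levels(age_band5(20)))
  df_young <- df[df$age < 60, ]
  expect_error(prepare_weights(df_young, reference = ref_bad), "band")
})

test_that("prevalence series: shares sum to one and equal raw proportions
           under uniform weights", {
  df <- make_epi_frame(1500, seed = 4)
  cl <- sample(c("a", "b", "c"), 1500, replace = TRUE,
               prob = c(0.5, 0.3, 0.2))
  sch <- prepare_weights(df)
  crude <- weighted_prevalence_series(cl, sch, standardized = FALSE)
  for (r in unique(crude$round)) {
    sub <- crude[crude$round == r, ]
    expect_equal(sum(sub$prevalence), 1, tolerance = 1e-12)
    raw <- prop.table(table(cl[df$round == r]))
    expect_equal(sub$prevalence[match(names(raw), sub$cluster)],
                 unname(as.numeric(raw)), tolerance = 1e-12)
  }
  # weight rescaling leaves within-round shares unchanged
  df2 <- df; df2$weight_sample <- df$weight_sample * 37
  crude2 <- weighted_prevalence_series(cl, prepare_weights(df2),
                                       standardized = FALSE)
  expect_equal(crude2$prevalence, crude$prevalence, tolerance = 1e-12)
})

test_that("a rising mixture component yields a rising standardized series", {
  arch <- separated_archetypes()
  arch[[2]]$weight_trend <- 0.25  # severe obesity rises
  cfg <- cohort_config(n_per_round = 1200,
                       rounds = data.frame(round = paste0("r", 1:5),
                                           mid_year = seq(2000, 2016, 4)),
                       archetypes = arch, seed = 47)
  co <- generate_cohort(cfg)
  cl <- clean_cohort(co$records)
  truth <- co$true_labels[match(cl$records$id, co$records$id)]
  sch <- prepare_weights(cl$records)
  prev <- weighted_prevalence_series(truth, sch)
  ob <- prev$prevalence[prev$cluster == "severe_obesity"]
  expect_true(all(diff(ob) > 0))
})

test_that("trend regression recovers a known slope and respects the null", {
  set.seed(51)
  n <- 20000
  yr <- sample(seq(2000, 2018, 2), n, replace = TRUE)
  age <- sample(20:80, n, replace = TRUE)
  eta <- -2 + 0.05 * (yr - 2000)
  y <- rbinom(n, 1, plogis(eta))
  df <- data.frame(age = age, round = paste0("r", yr), weight_sample = 1)
  sch <- prepare_weights(df)
  tr <- trend_regression(y, yr, sch)
  expect_lt(abs(tr$coef_per_year - 0.05), 3 * tr$se)
  expect_equal(tr$pct_change_per_year,
               100 * (exp(tr$coef_per_year) - 1), tolerance = 1e-8)
  expect_true(tr$converged)
  # slope equivariant to shifting the year origin
  tr2 <- trend_regression(y, yr - 1999, sch,
                          period = c(2000, 2018) - 1999)
  expect_equal(tr2$coef_per_year, tr$coef_per_year, tolerance = 1e-8)
  # period restriction and guards
  tr3 <- trend_regression(y, yr, sch, period = c(2000, 2010))
  expect_equal(tr3$n, sum(yr <= 2010))
  expect_error(trend_regression(y, rep(2000, n), sch), "distinct")
  expect_error(trend_regression(rep(1, n), yr, sch), "classes")
})

test_that("near-constant membership gives a near-zero percent change", {
  set.seed(53)
  n <- 8000
  yr <- sample(seq(2000, 2018, 2), n, replace = TRUE)
  df <- data.frame(age = sample(20:80, n, TRUE), round = paste0("r", yr),
                   weight_sample = 1)
  y <- rbinom(n, 1, 0.3)
  tr <- trend_regression(y, yr, prepare_weights(df))
  expect_lt(abs(tr$pct_change_per_year), 1.5)
  expect_gt(tr$p, 0.001)
})

test_that("membership predictors recover a doubled odds ratio and use
           reference coding", {
  set.seed(57)
  n <- 12000
  med <- rbinom(n, 1, 0.3)
  eta <- -1.2 + log(2) * med
  member <- rbinom(n, 1, plogis(eta))
  rec <- data.frame(
    age = sample(20:80, n, TRUE),
    round = sample(c("r2000", "r2010"), n, TRUE),
    weight_sample = 1,
    mid_year = 2000,
    ethnicity = sample(c("non-Hispanic White", "non-Hispanic Black",
                         "Hispanic", "Other"), n, TRUE),
    education = sample(c("below high school", "high school",
                         "university or college"), n, TRUE),
    smoking = sample(c("never", "former", "current"), n, TRUE),
    med_statin = med)
  rec$mid_year <- ifelse(rec$round == "r2000", 2000, 2010)
  sch <- prepare_weights(rec)
  cl <- ifelse(member == 1, "target", "rest")
  out <- membership_predictors(rec, cl, sch,
                               covariates = c("ethnicity", "education",
                                              "smoking", "med_statin"))
  est <- out$target
  b <- est$estimate[est$term == "med_statin"]
  se <- est$se[est$term == "med_statin"]
  expect_lt(abs(b - log(2)), 3 * se)
  # reference levels absent from the coefficient table
  expect_false(any(grepl("non-Hispanic White|below high school|^smokingnever",
                         est$term)))
  expect_true(any(grepl("ethnicitynon-Hispanic Black", est$term)))
})

test_that("independent covariates give uniform-ish p values and aliased
           designs are refused", {
  set.seed(59)
  reps <- 200
  pvals <- numeric(reps)
  n <- 400
  for (r in seq_len(reps)) {
    x <- rbinom(n, 1, 0.4)
    y <- rbinom(n, 1, 0.3)
    yr <- sample(c(2000, 2010), n, TRUE)
    df <- data.frame(age = sample(20:80, n, TRUE),
                     round = paste0("r", yr),
                     weight_sample = 1, mid_year = yr, covar = x)
    sch <- prepare_weights(df)
    out <- membership_predictors(df, ifelse(y == 1, "a", "b"), sch,
                                 covariates = "covar")
    est <- out$a
    pvals[r] <- est$p[est$term == "covar"]
  }
  expect_gt(suppressWarnings(stats::ks.test(pvals, "punif")$p.value), 0.01)
  # a duplicated covariate is aliased and must be named in the error
  df$covar2 <- df$covar
  expect_error(membership_predictors(df, ifelse(y == 1, "a", "b"),
                                     prepare_weights(df),
                                     covariates = c("covar", "covar2")),
               "aliased.*covar2")
})

test_that("Wilson intervals reproduce printed survey table cells", {
  # worked examples from published cluster-characteristics tables
  ci <- wilson_ci(117, 4632)
  expect_equal(round(ci$lower, 3), 0.021)
  expect_equal(round(ci$upper, 3), 0.030)
  ci <- wilson_ci(159, 3730)
  expect_equal(round(ci$lower, 3), 0.037)
  expect_equal(round(ci$upper, 3), 0.050)
  ci <- wilson_ci(2410, 2522)
  expect_equal(round(ci$lower, 3), 0.947)
  expect_equal(round(ci$upper, 3), 0.963)
})

test_that("Wilson intervals match prop.test and behave at the boundaries", {
  for (count in c(0, 1, 5, 50, 99, 100)) {
    n <- 100
    ci <- wilson_ci(count, n)
    ref <- suppressWarnings(
      prop.test(count, n, correct = FALSE)$conf.int)
    expect_equal(c(ci$lower, ci$upper), as.numeric(ref), tolerance = 1e-9)
    expect_true(ci$lower >= 0 && ci$upper <= 1)
    expect_true(ci$lower <= ci$estimate && ci$estimate <= ci$upper)
    # unlike the Wald interval, never degenerate at the boundaries
    if (count %in% c(0, n)) expect_gt(ci$upper - ci$lower, 0)
  }
  expect_equal(wilson_ci(0, 10)$lower, 0)
  expect_error(wilson_ci(5, 0), "n must")
  expect_error(wilson_ci(11, 10), "count")
})

test_that("age-pattern tables match hand-computed proportions", {
  cl <- c("a", "a", "b", "b", "a", "b")
  ag <- c("20-39", "20-39", "20-39", "40-59", "40-59", "40-59")
  rd <- rep("r1", 6)
  tab <- age_pattern_table(cl, ag, rd)
  get <- function(g, cc) tab$prevalence[tab$age_group == g &
                                          tab$cluster == cc]
  expect_equal(get("20-39", "a"), 2 / 3)
  expect_equal(get("40-59", "b"), 2 / 3)
  # shares across clusters sum to 1 per cell; uniform weights = counts
  sums <- tapply(tab$prevalence, list(tab$round, tab$age_group), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # weighted prevalence and a genuinely empty (round, age group) cell
  rd2 <- c("r1", "r1", "r1", "r1", "r1", "r2")
  tab2 <- age_pattern_table(cl, ag, rd2, weights = c(2, 1, 1, 1, 1, 1))
  expect_equal(tab2$prevalence[tab2$round == "r1" &
                                 tab2$age_group == "20-39" &
                                 tab2$cluster == "a"], 3 / 4)
  expect_true(is.na(tab2$prevalence[tab2$round == "r2" &
                                      tab2$age_group == "20-39" &
                                      tab2$cluster == "a"]))
})
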