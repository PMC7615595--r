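---
title: "Methods: data-driven cardiometabolic and renal phenotyping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven cardiometabolic and renal phenotyping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrpheno)
```

## The problem

Cardiometabolic and renal risk factors — adiposity, blood pressure, heart
rate, lipids, glycemia, kidney function — co-occur in structured ways:
they share behavioral, dietary and genetic determinants, and some cause
others. `cmrpheno` implements a pipeline for discovering *phenotypes* —
groups of survey participants with similar joint levels of ten risk
factors — in repeated cross-sectional health-examination surveys, and for
tracking how the prevalence of each phenotype changes across survey
rounds and population subgroups.

The ten features, in the package's canonical order (`risk_factors()`),
are: height (cm), body-mass index (BMI, kg/m²), waist-to-height ratio
(WHtR), systolic and diastolic blood pressure (SBP, DBP, mmHg), resting
heart rate (RHR, bpm, measured as a 60-second pulse), HDL and non-HDL
cholesterol (mmol/L), glycated hemoglobin (HbA1c, %), and estimated
glomerular filtration rate (eGFR, ml/min/1.73 m², from the CKD-EPI
creatinine equation). BMI, WHtR, non-HDL (= total cholesterol − HDL) and
eGFR are derived from raw measurements by the `derive_ratios()` /
`egfr_ckdepi()` functions.

## Pipeline overview

1. **Cleaning** (`clean_cohort()`): plausibility bounds, blood-pressure
   summarization, internal-consistency checks, a pairwise Mahalanobis
   outlier screen, and restriction to adults with complete feature
   vectors.
2. **Clustering** (`standardize()`, `kmeans_lloyd()`): sex-stratified
   k-means on standardized features, pooled across rounds, with elbow and
   silhouette diagnostics over a range of k.
3. **Profiling** (`cluster_profile()`): per-cluster medians, their
   percentile positions in the whole sample, and deterministic naming.
4. **Stability** (`subsample_stability()`, `null_calibration()`):
   half-subsample bootstrap Jaccard indices, calibrated against
   structureless Gaussian data; subperiod reclustering
   (`subperiod_consistency()`).
5. **Epidemiology** (`prepare_weights()`, `trend_regression()`,
   `membership_predictors()`, `wilson_ci()`): survey-weighted,
   age-standardized prevalence series, per-cluster logistic trend tests
   and membership-predictor regressions.

A synthetic cohort generator (`generate_cohort()`) supplies data with the
statistical structure the analysis assumes, so every stage is testable
without survey files.

## Cleaning

**Blood pressure.** Repeated readings are summarized by discarding the
first (which is systematically elevated by the measurement context) and
averaging the rest. A single reading yields a missing summary by default;
`bp_use_single = TRUE` keeps it instead. This matters: the generator
biases the first reading +3 mmHg, so using all readings would shift BP up
by about 1 mmHg.

**Plausibility.** Values outside wide physiological bounds (e.g. SBP
70–270 mmHg, BMI 10–80 kg/m², HbA1c 3–18%) are set to missing. The
default table in `default_plausibility_ranges()` is a documented package
default — real analyses should review and, where needed, override it.

**Consistency.** SBP must exceed DBP and total cholesterol must be at
least HDL; violating pairs are set to missing. A pair such as SBP 248 /
DBP 40 *passes* this rule — it is internally consistent, just jointly
implausible, which is the next rule's job.

**Pairwise Mahalanobis screen.** For every pair of anthropometric
variables (height, weight, BMI, waist, WHtR), the blood-pressure pair and
the lipid pair, the bivariate mean and covariance are estimated (per sex,
matching the sex-stratified clustering; all variables log-transformed
except the roughly symmetric height and DBP) and records whose squared
Mahalanobis distance exceeds a cutoff have both pair members set to
missing. The cutoff is the χ²₂ quantile matching a two-sided univariate
6-SD tail, `mahalanobis_threshold(6, 2)` ≈ 40.09 (commonly quoted as
40.08): under bivariate normality a fraction of only ~2 × 10⁻⁹ of clean
records is flagged per pair, so the screen costs essentially nothing when
the data are clean. We interpret the cutoff as applying to the *squared*
distance: the χ²₂ quantile at this tail probability is what equals
≈ 40.1, whereas the unsquared distance would be ≈ 6.33 — only the squared
reading is consistent with the "six standard deviations" gloss.

Flags for all pairs are computed from the input values before any
masking, so the result does not depend on pair order. Removal of a
participant then happens at the complete-case stage; the cleaning report
attributes each removal to the first failing rule, so rule counts sum
exactly to the attrition.

Two caveats discovered by testing are worth recording. First, the
procedure is exactly idempotent only on in-distribution data: after
removing heavy injected contamination, re-estimating the screen on the
cleaned sample tightens the covariance slightly and can flag a trace
(≲ 0.1%) of borderline records on a second pass. Second, the screen's
sensitivity to an injected discordant pair depends on the pair's
correlation: for strongly correlated pairs (BMI–waist, SBP–DBP) an
8-conditional-SD offset remains inside plausibility bounds and is flagged
essentially always, whereas for weakly correlated pairs (TC–HDL) such an
offset would be caught by the univariate bounds first. The artifact
injector therefore verifies the achieved bivariate distance and places
discordance in a pair where it is actually a *pairwise* outlier.

**Creatinine calibration.** A linear map (slope, intercept) is applied to
serum creatinine before eGFR computation to allow harmonization across
assay eras; the default is the identity, since published calibration
coefficients are external data. The CKD-EPI 2009 equation is the default
(the analysis period predates the 2021 race-free refit); the 2021 variant
is selectable via `egfr_version`, and the optional 1.159 multiplier of
the 2009 equation is off by default. No HbA1c recalibration is applied.

## Clustering

Features are centered and scaled per sex (`standardize()`), and Lloyd's
k-means with squared Euclidean distance is run with 50 random starts
(centers seeded at k distinct data points; k-means++ is available but not
the default), keeping the lowest within-cluster sum of squares (WCSS).
Numerical conventions, all of which matter for exact reproducibility:

* assignment ties break toward the lowest cluster index;
* an empty cluster is reseeded at the point farthest from its own center,
  keeping k fixed;
* iteration stops when assignments are unchanged or the largest center
  shift is below 10⁻⁶ standardized units, with at most 300 iterations;
* per-start seeds are spawned from the master seed by a prefix-stable
  stream, so the best-of-n-starts objective is non-increasing in the
  number of starts.

The core iteration is compiled (C++) so that the stability bootstrap and
the 30,180-point null calibration run in minutes on one core. Tests
verify the implementation against exhaustive enumeration of all
partitions on small instances and against an independent Lloyd
implementation on larger ones.

`k_diagnostics()` reports the WCSS elbow curve and the mean silhouette
width for k in a configurable range (default 5–12). The silhouette is
quadratic in n and is therefore evaluated on a 5,000-point subsample
beyond that size; a point in a singleton cluster contributes 0. Neither
heuristic is treated as decisive — consistent with general experience on
population risk-factor data, where cluster boundaries are not sharp — and
the pipeline's k is a pre-specified configuration value (default 10).

**Profiling and naming.** Clusters are summarized by their per-feature
medians and the percentile position of each median in the whole-sample
distribution, with positions reversed for height, HDL and eGFR (lower
values indicate higher risk). Published analyses of this kind name
clusters by inspection; for testability the package formalizes that as
priority-ordered rules on the positions (severe hyperglycemia: HbA1c
≥ P95; severe obesity: BMI ≥ P90; high blood pressure: SBP ≥ P90; high
cholesterol: non-HDL ≥ P90; high heart rate: RHR ≥ P90; low DBP + low
eGFR: both ≤ P25; low risk: all risk-oriented positions ≤ P40; low BMI +
high HDL: BMI ≤ P25 and HDL risk-position ≤ P25; otherwise mid risk,
split tall/short at the sample median height). Two conventions deserve a
note. The obesity severity threshold is P90, not P95: a severe-obesity
cluster typically holds around a tenth of the sample, which caps its
median near the 95th percentile, so a P95 rule would be unattainable for
a cluster of realistic size. And the low-risk rule fires before the
low-BMI/high-HDL rule, because a cluster that is near-optimal on every
factor also trivially has low BMI and high HDL. All thresholds are
configurable; the first matching rule wins, and duplicate names get a
numeric suffix rather than silently colliding.

`match_clusters()` compares two clusterings by their pairwise Jaccard
matrix under an exact one-to-one assignment (dynamic programming over
column subsets — exact for the k ≤ 12 used here, and verified against
brute-force enumeration). `cluster_flow()` tabulates how clusters split
and merge between two values of k, and `intra_inter_distances()` reports
exact average pairwise Euclidean distances within and between clusters in
a single compiled pass.

## Stability

For each of B replicates (1,000 in a full analysis), half the sample is
drawn without replacement and re-clustered with the same k (10 starts per
replicate by default — a deliberate economy relative to the 50-start
reference fit, configurable via `n_starts`). Each reference cluster,
restricted to the subsample, is scored by its Jaccard index with the
best-matching replicate cluster — the maximum over replicate clusters,
which is standard clusterwise-stability practice; a global one-to-one
assignment is available via `match = "assignment"` and is never larger.
Replicates reuse the full-sample standardization (the subsample is a view
of the same space); per-subsample standardization is available behind a
flag. The per-cluster average over replicates is the stability index.

**Null calibration.** The same procedure applied to n points drawn iid
from a 10-dimensional uncorrelated standard normal gives the yardstick
for "no real structure": k-means will always carve a featureless Gaussian
into k pieces, but those pieces do not survive subsampling. At the
30,180-point scale of a pooled single-sex survey sample with k = 10, the
maximum per-cluster average Jaccard stays near or below 0.30, whereas
separated mixtures score 0.9 or higher — a wide margin that makes the
calibration informative. At B = 50 (the desk-scale default used by the
tests and the acceptance script) the per-cluster averages carry
Monte-Carlo noise of a few hundredths relative to B = 1,000, so the test
asserts the 0.30 yardstick with a 0.05 subsample-count allowance.

`subperiod_consistency()` re-clusters calendar subperiods with their own
standardization and matches the resulting profiles to the pooled
reference by Euclidean distance over percentile positions, reporting
unmatched phenotypes — the check that pooled-round phenotypes are not an
artifact of pooling.

## Survey-weighted epidemiology

`prepare_weights()` performs two steps: (1) within each round, weights
are rescaled to a common total (the mean per-round sample size by
default; any total gives identical prevalence estimates, since weighted
shares are scale-invariant) so every round contributes the same effective
sample size; (2) within each round, 5-year age-band multipliers are
applied so the weighted age distribution matches a reference population.
The reference ships as a configurable table and defaults to uniform over
observed bands in tests, since census age counts are external data;
results standardized to a different reference are not comparable in level,
only in trend.

`trend_regression()` fits one weighted logistic regression per cluster —
membership on continuous mid-year plus age-band indicators — over
pre-specified periods (default 1988–2000, 2000–2010, 2010–2018, boundary
years inclusive on both ends, plus the whole period), reporting the
log-odds slope per year, the percent change in odds per year
(100·(e^β − 1)), and a two-sided t-based p value.
`membership_predictors()` fits one weighted multivariate logistic
regression per cluster on year (per decade), age band, ethnicity,
education, smoking, medication use and disease history, with declared
reference levels (youngest band, non-Hispanic White, below high school,
never-smoker). No multiple-testing adjustment is applied, matching the
reporting convention of the analyses this package reproduces.

Weights enter the IRLS fits as frequency-style weights (via the
quasi-binomial family, whose dispersion-scaled t tests are the package's
p values). Design-based (strata/PSU linearized) variance estimation is
deliberately out of scope; consequently the type-I-error calibration
verified in the tests (rejection rate within [0.03, 0.07] at α = 0.05
over 500 null replicates) is demonstrated under equal weights, where the
frequency-weight variance is correct. With strongly informative weights
the nominal level is not guaranteed — a known limitation, inherited from
treating weights as frequencies.

Binomial proportions in composition tables carry Wilson score intervals
(`wilson_ci()`), which are never degenerate at 0/1 — unlike Wald — and
match `prop.test(..., correct = FALSE)` exactly. `age_pattern_table()`
reports binned weighted prevalence by age group and round without
smoothing.

## The synthetic cohort generator

`generate_cohort()` draws, per survey round, archetype memberships from a
mixture whose log-odds evolve linearly per round, then features from each
archetype's multivariate normal on natural scales, truncated to the
plausibility ranges by resampling. The default library has ten sex-specific
archetypes mirroring the phenotypes this analysis style finds (their
defining medians — e.g. HbA1c 9.9%, BMI 41.1 kg/m², SBP 159 mmHg, non-HDL
5.5 mmol/L — set to published cluster medians where available, otherwise
to round plausible values; the profiles are illustrative, not survey
estimates). Within-archetype covariance is diagonal except for the two
strongly coupled pairs BMI–WHtR (r = 0.75) and SBP–DBP (r = 0.70), which
real anthropometry and hemodynamics exhibit and which the pairwise
outlier screen relies on.

Raw fields are back-derived so the derived measures are true functions of
raw data: weight = BMI·(height/100)², waist = WHtR·height, TC = non-HDL +
HDL, serum creatinine by numerically inverting the CKD-EPI equation at
the drawn age and sex, and three BP readings with iid 2-mmHg noise and a
+3 mmHg first-reading bias. Ages are drawn from per-archetype
discretized-normal distributions over 5-year bands; survey weights are
log-normal (σ = 0.5) and independent of archetype; default round
structure is one 1988–1994 round plus ten two-year rounds through 2018,
with 2,744 participants per round (≈30,000 pooled, the order of a
single-sex pooled survey sample).

What the generator does *not* emulate: multistage stratified sampling
(weights are iid, not design-derived), oversampling and nonresponse
adjustment, assay drift, within-person measurement correlation beyond the
BP readings, and non-Gaussian within-phenotype shapes. Passing tests on
synthetic cohorts therefore demonstrate that the machinery is correct
under the model it assumes — not that any particular published prevalence
is reproduced. The generator's mixture trends are qualitative (rising
severe obesity and low-DBP/low-eGFR, falling high blood pressure and high
cholesterol), so synthetic trend tables resemble published ones in sign,
not in magnitude.

`inject_artifacts()` adds ground-truth labeled errors — out-of-range
values, pairwise-discordant combinations verified to be ≥ 8 Mahalanobis
units out, in-range consistency violations (an SBP/DBP swap), and deleted
fields — to exercise each cleaning rule and measure its sensitivity and
false-flag rate.

## Problem sizes and determinism

The test suite exercises the full 30,180 × 10 null calibration with
B = 50 and k-means instances up to a few thousand points; the bundled
acceptance script does the same calibration from scratch. Every stochastic
stage takes an explicit integer seed, children are spawned by a
prefix-stable stream, and reruns with the same configuration are
bit-identical; `run_pipeline()` writes the configuration hash and all
seeds next to its outputs.

## Known limitations

* k-means with Euclidean distance assumes roughly spherical clusters in
  standardized space; probabilistic mixture models are out of scope.
* Design-based variance and real census reference populations are not
  included (see above).
* Plausibility bounds and naming thresholds are package defaults, not
  survey-validated values; both are fully configurable.
* The exact-assignment matcher is exponential in the smaller cluster
  count and is intended for k ≤ 12.
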