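# cmrpheno

Data-driven discovery and monitoring of **cardiometabolic and renal
phenotypes** in repeated cross-sectional health-examination surveys.

Population surveys such as national health examination studies measure,
on tens of thousands of adults, a panel of physiological risk factors
whose joint structure matters more than any single one: adiposity, blood
pressure, heart rate, lipids, glycemia and kidney function co-occur in
patterned ways. `cmrpheno` is for epidemiologists and biostatisticians
who want to partition such a sample into phenotypes — groups of
participants with similar joint risk-factor levels — and track how the
prevalence of each phenotype moves across survey rounds, age groups and
sociodemographic strata.

## What it implements

Ten risk factors in a fixed canonical order: height, BMI, waist-to-height
ratio, SBP, DBP, resting heart rate, HDL and non-HDL cholesterol, HbA1c,
and eGFR from the CKD-EPI creatinine equation
(eGFR = 141 · min(Scr/κ,1)^α · max(Scr/κ,1)^−1.209 · 0.993^age · 1.018[female]).

* **Cleaning** — plausibility bounds; blood-pressure summarization
  (discard the first reading, average the rest); SBP > DBP and TC ≥ HDL
  consistency; a pairwise Mahalanobis outlier screen over anthropometric,
  blood-pressure and lipid variable pairs on the log scale, with cutoff
  d² > χ²₂ at the two-sided univariate 6-SD tail (≈ 40.1); adult
  complete-case restriction with first-failing-rule attrition accounting.
* **Clustering** — sex-stratified k-means (Lloyd, Euclidean, 50 random
  starts, compiled inner loop) on standardized features pooled across
  rounds; elbow and silhouette diagnostics for k in 5–12; cluster
  profiling by median percentile positions and deterministic naming
  ("low risk", "severe obesity", "low DBP, low eGFR", ...).
* **Stability** — per-cluster average Jaccard index over B half-samples
  drawn without replacement and re-clustered (best-match comparison),
  calibrated against k-means applied to an uncorrelated 10-d Gaussian of
  the same size, where stability collapses below ≈ 0.30.
* **Survey-weighted epidemiology** — per-round weight rescaling, 5-year
  age-band post-stratification, crude and age-standardized prevalence
  series, per-cluster logistic trend regressions
  (percent change in odds per year = 100·(e^β − 1)), multivariate
  membership-predictor regressions, Wilson score intervals.
* **Synthetic cohorts** — a generator drawing participants from
  sex-specific phenotype archetype mixtures with round-evolving weights,
  back-deriving internally consistent raw fields (including serum
  creatinine by inverting the eGFR equation), plus a ground-truth
  artifact injector for validating every cleaning rule.

## Worked example

```r
library(cmrpheno)

co    <- generate_cohort(cohort_config(n_per_round = 1000, sex = "female",
                                       seed = 42))
cl    <- clean_cohort(co$records)
feats <- assemble_feature_matrix(cl$records)
z     <- standardize(feats)
model <- kmeans_lloyd(z$x, k = 10, n_starts = 50, seed = 42)
prof  <- cluster_profile(feats, model$cluster)
print(prof)
```

```
                 name share height   bmi whtr    sbp   dbp   rhr  hdl non_hdl hba1c   egfr
    low BMI, high HDL 0.097 161.88 21.49 0.46 117.33 70.56 69.00 2.29    2.96  5.38  90.05
        mid risk tall 0.121 167.39 27.36 0.53 118.94 73.82 69.69 1.38    3.45  5.39  92.30
             low risk 0.147 164.49 22.04 0.45 103.40 63.38 67.67 1.70    2.58  5.01 112.48
  high blood pressure 0.082 159.81 28.32 0.58 158.24 85.89 72.86 1.43    3.79  5.70  79.74
       severe obesity 0.113 162.10 41.13 0.72 121.68 73.74 76.05 1.16    3.60  5.80  96.46
 severe hyperglycemia 0.029 160.63 31.96 0.62 125.49 73.78 78.41 1.16    4.06  9.89  92.73
     high cholesterol 0.084 160.93 28.12 0.57 123.57 76.05 72.19 1.40    5.52  5.63  86.90
       mid risk short 0.129 154.41 27.01 0.55 111.47 70.00 72.31 1.43    3.30  5.41 101.68
    low DBP, low eGFR 0.106 157.77 26.91 0.57 135.89 60.84 67.93 1.40    3.60  5.90  62.91
      high heart rate 0.093 162.01 26.18 0.52 111.13 70.85 93.71 1.45    3.34  5.44 103.60
```

Each row is one discovered phenotype: its share of the 11,000-person
synthetic sample and the cluster median of each risk factor on its
natural scale. The defining factor of each named phenotype stands far
from the sample median (e.g. HbA1c 9.9 % for "severe hyperglycemia",
BMI 41 kg/m² for "severe obesity", SBP 158 mmHg for "high blood
pressure"), while the "low risk" group is near-optimal on all ten.

Stability and trends:

```r
st <- subsample_stability(z$x, model, B = 50, seed = 42)
round(st$average, 2)
#  [1] 1.00 1.00 0.99 0.98 0.97 0.98 1.00 0.97 0.99 0.98

sch <- prepare_weights(cl$records)
tt  <- trend_table(prof$name[model$cluster], cl$records$mid_year, sch,
                   periods = list(c(1988, 2018)))
```

All ten phenotypes have average half-sample Jaccard stability near 1 —
far above the ≈ 0.30 ceiling that the same procedure produces on
structureless Gaussian data (`null_calibration()`). The trend table
reports, per phenotype, the age-adjusted percent change in odds per year
with its two-sided p value; on the default synthetic mixture the severe
obesity and low-DBP/low-eGFR phenotypes rise while the high blood
pressure and high cholesterol ones fall, mirroring the generator's
configured mixture trends.

The full pipeline (simulate → clean → cluster → profile → stability →
trends/predictors, with all seeds and the configuration hash written
next to the outputs) is one call:

```r
run_pipeline(default_pipeline_config(), out_dir = "artifacts")
```

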