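# thyromr

Does adiposity cause thyroid neoplasia? Observational cohorts report
that higher body mass index (BMI), waist–hip ratio and type 2 diabetes
(T2DM) travel with benign nodular thyroid disease and differentiated
thyroid cancer, but those signals are exposed to confounding and
reverse causality. `thyromr` is an R package for epidemiologists and
methodologists that implements the full Mendelian-randomization (MR)
analysis chain for this question — from registry-style records and
genotype dosages to observational, one-sample MR, and two-sample MR
estimates — exercised end-to-end on a bundled synthetic-cohort
generator, because the individual-level biobank data behind such
studies are access-restricted.

## What it computes

**Genetic risk scores.** For a panel of independent variants with
GWAS weights $\beta_j$ oriented to the trait-increasing allele and
dosages $d_{ij} \in [0,2]$,

$$\mathrm{GRS}_i = \sum_j \beta_j d_{ij}, \qquad
  \mathrm{rescaled}_i = \mathrm{GRS}_i \cdot \frac{m}{\sum_j \beta_j},$$

with the first-stage F statistic (weak-instrument bar F > 10) from the
regression of the exposure on the score plus covariates.

**One-sample MR** (two-stage, binary outcome): stage 1 regresses the
exposure on the GRS and covariates; stage 2 is a logistic regression of
the outcome on the stage-1 fitted values, with HC1 sandwich standard
errors. For binary exposures (T2DM liability) the package instead
contrasts GRS quartiles, $\mathrm{OR}_{q} = \frac{a_q d_1}{a_1 d_q}$
crude and covariate-adjusted, quartile 1 fixed at 1.00.

**Two-sample MR** on harmonized summary statistics
$(\hat\beta_{Xj}, \hat\beta_{Yj})$:

- IVW: $\hat\beta = \sum_j w_j \hat\beta_{Xj}\hat\beta_{Yj} \big/
  \sum_j w_j \hat\beta_{Xj}^2$ with $w_j = 1/\mathrm{se}^2(\hat\beta_{Yj})$,
  fixed-effect SE, Cochran's Q;
- MR-Egger: the same weighted regression with a free intercept — the
  intercept estimates average directional pleiotropy and its p-value is
  the pleiotropy test;
- weighted median: the 50% point of the inverse-variance-weighted
  distribution of Wald ratios $\hat\beta_{Yj}/\hat\beta_{Xj}$,
  consistent while valid instruments carry >50% of the weight, SE by
  parametric bootstrap;
- penalized weighted median: weights down-scaled by
  $\min(1, 20\,p_j)$ from each variant's one-df heterogeneity
  chi-square.

**Phenotyping.** An auditable rule engine turns ICD-10 registry rows
into case/control/excluded assignments: C73 restricted to
papillary/follicular histology, non-toxic D34, a 12-month
dual-diagnosis exclusion window, outcome-specific control pools, the
questionnaire T2DM definition (diagnosed ≥35, no first-year insulin,
≥1 year before enrollment), and a thyroid-dysfunction sensitivity
exclusion.

## Worked example

The headline quartile analysis reduces to contingency arithmetic on
published counts bundled with the package:

```r
library(thyromr)
counts <- read.csv(system.file("extdata", "published_quartile_counts.csv",
                               package = "thyromr"))
round(crude_quartile_or(counts$n_cases, counts$n_controls), 3)
#>   quartile n_cases n_controls odds_ratio ci95_low ci95_high case_pct
#> 1        1      89      77358      1.000       NA        NA   20.941
#> 2        2     101      77529      1.132    0.851     1.506   23.765
#> 3        3     106      77701      1.186    0.894     1.572   24.941
#> 4        4     129      77588      1.445    1.103     1.894   30.353
```

Participants in the top T2DM-liability quartile hold 30.4% of thyroid
cancer cases against 25.0% of controls: crude OR 1.45 (1.10–1.89)
versus quartile 1, matching the published adjusted estimate to two
decimals.

Two-sample MR under directional pleiotropy (true causal effect 0.2,
i.e. OR 1.22 per SD; mean direct effect 0.004 per allele):

```r
specs <- variant_panel("BMI", seed = 1)          # 73 instruments
ss <- simulate_summary_stats(specs, causal_effect = 0.2, n_exp = 1e6,
                             n_out = 2e5, pleiotropy_mode = "directional",
                             pleiotropy_mean = 0.004, pleiotropy_sd = 0.004,
                             seed = 2)
mr_all_methods(harmonize(ss), n_boot = 1000, seed = 3)
#> ivw                       OR 1.43 (1.39-1.48)  p = 1.4 x 10^-91
#> egger                     OR 1.27 (1.03-1.55)  p = 0.026
#> weighted_median           OR 1.39 (1.31-1.48)  p = 5.0 x 10^-28
#> penalized_weighted_median OR 1.36 (1.24-1.48)  p = 4.2 x 10^-12
```

IVW absorbs the pleiotropic offset and overshoots (1.43), while the
Egger slope stays near the truth and the median estimators land in
between — the textbook sensitivity pattern.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on the
generator and write tables under `results/`:

1. `01_simulate_cohort.R` — benign (0.5%) and cancer (0.1%) cohorts of
   50 000 with a latent confounder and no causal effect;
2. `02_build_cohort.R` — registry phenotyping with an exclusion audit;
3. `03_grs_observational.R` — scores, F statistics, per-SD
   observational associations;
4. `04_mr_one_sample.R` — two-stage MR, sensitivity exclusion, quartile
   contrasts;
5. `05_mr_two_sample.R` — all four estimators under none / balanced /
   directional pleiotropy;
6. `06_report.R` — the one-command `run_pipeline()` demo plus the
   published-count reproduction.

The methods vignette
(`vignettes/adiposity-thyroid-mr-methods.Rmd`) documents the model,
parameter defaults, numerical choices, and the estimators' validity
regimes.

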