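---
title: "Methods: Mendelian randomization of adiposity traits on thyroid neoplasia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mendelian randomization of adiposity traits on thyroid neoplasia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The question and the causal model

Observational studies report that obesity and type 2 diabetes (T2DM)
associate with benign nodular thyroid disease and with differentiated
thyroid cancer, but such associations are vulnerable to confounding and
reverse causality (for example, heavier patients are screened more, and
thyroid dysfunction affects weight). Mendelian randomization (MR) uses
genetic variants as instrumental variables: because alleles are assigned
at conception, a genetic predictor of adiposity cannot be confounded by
later-life factors, and if adiposity truly causes thyroid neoplasia the
adiposity-raising alleles must also associate with the outcome.

The package implements that full chain for registry-phenotyped, rare
binary outcomes:

1. a synthetic-cohort generator with the assumed causal structure
   (genotypes → exposure ← confounder → outcome ← exposure), so every
   downstream stage is testable without restricted biobank data;
2. an ICD-10 phenotyping rule engine (cases, outcome-specific controls,
   exclusions, the questionnaire T2DM definition);
3. weighted genetic risk scores (GRS) with instrument-strength checks
   and liability quartiles;
4. covariate-adjusted observational logistic associations per SD of
   exposure;
5. one-sample MR: two-stage estimation with sandwich standard errors,
   plus the GRS-quartile analysis used for binary exposures;
6. two-sample MR on harmonized summary statistics: inverse-variance
   weighted (IVW), MR-Egger, weighted median (WM), and penalized
   weighted median (PWM).

## What the generator emulates — and what it does not

`simulate_cohort()` draws, in a fixed order under one seed: genotypes as
binomial(2, eaf) dosages (Hardy–Weinberg, no linkage disequilibrium, no
relatedness, no population structure); a standard-normal latent
confounder `U`; a continuous exposure `GRS + b_U·U + noise`,
standardized to mean 0, SD 1; a binary outcome from a logistic model
whose intercept is root-found (`uniroot` on the marginal mean of the
logistic link) so the realized prevalence matches the target — the
source study reports prevalences, never intercepts; registry diagnosis
rows consistent with outcome status, plus low-rate unrelated cancer
(C50), thyroid-dysfunction (E03/E05) and toxic-nodule codes so the
phenotyping rules and sensitivity exclusions have genuine work; and
covariates (age 40–69, sex, smoking, alcohol, Townsend index,
assessment centre, genotyping platform, five principal components)
drawn independently of everything else.

Defaults are the study conditions: 50 000 participants per simulated
cohort (scaled down from ~380 000 to keep runs in minutes), outcome
prevalence 0.5% (benign nodular disease) or 0.1% (thyroid cancer), a
73-variant BMI panel (14 for favourable adiposity) with frequencies
uniform on (0.05, 0.95) and positive per-allele weights sized so the
panel explains ≈1.5% of exposure variance — the regime in which the
first-stage F statistic clears the conventional bar of 10 by a wide
margin at these sample sizes. Per-variant weights and frequencies of
the real instruments are not public inputs, so they are declared
defaults, not estimates. Confounder effects default to +0.3 SD on the
exposure and +0.4 log-odds on the outcome: strong enough that the
observational association is visibly biased away from a null causal
effect, weak enough to be epidemiologically plausible.

Because covariates are independent of exposure and outcome, passing
tests demonstrate the estimators' statistical properties, not
robustness to covariate-driven selection, population stratification, or
linkage disequilibrium — all deliberately out of scope.

`simulate_summary_stats()` draws exposure betas around the panel's true
effects with SE `1/sqrt(2·eaf·(1−eaf)·n)` and outcome betas as
`causal_effect × true beta + α_j + noise`; the direct effects `α_j` are
zero (`none`), mean-zero normal (`balanced`), or normal with nonzero
mean (`directional` — the violation MR-Egger's intercept estimates).

## Phenotyping rules and their edge cases

- Thyroid cancer: ≥1 C73 record with papillary or follicular histology;
  the earliest eligible date is the index (recurrences and duplicates
  collapse). Any C73 record with medullary, anaplastic, lymphoma or
  unspecified histology excludes the participant outright — these
  subtypes have different etiology, and we read "had a diagnosis of"
  as any record, so a mixed papillary+medullary history is excluded.
- Benign nodular disease: ≥1 non-toxic D34 record; any toxic record
  excludes.
- Dual diagnosis: cancer and benign index dates strictly closer than
  the window (12 months by default, converted at 365.25/12 days per
  month) remove the participant from both analyses as diagnostic
  uncertainty; a gap exactly at the boundary is retained. A remote
  benign history before cancer keeps both statuses — and by default the
  benign index event also stays in the benign analysis, since the
  source rules do not say otherwise; the window parameter makes the
  alternative a one-line sensitivity analysis.
- Controls are outcome-specific: cancer controls have no C-prefixed
  code of any kind; benign controls no D34 record, toxic or not.
- T2DM: self-report and age at diagnosis ≥35 and no first-year insulin
  and diagnosis ≥1 year before enrollment. Missing subfields fail the
  criterion rather than being imputed — conservative, matching an
  exclusion-based definition.

## Scores, quartiles, and the observational model

The GRS is `Σ β_j d_j` with weights oriented to the trait-increasing
allele (negative weights are flipped together with `2 − dosage`), and is
rescaled to allele-count units by `× n_variants / Σ β_j` — the standard
convention; the rescaled score is invariant to multiplying all weights
by a positive constant. Quartile cut points come from the pooled scored
population (cases and controls together; whether the original analysis
cut on controls only is not stated, and pooling reproduces the near-25%
control split of the published quartile table). Boundary values join
the lower quartile.

Observational associations are maximum-likelihood logistic fits with
Wald 95% intervals (matching the OR-and-CI reporting style throughout),
per-SD scaling using the analysis population's own SD (reported
alongside, e.g. 4.8 kg/m² per SD of BMI), a rank-based inverse normal
transform (`qnorm((rank − 0.5)/n)`, average ranks for ties) for skewed
covariates such as alcohol intake, complete-case covariate handling,
a 10-case minimum, and an explicit error on separation.

## One-sample MR

Stage 1 regresses the exposure on the GRS plus covariates (age, sex,
assessment centre, genotyping platform, principal components); stage 2
regresses the outcome on the stage-1 fitted values plus the same
covariates, logistic for binary outcomes. We use predictor substitution
— the standard two-stage approach for binary outcomes — with a
control-function variant (adding the first-stage residuals) behind a
flag, since the original wording ("predicted values and residuals …
used … as the independent variable") is ambiguous. The causal
coefficient's standard error is the HC1 sandwich, acknowledging the
estimated regressor; a first-stage F below 10 attaches a warning rather
than failing. One-sample MR is deliberately not offered for binary
exposures such as T2DM (ratio estimates for binary exposures are hard
to interpret); the GRS-quartile logistic contrast, with quartile 1
fixed at OR 1.00 and crude cross-product ORs reported beside the
adjusted ones, is the provided substitute.

## Two-sample MR

Harmonization orients every variant to the exposure-increasing allele
(both betas sign-flipped, alleles swapped), reconciles outcome-study
allele columns when present (flipping on swapped reports, failing
loudly on genuine mismatches), and keeps or drops palindromic A/T and
C/G variants by policy (kept by default; the simulated data carry no
strand ambiguity).

- IVW: closed-form weighted regression through the origin with weights
  `1/se_out²`; fixed-effect SE by default because the source reports
  single IVW estimates without heterogeneity inflation, with a
  multiplicative random-effects option; Cochran's Q attached.
- MR-Egger: weighted regression with a free intercept; the intercept is
  the average directional pleiotropy and its p-value the pleiotropy
  test; SEs use the conventional floor on the residual scale (no
  under-dispersion) and t inference on m − 2 degrees of freedom.
- WM: the interpolated 50% point of the inverse-variance-weighted
  empirical distribution of per-variant Wald ratios (weights
  `β_x²/se_out²`), consistent while valid instruments hold >50% of the
  weight; SE by parametric bootstrap (default 1000 resamples, seed
  required).
- PWM: per-variant heterogeneity `Q_j = w_j (ratio_j − β_WM)²` referred
  to χ²₁; weights multiplied by `min(1, 20·p_j)` (penalty constant 20,
  configurable), then the WM procedure re-applied. Concordant variants
  are untouched; gross outliers lose essentially all weight.

## Numerical choices and validity regimes

Simulation scales were chosen so the whole test suite runs in minutes:
cohorts of 20 000–50 000, 100 replicate cohorts for one-sample CI
coverage, 50 seeds for two-sample recovery, 400 runs for test-level
calibration.

Two regime choices deserve emphasis because they are properties of the
estimators, not of this implementation:

- *Strong instruments for two-sample calibration.* IVW and Egger
  consistency and the Egger intercept test's nominal level presuppose
  negligible error in the exposure betas (the NOME condition). Our
  calibration simulations therefore use an exposure GWAS of n = 10⁶.
  At realistic discovery sizes (tens of thousands), per-variant z
  scores of 3–10 produce a few percent of regression-dilution
  attenuation and a measurably anticonservative intercept test (~8%
  at nominal 5% in our setting) — a known weak-instrument limitation
  worth remembering when reading real applications.
- *Weight share for median robustness.* The weighted median tolerates
  up to 50% invalid **weight**. Forty percent of instruments by count
  can carry anywhere from ~25% to >50% of the weight depending on which
  instruments they are; at the boundary the estimator sits at its
  breakdown point and acquires a finite-sample quantile-shift bias of
  the same order as its bootstrap SE. The contamination demonstration
  therefore corrupts the 40% of instruments with the smallest weights
  (~11% of total weight), where the guarantee genuinely applies.

Other numerics: prevalence intercepts are root-found to |f| ≤ 1e−10 on
a bracket of (−40, 10); degenerate inputs fail loudly (constant scores,
zero-variance traits, empty quartiles, <3 instruments for Egger/WM,
separation); exact (noise-free) Egger fits report SE 0 rather than
dividing by a zero residual scale; all seeded draws restore the
caller's RNG state, so nested simulations cannot silently share
streams.

## Known limitations

No linkage disequilibrium, relatedness, or ancestry structure; no
mixed-model GWAS stage (summary statistics come from the generator);
covariates carry no confounding signal, so covariate adjustment is
exercised mechanically, not epidemiologically; bootstrap SEs for the
median estimators ignore between-variant correlation (none exists in
the generator); and the registry simulator writes one diagnosis per
case, so duplicate-collapse logic is exercised only by the bundled
fixtures.
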