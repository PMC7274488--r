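#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Two individual-level cohorts (benign nodular thyroid disease at ~0.5%
# prevalence, differentiated thyroid cancer at ~0.1%) of 50 000 unrelated
# participants each, instrumented by the default 73-variant BMI panel,
# with a latent confounder acting on both exposure and outcome and no
# true causal effect — the regime in which observational and MR analyses
# should disagree. Writes genotype, participant, diagnosis and weight
# tables under results/data/.

library(thyromr)

for (oc in c("benign", "cancer")) {
  cfg <- sim_config(n_participants = 50000L, causal_effect = 0,
                    confounder_effect_on_exposure = 0.3,
                    confounder_effect_on_outcome = 0.4,
                    outcome = oc, seed = if (oc == "benign") 101L else 102L)
  cohort <- simulate_cohort(cfg)
  dir <- file.path("results", "data", oc)
  write_cohort(cohort, dir)
  message(sprintf(
    "%s cohort: n = %d, %d variants, realized prevalence %.3f%% (target %.3f%%)",
    oc, nrow(cohort$participants), ncol(cohort$genotypes),
    100 * cohort$truth$realized_prevalence,
    100 * cfg$outcome_baseline_prevalence))
}
message("inputs written under results/data/")
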