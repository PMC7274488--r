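#!/usr/bin/env Rscript
# Stage 3: genetic risk scores, instrument strength, and the
# covariate-adjusted observational association.
#
# Scores each cohort with the weighted BMI panel, checks the first-stage
# F statistic (the weak-instrument bar is F > 10), assigns liability
# quartiles on the pooled population, and fits the per-SD observational
# logistic association. Because the generator put a confounder on both
# equations and no causal effect, the observational odds ratio should
# sit above 1 — the bias MR is meant to remove.

library(thyromr)

obs_rows <- list()
for (oc in c("benign", "cancer")) {
  dir <- file.path("results", "data", oc)
  participants <- read.csv(file.path(dir, "participants.csv"),
                           stringsAsFactors = FALSE)
  specs <- read_variant_weights(file.path(dir, "variant_weights.tsv"))
  g <- as.matrix(read.delim(file.path(dir, "genotypes.tsv"),
                            row.names = 1, check.names = FALSE))
  grs <- compute_weighted_grs(g, specs)
  grs$quartile <- assign_quartiles(grs$raw_score)
  write.csv(grs, file.path("results", sprintf("grs_%s.csv", oc)),
            row.names = FALSE)

  f <- instrument_strength(grs$raw_score, participants$exposure,
                           covariates = participants[
                             c("age_at_recruitment", "sex")])
  message(sprintf("[%s] first-stage F = %.1f (partial R2 = %.2f%%)",
                  oc, f$F, 100 * f$r_squared_partial))

  asn <- read.csv(file.path("results", sprintf("assignments_%s.csv", oc)),
                  stringsAsFactors = FALSE)
  a <- asn[asn$outcome == oc, ]
  d <- merge(participants, a[c("participant_id", "status")])
  d <- d[d$status != "excluded", ]
  d$case <- as.integer(d$status == "case")
  fit <- logistic_association(d, "case", "exposure",
                              covariates = c("age_at_recruitment", "sex",
                                             "smoking", "alcohol_units",
                                             "townsend"))
  fit$trait <- "exposure (per SD)"
  obs_rows[[oc]] <- fit
  message(sprintf("[%s] observational OR per SD: %s (p = %s)", oc,
                  format_or_ci(fit$odds_ratio, fit$ci95_low, fit$ci95_high),
                  format_p(fit$p_value)))
}
obs <- do.call(rbind, obs_rows)
write.csv(obs, "results/observational.csv", row.names = FALSE)
writeLines(format_results_table(obs, layout = "observational"),
           "results/observational_table.tsv")
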