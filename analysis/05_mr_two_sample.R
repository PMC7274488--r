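#!/usr/bin/env Rscript
# Stage 5: two-sample summary-statistic Mendelian randomization.
#
# Simulates harmonizable exposure/outcome GWAS summary statistics for
# the BMI panel under three pleiotropy regimes — none, balanced, and
# directional — and applies all four estimators (IVW, MR-Egger,
# weighted median, penalized weighted median). The true causal effect
# is 0.2 throughout. Under directional pleiotropy IVW should drift
# while the Egger intercept flags the offset and the median estimators
# stay near the truth.

library(thyromr)

specs <- variant_panel("BMI", seed = 101L)
tables <- list()
for (mode in c("none", "balanced", "directional")) {
  ss <- simulate_summary_stats(
    specs, causal_effect = 0.2, n_exp = 1e6, n_out = 200000,
    pleiotropy_mode = mode,
    pleiotropy_mean = if (mode == "directional") 0.004 else 0,
    pleiotropy_sd = if (mode == "none") 0 else 0.004,
    seed = 200L + match(mode, c("none", "balanced", "directional")))
  write_summary_stats(ss, file.path("results",
                                    sprintf("summary_stats_%s.tsv", mode)))
  res <- mr_all_methods(ss, n_boot = 1000, seed = 300L)
  res$pleiotropy <- mode
  tables[[mode]] <- res
  eg <- res[res$method == "egger", ]
  message(sprintf("[%s] IVW %s | Egger %s (intercept p = %s) | WM %s | PWM %s",
                  mode,
                  format_or_ci(res$or[1], res$ci95_low[1], res$ci95_high[1]),
                  format_or_ci(eg$or, eg$ci95_low, eg$ci95_high),
                  format_p(eg$egger_intercept_p),
                  format_or_ci(res$or[3], res$ci95_low[3], res$ci95_high[3]),
                  format_or_ci(res$or[4], res$ci95_low[4], res$ci95_high[4])))
}
flat <- do.call(rbind, tables)
write.csv(flat, "results/mr_two_sample.csv", row.names = FALSE)
writeLines(format_results_table(tables, layout = "two_sample_mr"),
           "results/mr_two_sample_table.tsv")
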