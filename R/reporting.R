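#' Pipeline configuration
#'
#' Bundles everything [run_pipeline()] needs: the simulation settings
#' (or paths to pre-existing inputs), analysis toggles, and one root
#' seed from which all stage seeds are derived in a fixed order.
#'
#' @param outdir Output directory for result CSVs and the run log.
#' @param seed Root integer seed.
#' @param n_participants Cohort size for the simulated stages.
#' @param outcome `"benign"` or `"cancer"`.
#' @param causal_effect True causal log-OR per SD used by the generator.
#' @param prevalence Target outcome prevalence.
#' @param run_observational,run_mr1s,run_mr2s,run_sensitivity Stage
#'   toggles.
#' @param n_boot Bootstrap resamples for the median estimators.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L, n_participants = 50000L,
                            outcome = c("benign", "cancer"),
                            causal_effect = 0, prevalence = NULL,
                            run_observational = TRUE, run_mr1s = TRUE,
                            run_mr2s = TRUE, run_sensitivity = TRUE,
                            n_boot = 1000L) {
  outcome <- match.arg(outcome)
  if (is.null(prevalence)) {
    prevalence <- if (outcome == "benign") 0.005 else 0.001
  }
  structure(list(outdir = outdir, seed = as.integer(seed),
                 n_participants = as.integer(n_participants),
                 outcome = outcome, causal_effect = causal_effect,
                 prevalence = prevalence,
                 run_observational = run_observational,
                 run_mr1s = run_mr1s, run_mr2s = run_mr2s,
                 run_sensitivity = run_sensitivity,
                 n_boot = as.integer(n_boot)),
            class = "pipeline_config")
}

log_line <- function(con, fmt, ...) {
  msg <- sprintf(fmt, ...)
  writeLines(msg, con)
  message(msg)
}

#' Run the full pipeline
#'
#' Simulate a cohort, build case/control assignments, score the
#' instrument panel, and run the enabled observational, one-sample MR,
#' and two-sample MR stages, writing one CSV per stage plus a run log
#' (seeds and counts at every filter step) under `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(config$outdir, "run_log.txt"), "w")
  on.exit(close(logf))
  res <- list()
  log_line(logf, "pipeline seed %d, n = %d, outcome = %s",
           config$seed, config$n_participants, config$outcome)

  cfg <- sim_config(n_participants = config$n_participants,
                    causal_effect = config$causal_effect,
                    outcome_baseline_prevalence = config$prevalence,
                    outcome = config$outcome, seed = config$seed)
  cohort <- simulate_cohort(cfg)
  log_line(logf, "simulated cohort: %d participants, %d variants, %.4g%% cases",
           nrow(cohort$participants), ncol(cohort$genotypes),
           100 * cohort$truth$realized_prevalence)

  asn <- build_cohort_assignments(cohort$participants, cohort$diagnoses)
  utils::write.csv(rbind(asn$cancer, asn$benign),
                   file.path(config$outdir, "assignments.csv"),
                   row.names = FALSE)
  for (i in seq_len(nrow(asn$log))) {
    log_line(logf, "%s analysis: %d cases, %d controls, %d excluded",
             asn$log$outcome[i], asn$log$n_case[i], asn$log$n_control[i],
             asn$log$n_excluded[i])
  }
  res$assignments <- asn

  grs <- compute_weighted_grs(cohort$genotypes, cohort$specs)
  grs$quartile <- assign_quartiles(grs$raw_score)
  utils::write.csv(grs, file.path(config$outdir, "grs_profiles.csv"),
                   row.names = FALSE)
  res$grs <- grs

  a <- if (config$outcome == "benign") asn$benign else asn$cancer
  dat <- merge(cohort$participants, a[c("participant_id", "status")],
               by = "participant_id")
  dat <- merge(dat, asn$t2dm, by = "participant_id")
  dat <- merge(dat, grs[c("participant_id", "raw_score", "quartile")],
               by = "participant_id")
  dat <- dat[dat$status != "excluded", ]
  dat$case <- as.integer(dat$status == "case")
  log_line(logf, "analysis table: %d rows after exclusions", nrow(dat))

  if (config$run_observational) {
    obs <- logistic_association(dat, "case", "exposure")
    utils::write.csv(obs, file.path(config$outdir, "observational.csv"),
                     row.names = FALSE)
    log_line(logf, "observational OR per SD exposure: %s",
             format_or_ci(obs$odds_ratio, obs$ci95_low, obs$ci95_high))
    res$observational <- obs
  }

  if (config$run_mr1s) {
    mr1 <- two_stage_mr(dat, "case", "exposure", "raw_score")
    log_line(logf, "one-sample two-stage MR (F = %.1f): %s",
             attr(mr1, "first_stage_F"),
             format_or_ci(mr1$or, mr1$ci95_low, mr1$ci95_high))
    qa <- quartile_association(dat, "case", "quartile")
    utils::write.csv(qa$adjusted,
                     file.path(config$outdir, "quartile_mr.csv"),
                     row.names = FALSE)
    res$mr_one_sample <- mr1
    res$quartiles <- qa
    if (config$run_sensitivity) {
      a2 <- sensitivity_exclude_thyroid_dysfunction(a, cohort$diagnoses)
      log_line(logf, "sensitivity exclusion removed %d participants",
               attr(a2, "n_removed"))
      dat2 <- dat[dat$participant_id %in%
                    a2$participant_id[a2$status != "excluded"], ]
      res$mr_one_sample_sensitivity <-
        two_stage_mr(dat2, "case", "exposure", "raw_score")
    }
  }

  if (config$run_mr2s) {
    ss <- simulate_summary_stats(cohort$specs, config$causal_effect,
                                 n_exp = 300000L, n_out = 400000L,
                                 seed = config$seed + 1L)
    write_summary_stats(ss, file.path(config$outdir, "summary_stats.tsv"))
    mr2 <- mr_all_methods(ss, n_boot = config$n_boot,
                          seed = config$seed + 2L)
    utils::write.csv(mr2[c("method", "beta", "se", "or", "ci95_low",
                           "ci95_high", "p", "egger_intercept",
                           "egger_intercept_p")],
                     file.path(config$outdir, "mr_two_sample.csv"),
                     row.names = FALSE)
    for (i in seq_len(nrow(mr2))) {
      log_line(logf, "two-sample %s: %s", mr2$method[i],
               format_or_ci(mr2$or[i], mr2$ci95_low[i], mr2$ci95_high[i]))
    }
    res$mr_two_sample <- mr2
  }
  invisible(res)
}

#' Render results in the published table layouts
#'
#' Formats result objects as delimited text mirroring the journal
#' tables: odds ratios to two decimals, intervals as `"(low-high)"`,
#' p-values in scientific notation below 0.001.
#'
#' `"observational"` expects stacked [logistic_association()] rows;
#' `"two_sample_mr"` a named list of [mr_all_methods()] tables (one per
#' trait); `"quartile"` the output of [quartile_association()].
#'
#' @param results The result object for the layout.
#' @param layout One of `"observational"`, `"two_sample_mr"`,
#'   `"quartile"`.
#' @return A character vector of tab-separated lines.
#' @export
format_results_table <- function(results,
                                 layout = c("observational", "two_sample_mr",
                                            "quartile")) {
  layout <- match.arg(layout)
  tsv <- function(...) paste(c(...), collapse = "\t")
  if (layout == "observational") {
    lines <- tsv("Trait", "OR", "95% CI", "P Value")
    for (i in seq_len(nrow(results))) {
      r <- results[i, ]
      lines <- c(lines, tsv(r$trait, sprintf("%.2f", r$odds_ratio),
                            sprintf("%.2f-%.2f", r$ci95_low, r$ci95_high),
                            format_p(r$p_value)))
    }
    return(lines)
  }
  if (layout == "two_sample_mr") {
    header <- tsv("Trait", "IVW OR (95% CI)", "P Value",
                  "Egger OR (95% CI)", "P Value", "Int p",
                  "WM OR (95% CI)", "P Value", "PWM OR (95% CI)",
                  "P Value")
    lines <- header
    cell <- function(m, tab) {
      r <- tab[tab$method == m, ]
      if (nrow(r) != 1) {
        warning(sprintf("method %s missing from results", m))
        return(c("", ""))
      }
      c(format_or_ci(r$or, r$ci95_low, r$ci95_high), format_p(r$p))
    }
    for (trait in names(results)) {
      tab <- results[[trait]]
      eg <- tab[tab$method == "egger", ]
      intp <- if (nrow(eg)) format_p(eg$egger_intercept_p) else ""
      lines <- c(lines, tsv(trait, cell("ivw", tab), cell("egger", tab),
                            intp, cell("weighted_median", tab),
                            cell("penalized_weighted_median", tab)))
    }
    return(lines)
  }
  adj <- results$adjusted
  lines <- tsv("Quartiles", "Cases", "Controls", "OR (95% CI)", "P")
  for (i in seq_len(nrow(adj))) {
    r <- adj[i, ]
    orcell <- if (r$quartile == 1) "1.00" else {
      format_or_ci(r$odds_ratio, r$ci95_low, r$ci95_high)
    }
    lines <- c(lines, tsv(r$quartile,
                          sprintf("%d (%.1f)", r$n_cases,
                                  100 * r$n_cases / sum(adj$n_cases)),
                          r$n_controls, orcell,
                          if (is.na(r$p)) "" else format_p(r$p)))
  }
  lines
}
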