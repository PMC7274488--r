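#' Simulate genotype dosages under Hardy-Weinberg equilibrium
#'
#' Each variant's dosage column is an independent draw of the count of
#' effect alleles, binomial(2, eaf) per participant. No linkage
#' disequilibrium or relatedness structure is modelled: the panel is meant
#' to emulate independent, LD-pruned instruments in unrelated individuals.
#'
#' @param specs A [variant_spec()] table.
#' @param n Number of participants (>= 1).
#' @param seed Integer seed; the same seed reproduces the same matrix.
#' @return Integer matrix, `n` rows (participants, named `id000001`, ...)
#'   by `nrow(specs)` columns (variant ids), dosages in `{0, 1, 2}`.
#' @examples
#' g <- simulate_genotypes(variant_panel("FA"), n = 100, seed = 7)
#' range(g)  # within [0, 2]
#' @export
simulate_genotypes <- function(specs, n, seed = 1L) {
  specs <- validate_variant_spec(specs)
  assert_that(is_count(n) && n >= 1, "n must be a positive count")
  g <- with_seed(seed, {
    vapply(specs$eaf, function(p) stats::rbinom(n, 2L, p), integer(n))
  })
  if (n == 1L) g <- matrix(g, nrow = 1L)
  dimnames(g) <- list(sprintf("id%06d", seq_len(n)), specs$variant_id)
  g
}

#' Configuration for a synthetic cohort
#'
#' Bundles the generative parameters for [simulate_cohort()]. Defaults
#' emulate the study conditions: a large unrelated adult cohort with a
#' rare registry-ascertained outcome (benign nodular thyroid disease at
#' about 0.5% prevalence, differentiated thyroid cancer at about 0.1%),
#' a polygenic continuous exposure, and a shared latent confounder acting
#' on both exposure and outcome.
#'
#' @param n_participants Cohort size.
#' @param specs Instrument panel ([variant_spec()]); default the 73-variant
#'   BMI panel.
#' @param causal_effect True causal log-odds of the outcome per SD exposure.
#' @param confounder_effect_on_exposure Effect of the standard-normal latent
#'   confounder U on the exposure, SD units.
#' @param confounder_effect_on_outcome Effect of U on the outcome, log-odds.
#' @param outcome_baseline_prevalence Target marginal outcome prevalence;
#'   defaults to 0.005 for the benign outcome and 0.001 for cancer.
#' @param outcome One of `"benign"` (D34 registry codes) or `"cancer"`
#'   (C73 with papillary/follicular histology) for the records written for
#'   simulated cases.
#' @param pleiotropy_mode,pleiotropy_mean,pleiotropy_sd Horizontal
#'   pleiotropy of the instruments on the outcome: `"none"`, `"balanced"`
#'   (zero-mean direct effects), or `"directional"`.
#' @param t2dm_prevalence Fraction given a qualifying type 2 diabetes
#'   self-report (for exercising the diabetes status rules).
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_participants = 50000L,
                       specs = variant_panel("BMI"),
                       causal_effect = 0,
                       confounder_effect_on_exposure = 0.3,
                       confounder_effect_on_outcome = 0.4,
                       outcome_baseline_prevalence = NULL,
                       outcome = c("benign", "cancer"),
                       pleiotropy_mode = c("none", "balanced", "directional"),
                       pleiotropy_mean = 0, pleiotropy_sd = 0,
                       t2dm_prevalence = 0.03,
                       seed = 1L) {
  assert_that(is_count(n_participants) && n_participants >= 1,
              "n_participants must be >= 1")
  outcome <- match.arg(outcome)
  if (is.null(outcome_baseline_prevalence)) {
    outcome_baseline_prevalence <- if (outcome == "benign") 0.005 else 0.001
  }
  assert_that(outcome_baseline_prevalence > 0 &&
                outcome_baseline_prevalence < 1,
              "outcome_baseline_prevalence must lie in (0, 1)")
  assert_that(pleiotropy_sd >= 0, "pleiotropy_sd must be >= 0")
  cfg <- list(
    n_participants = as.integer(n_participants),
    specs = validate_variant_spec(specs),
    causal_effect = causal_effect,
    confounder_effect_on_exposure = confounder_effect_on_exposure,
    confounder_effect_on_outcome = confounder_effect_on_outcome,
    outcome_baseline_prevalence = outcome_baseline_prevalence,
    outcome = outcome,
    pleiotropy_mode = match.arg(pleiotropy_mode),
    pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd,
    t2dm_prevalence = t2dm_prevalence,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

# Root-find the logistic intercept whose marginal mean prevalence over the
# realized linear predictor equals the target.
calibrate_intercept <- function(eta, target) {
  f <- function(a) mean(stats::plogis(a + eta)) - target
  stats::uniroot(f, lower = -40, upper = 10, tol = 1e-10)$root
}

#' Simulate an individual-level cohort with registry records
#'
#' Generates, in a documented draw order (genotypes, confounder, exposure
#' noise, outcome, pleiotropic variant effects, covariates, registry
#' dates): a genotype matrix; a standardized continuous exposure
#' `weighted allele score + confounder effect * U + noise` scaled to mean
#' 0, SD 1; a binary outcome from a logistic model whose intercept is
#' root-found so the marginal prevalence matches the target; registry
#' diagnosis rows consistent with outcome status (plus a sprinkling of
#' unrelated cancer, thyroid-dysfunction and toxic-nodule codes so the
#' phenotyping rules have work to do); and independent covariates (age
#' 40-69, sex, smoking, alcohol, Townsend index, assessment centre,
#' genotyping platform, five principal components).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_cohort` with elements `genotypes`,
#'   `participants`, `diagnoses`, `specs`, and `truth` (the generative
#'   parameters plus the realized prevalence and calibrated intercept).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_participants
  specs <- config$specs
  with_seed(config$seed, simulate_cohort_impl(config, n, specs))
}

simulate_cohort_impl <- function(config, n, specs) {

  g <- vapply(specs$eaf, function(p) stats::rbinom(n, 2L, p), integer(n))
  if (n == 1L) g <- matrix(g, nrow = 1L)
  ids <- sprintf("id%06d", seq_len(n))
  dimnames(g) <- list(ids, specs$variant_id)

  u <- stats::rnorm(n)
  raw_grs <- as.numeric(g %*% specs$beta)
  var_grs <- sum(specs$beta^2 * 2 * specs$eaf * (1 - specs$eaf))
  sigma2 <- max(1 - var_grs - config$confounder_effect_on_exposure^2, 0.1)
  exposure <- raw_grs + config$confounder_effect_on_exposure * u +
    stats::rnorm(n, sd = sqrt(sigma2))
  if (n >= 2 && stats::sd(exposure) > 0) {
    exposure <- as.numeric(scale(exposure))
  }

  # direct (pleiotropic) variant effects on the outcome, bypassing exposure
  alpha <- switch(config$pleiotropy_mode,
    none = rep(0, nrow(specs)),
    balanced = stats::rnorm(nrow(specs), 0, config$pleiotropy_sd),
    directional = stats::rnorm(nrow(specs), config$pleiotropy_mean,
                               config$pleiotropy_sd)
  )
  eta <- config$causal_effect * exposure +
    config$confounder_effect_on_outcome * u +
    as.numeric(g %*% alpha)
  a0 <- calibrate_intercept(eta, config$outcome_baseline_prevalence)
  y <- stats::rbinom(n, 1L, stats::plogis(a0 + eta))
  if (sum(y) == 0L) {
    stopf(paste("no cases realized at n = %d and prevalence %.4g;",
                "increase n_participants"), n,
          config$outcome_baseline_prevalence)
  }

  participants <- data.frame(
    participant_id = ids,
    sex = sample(c("F", "M"), n, replace = TRUE, prob = c(0.54, 0.46)),
    age_at_recruitment = sample(40:69, n, replace = TRUE),
    enrollment_date = as.Date("2006-03-01") +
      sample.int(1700, n, replace = TRUE),
    exposure = exposure,
    outcome = y,
    bmi = 27.4 + 4.8 * exposure,
    whr = pmax(0.6, 0.86 + 0.09 * stats::rnorm(n)),
    hdl = pmax(0.3, 1.45 + 0.38 * stats::rnorm(n)),
    ldl = pmax(0.5, 3.56 + 0.87 * stats::rnorm(n)),
    tg = exp(stats::rnorm(n, 0.4, 0.5)),
    glucose = pmax(2, 5.1 + 1.2 * stats::rnorm(n)),
    smoking = sample(c("never", "former", "current", "missing"), n,
                     replace = TRUE, prob = c(0.545, 0.35, 0.092, 0.013)),
    alcohol_units = stats::rlnorm(n, 1.8, 1.0),
    townsend = stats::rnorm(n, -1.4, 3.0),
    assessment_centre = sample(sprintf("centre%02d", 1:22), n, replace = TRUE),
    genotyping_platform = sample(c("axiom", "bileve"), n, replace = TRUE,
                                 prob = c(0.9, 0.1)),
    stringsAsFactors = FALSE
  )
  for (k in 1:5) participants[[paste0("pc", k)]] <- stats::rnorm(n)

  # self-reported diabetes fields; a fraction of reporters fail each of the
  # age/insulin/recency criteria so the status rules are exercised
  sr <- stats::runif(n) < config$t2dm_prevalence * 1.4
  participants$self_report_diabetes <- sr
  participants$age_at_diabetes_diagnosis <- NA_real_
  participants$insulin_within_first_year <- NA
  nsr <- sum(sr)
  if (nsr > 0) {
    participants$age_at_diabetes_diagnosis[sr] <-
      sample(c(25:34, 35:68), nsr, replace = TRUE,
             prob = c(rep(0.1 / 10, 10), rep(0.9 / 34, 34)))
    participants$insulin_within_first_year[sr] <- stats::runif(nsr) < 0.1
    participants$years_since_diabetes_diagnosis <- NA_real_
    participants$years_since_diabetes_diagnosis[sr] <-
      stats::rexp(nsr, 1 / 8)
  } else {
    participants$years_since_diabetes_diagnosis <- NA_real_
  }

  diagnoses <- simulate_registry_records(participants, config)

  structure(list(
    genotypes = g, participants = participants, diagnoses = diagnoses,
    specs = specs,
    truth = list(causal_effect = config$causal_effect,
                 intercept = a0,
                 realized_prevalence = mean(y),
                 pleiotropy = alpha)
  ), class = "sim_cohort")
}

# Registry rows: outcome-consistent thyroid codes for cases, plus low-rate
# unrelated cancers (C50), thyroid dysfunction (E03/E05) and toxic nodules.
simulate_registry_records <- function(participants, config) {
  n <- nrow(participants)
  rows <- list()
  case_idx <- which(participants$outcome == 1L)
  if (length(case_idx)) {
    if (config$outcome == "cancer") {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participants$participant_id[case_idx],
        icd10_code = "C73",
        diagnosis_date = participants$enrollment_date[case_idx] +
          sample.int(2500, length(case_idx), replace = TRUE),
        histology_class = sample(c("papillary", "follicular"),
                                 length(case_idx), replace = TRUE,
                                 prob = c(0.85, 0.15)),
        toxic_flag = FALSE, stringsAsFactors = FALSE)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = participants$participant_id[case_idx],
        icd10_code = "D34",
        diagnosis_date = participants$enrollment_date[case_idx] +
          sample.int(2500, length(case_idx), replace = TRUE),
        histology_class = "not_applicable",
        toxic_flag = FALSE, stringsAsFactors = FALSE)
    }
  }
  sprinkle <- function(code, rate, histology = "not_applicable",
                       toxic = FALSE) {
    idx <- which(stats::runif(n) < rate & participants$outcome == 0L)
    if (!length(idx)) return(NULL)
    data.frame(participant_id = participants$participant_id[idx],
               icd10_code = code,
               diagnosis_date = participants$enrollment_date[idx] +
                 sample.int(2500, length(idx), replace = TRUE),
               histology_class = histology, toxic_flag = toxic,
               stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1L]] <- sprinkle("C50", 0.01)
  rows[[length(rows) + 1L]] <- sprinkle("E03", 0.02)
  rows[[length(rows) + 1L]] <- sprinkle("E05", 0.005)
  rows[[length(rows) + 1L]] <- sprinkle("D34", 0.0005, toxic = TRUE)
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(participant_id = character(), icd10_code = character(),
                      diagnosis_date = as.Date(character()),
                      histology_class = character(), toxic_flag = logical(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$participant_id, out$diagnosis_date), , drop = FALSE]
}

#' Simulate two-sample GWAS summary statistics
#'
#' Draws harmonizable exposure and outcome association estimates for a
#' variant panel. Exposure betas are drawn around the panel's true
#' per-allele effects with standard errors `1 / sqrt(2 eaf (1 - eaf)
#' n_exp)`; outcome betas equal `causal_effect` times the true exposure
#' beta plus a per-variant direct (pleiotropic) effect and sampling noise
#' with the analogous standard error at `n_out`. Direct effects are zero
#' (`"none"`), mean-zero normal (`"balanced"`), or normal with nonzero
#' mean (`"directional"`, the case MR-Egger's intercept is built to
#' detect).
#'
#' @param specs A [variant_spec()] table (true per-allele exposure effects).
#' @param causal_effect True causal effect of the exposure on the outcome.
#' @param n_exp,n_out Effective GWAS sample sizes for the two studies.
#' @param pleiotropy_mode,pleiotropy_mean,pleiotropy_sd See [sim_config()].
#' @param seed Integer seed.
#' @return A `summary_stats` data.frame: `variant_id`, alleles, `beta_exp`,
#'   `se_exp`, `beta_out`, `se_out`, `harmonized = FALSE`.
#' @export
simulate_summary_stats <- function(specs, causal_effect, n_exp, n_out,
                                   pleiotropy_mode = c("none", "balanced",
                                                       "directional"),
                                   pleiotropy_mean = 0, pleiotropy_sd = 0,
                                   seed = 1L) {
  specs <- validate_variant_spec(specs)
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  assert_that(is_count(n_exp) && n_exp >= 2 && is_count(n_out) && n_out >= 2,
              "sample sizes must be counts >= 2")
  assert_that(pleiotropy_sd >= 0, "pleiotropy_sd must be >= 0")
  with_seed(seed, simulate_summary_stats_impl(specs, causal_effect, n_exp,
                                              n_out, pleiotropy_mode,
                                              pleiotropy_mean, pleiotropy_sd))
}

simulate_summary_stats_impl <- function(specs, causal_effect, n_exp, n_out,
                                        pleiotropy_mode, pleiotropy_mean,
                                        pleiotropy_sd) {
  m <- nrow(specs)
  info <- 2 * specs$eaf * (1 - specs$eaf)
  se_exp <- 1 / sqrt(info * n_exp)
  se_out <- 1 / sqrt(info * n_out)
  alpha <- switch(pleiotropy_mode,
    none = rep(0, m),
    balanced = stats::rnorm(m, 0, pleiotropy_sd),
    directional = stats::rnorm(m, pleiotropy_mean, pleiotropy_sd)
  )
  out <- data.frame(
    variant_id = specs$variant_id,
    effect_allele = specs$effect_allele,
    other_allele = specs$other_allele,
    beta_exp = specs$beta + stats::rnorm(m, 0, se_exp),
    se_exp = se_exp,
    beta_out = causal_effect * specs$beta + alpha +
      stats::rnorm(m, 0, se_out),
    se_out = se_out,
    harmonized = FALSE,
    stringsAsFactors = FALSE
  )
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Write the simulated cohort to delimited text
#'
#' Genotypes as TSV (header = variant ids, first column = participant id),
#' the participant table as CSV, diagnoses as CSV, and summary statistics
#' as TSV.
#'
#' @param cohort A `sim_cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gpath <- file.path(dir, "genotypes.tsv")
  g <- data.frame(participant_id = rownames(cohort$genotypes),
                  cohort$genotypes, check.names = FALSE)
  utils::write.table(g, gpath, sep = "\t", quote = FALSE, row.names = FALSE)
  ppath <- file.path(dir, "participants.csv")
  utils::write.csv(cohort$participants, ppath, row.names = FALSE)
  dpath <- file.path(dir, "diagnoses.csv")
  utils::write.csv(cohort$diagnoses, dpath, row.names = FALSE)
  wpath <- file.path(dir, "variant_weights.tsv")
  write_variant_weights(cohort$specs, wpath)
  invisible(c(genotypes = gpath, participants = ppath, diagnoses = dpath,
              weights = wpath))
}

#' @rdname write_cohort
#' @param stats A `summary_stats` table.
#' @param path Output TSV path.
#' @export
write_summary_stats <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_summary_stats <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (is.null(out$harmonized)) out$harmonized <- FALSE
  class(out) <- c("summary_stats", "data.frame")
  out
}
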