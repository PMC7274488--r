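# Default covariate set for genetic analyses: age, sex, assessment
# centre, genotyping platform and the first five principal components.
MR_COVARIATES <- c("age_at_recruitment", "sex", "assessment_centre",
                   "genotyping_platform", "pc1", "pc2", "pc3", "pc4", "pc5")

#' Two-stage one-sample Mendelian randomization
#'
#' Stage 1 regresses the continuous exposure on the genetic risk score
#' plus covariates by least squares and saves the fitted values — the
#' genetically predicted, unconfounded component of the exposure. Stage 2
#' regresses the outcome on those fitted values plus the same covariates:
#' logistic for a binary outcome (predictor substitution, the standard
#' two-stage approach for binary outcomes), linear for a continuous one.
#' The causal coefficient's standard error is the heteroskedasticity-
#' robust HC1 sandwich, acknowledging that the regressor is itself
#' estimated. A control-function variant (first-stage residuals added to
#' stage 2) is available behind a flag.
#'
#' A first-stage F below 10 attaches a weak-instrument warning to the
#' result rather than failing, mirroring how the check is reported in
#' practice.
#'
#' @param data Data frame with outcome, exposure, score and covariates.
#' @param outcome Binary (0/1) or continuous outcome column name.
#' @param exposure Continuous exposure column name (per-SD units).
#' @param grs Genetic risk score column name.
#' @param covariates Covariate column names; default [MR_COVARIATES]
#'   intersected with what is present.
#' @param family `"binomial"` (log-odds causal effect) or `"gaussian"`.
#' @param control_function Add first-stage residuals to stage 2.
#' @return An [mr_estimate()] (`method = "two_stage"`) with attributes
#'   `first_stage_F` and, when F < 10, `weak_instrument = TRUE`.
#' @export
two_stage_mr <- function(data, outcome, exposure, grs,
                         covariates = NULL,
                         family = c("binomial", "gaussian"),
                         control_function = FALSE) {
  family <- match.arg(family)
  if (is.null(covariates)) {
    covariates <- intersect(MR_COVARIATES, names(data))
  }
  covariates <- setdiff(covariates, c(outcome, exposure, grs))
  keep <- c(outcome, exposure, grs, covariates)
  data <- data[stats::complete.cases(data[keep]), keep, drop = FALSE]

  s1 <- stats::lm(stats::reformulate(c(grs, covariates),
                                     response = exposure), data = data)
  tval <- summary(s1)$coefficients[grs, "t value"]
  Fstat <- tval^2
  data$.fitted_exposure <- stats::fitted(s1)
  rhs <- c(".fitted_exposure", covariates)
  if (control_function) {
    data$.stage1_resid <- stats::resid(s1)
    rhs <- c(rhs, ".stage1_resid")
  }
  fml <- stats::reformulate(rhs, response = outcome)
  s2 <- if (family == "binomial") {
    stats::glm(fml, family = stats::binomial(), data = data)
  } else {
    stats::lm(fml, data = data)
  }
  vc <- sandwich::vcovHC(s2, type = "HC1")
  b <- stats::coef(s2)[".fitted_exposure"]
  se <- sqrt(vc[".fitted_exposure", ".fitted_exposure"])
  est <- mr_estimate("two_stage", unname(b), se,
                     n_participants = nrow(data))
  attr(est, "first_stage_F") <- Fstat
  if (Fstat < 10) {
    warning(sprintf("weak instrument: first-stage F = %.2f < 10", Fstat))
    attr(est, "weak_instrument") <- TRUE
  }
  est
}

#' Crude odds ratios from quartile case/control counts
#'
#' Cross-product odds ratios of each quartile against quartile 1 from a
#' 4 x 2 table of counts; the closed form `(cases_q * controls_1) /
#' (cases_1 * controls_q)`.
#'
#' @param cases,controls Length-4 integer vectors, quartiles 1-4.
#' @return Data frame `quartile`, `n_cases`, `n_controls`, `odds_ratio`
#'   (quartile 1 fixed at 1), `ci95_low`, `ci95_high` (Woolf intervals),
#'   `case_pct` (percent of all cases in the quartile).
#' @examples
#' crude_quartile_or(c(89, 101, 106, 129), c(77358, 77529, 77701, 77588))
#' @export
crude_quartile_or <- function(cases, controls) {
  assert_that(length(cases) == 4 && length(controls) == 4,
              "expect 4 quartiles of counts")
  assert_that(all(cases > 0) && all(controls > 0),
              "empty cells: crude odds ratios undefined")
  or <- (cases * controls[1]) / (cases[1] * controls)
  se_log <- sqrt(1 / cases + 1 / controls + 1 / cases[1] + 1 / controls[1])
  z <- stats::qnorm(0.975)
  out <- data.frame(
    quartile = 1:4, n_cases = cases, n_controls = controls,
    odds_ratio = or,
    ci95_low = exp(log(or) - z * se_log),
    ci95_high = exp(log(or) + z * se_log),
    case_pct = 100 * cases / sum(cases)
  )
  out$ci95_low[1] <- out$ci95_high[1] <- NA_real_
  out
}

#' Genetic-liability quartile association
#'
#' Logistic regression of the outcome on quartile indicators (quartile 1
#' the reference, odds ratio fixed at 1.00), adjusted for covariates —
#' the analysis used when per-SD MR is not interpretable for a binary
#' exposure such as type 2 diabetes liability. Also returns the crude
#' cross-product odds ratios from the underlying counts.
#'
#' @param data Data frame with the outcome and covariates.
#' @param outcome Binary outcome column name.
#' @param quartile Column of quartile labels 1-4 (see
#'   [assign_quartiles()]).
#' @param covariates Covariate names; default age, sex, assessment centre
#'   and principal components as available.
#' @return List: `adjusted` (per-quartile OR/CI/p from the model),
#'   `crude` (from [crude_quartile_or()]).
#' @export
quartile_association <- function(data, outcome, quartile,
                                 covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- intersect(c("age_at_recruitment", "sex",
                              "assessment_centre", "pc1", "pc2", "pc3",
                              "pc4", "pc5"), names(data))
  }
  covariates <- setdiff(covariates, c(outcome, quartile))
  keep <- c(outcome, quartile, covariates)
  data <- data[stats::complete.cases(data[keep]), keep, drop = FALSE]
  q <- data[[quartile]]
  assert_that(all(q %in% 1:4), "quartile labels must be in 1..4")
  assert_that(all(1:4 %in% q), "empty quartile: cannot contrast")
  y <- as.integer(data[[outcome]])
  counts_case <- as.integer(table(factor(q[y == 1L], 1:4)))
  counts_ctrl <- as.integer(table(factor(q[y == 0L], 1:4)))
  data$.q <- factor(q, 1:4)
  fit <- stats::glm(stats::reformulate(c(".q", covariates),
                                       response = outcome),
                    family = stats::binomial(), data = data)
  co <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  rows <- lapply(2:4, function(k) {
    nm <- paste0(".q", k)
    b <- co[nm, "Estimate"]; se <- co[nm, "Std. Error"]
    data.frame(quartile = k, odds_ratio = exp(b),
               ci95_low = exp(b - z * se), ci95_high = exp(b + z * se),
               p = 2 * stats::pnorm(-abs(b / se)))
  })
  adjusted <- rbind(
    data.frame(quartile = 1, odds_ratio = 1, ci95_low = NA_real_,
               ci95_high = NA_real_, p = NA_real_),
    do.call(rbind, rows)
  )
  adjusted$n_cases <- counts_case
  adjusted$n_controls <- counts_ctrl
  list(adjusted = adjusted,
       crude = crude_quartile_or(counts_case, counts_ctrl))
}
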