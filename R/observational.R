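#' Standardize a trait to analysis-population SD units
#'
#' Centers and scales by the analysis population's own mean and SD, and
#' reports the SD so per-SD odds ratios can be read back in raw units
#' (e.g. one SD of BMI = 4.8 kg/m2).
#'
#' @param values Numeric vector, at least 2 non-missing values.
#' @return List: `values` (standardized, NAs preserved), `sd`, `mean`.
#' @export
standardize_per_sd <- function(values) {
  ok <- !is.na(values)
  assert_that(sum(ok) >= 2, "need at least 2 non-missing values")
  s <- stats::sd(values[ok])
  assert_that(s > 0, "zero variance: cannot standardize")
  m <- mean(values[ok])
  list(values = (values - m) / s, sd = s, mean = m)
}

#' Rank-based inverse normal transform
#'
#' Maps values to normal quantiles of their mid-ranks,
#' `qnorm((rank - 0.5) / n)`, with ties sharing the average rank. Used
#' for heavily skewed covariates such as weekly alcohol units.
#'
#' @param values Numeric vector (NAs preserved).
#' @return Transformed vector, approximately mean 0 and SD 1.
#' @export
inverse_normal_transform <- function(values) {
  ok <- !is.na(values)
  assert_that(sum(ok) >= 2, "need at least 2 non-missing values")
  out <- rep(NA_real_, length(values))
  r <- rank(values[ok], ties.method = "average")
  out[ok] <- stats::qnorm((r - 0.5) / sum(ok))
  out
}

# Default covariate set for trait-outcome models: age, sex, smoking,
# alcohol, Townsend index, BMI and T2DM, with the exposure itself dropped
# when it is one of these.
OBS_COVARIATES <- c("age_at_recruitment", "sex", "smoking", "alcohol_units",
                    "townsend", "bmi", "t2dm")

#' Covariate-adjusted logistic association
#'
#' Maximum-likelihood logistic regression of a binary outcome on one
#' trait plus covariates, reporting the odds ratio per unit of the trait
#' (per SD if the trait was standardized) with a Wald 95% confidence
#' interval and p-value. Refuses to report with fewer than 10 cases, and
#' raises an explicit error on (quasi-)separation.
#'
#' @param data Data frame holding all columns.
#' @param outcome Name of the binary outcome column (0/1 or logical).
#' @param trait Name of the exposure column.
#' @param covariates Character vector of covariate column names; the
#'   trait is dropped from it automatically. Default [OBS_COVARIATES]
#'   intersected with the available columns.
#' @param stratum `"all"`, `"female"`, or `"male"` (requires `sex`).
#' @return A one-row data.frame: `trait`, `outcome`, `odds_ratio`,
#'   `ci95_low`, `ci95_high`, `p_value`, `n_cases`, `n_controls`,
#'   `stratum`, `covariate_set`.
#' @export
logistic_association <- function(data, outcome, trait, covariates = NULL,
                                 stratum = c("all", "female", "male")) {
  stratum <- match.arg(stratum)
  if (stratum != "all") {
    data <- data[data$sex == c(female = "F", male = "M")[[stratum]], ,
                 drop = FALSE]
  }
  if (is.null(covariates)) {
    covariates <- intersect(OBS_COVARIATES, names(data))
  }
  covariates <- setdiff(covariates, c(trait, outcome))
  if (stratum != "all") covariates <- setdiff(covariates, "sex")
  keep <- c(outcome, trait, covariates)
  data <- data[stats::complete.cases(data[keep]), keep, drop = FALSE]
  y <- as.integer(data[[outcome]])
  assert_that(all(y %in% c(0L, 1L)), "outcome must be binary 0/1")
  n_cases <- sum(y == 1L)
  assert_that(n_cases >= 10,
              "only %d cases after filtering: refusing an unstable fit",
              n_cases)
  fml <- stats::reformulate(c(trait, covariates), response = outcome)
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(), data = data)
  )
  co <- summary(fit)$coefficients
  row <- grep(paste0("^", trait), rownames(co))[1]
  b <- co[row, "Estimate"]; se <- co[row, "Std. Error"]
  if (!fit$converged || !is.finite(se) || se > 50 || abs(b) > 50) {
    stopf("separation or non-convergence fitting %s on %s", outcome, trait)
  }
  z <- stats::qnorm(0.975)
  data.frame(
    trait = trait, outcome = outcome,
    odds_ratio = exp(b), ci95_low = exp(b - z * se),
    ci95_high = exp(b + z * se),
    p_value = 2 * stats::pnorm(-abs(b / se)),
    n_cases = n_cases, n_controls = sum(y == 0L),
    stratum = stratum,
    covariate_set = paste(covariates, collapse = "+"),
    stringsAsFactors = FALSE
  )
}

#' Demographic comparison adjusted for age and sex
#'
#' Convenience preset for case-versus-control demographic contrasts: the
#' same logistic machinery with only age and sex as covariates.
#'
#' @inheritParams logistic_association
#' @export
demographic_association <- function(data, outcome, trait) {
  logistic_association(data, outcome, trait,
                       covariates = c("age_at_recruitment", "sex"))
}
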