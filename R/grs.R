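#' Weighted genetic risk scores
#'
#' The score for a participant is the weight-by-dosage sum over the
#' instrument panel, `raw = sum_j beta_j d_j`, with weights from the
#' discovery GWAS oriented so every beta is positive (trait-increasing
#' allele); flipped variants count `2 - dosage`. The raw score is
#' rescaled to trait-increasing-allele-count units,
#' `rescaled = raw * n_variants / sum_j beta_j`, which runs from 0 to
#' `2 * n_variants` and is invariant to rescaling all weights by a
#' positive constant.
#'
#' @param genotypes Dosage matrix (participants x variants, dosages in
#'   \[0, 2\]), columns named by variant id.
#' @param specs A [variant_spec()] table; negative betas are oriented via
#'   [orient_to_increasing_allele()] before scoring.
#' @return Data frame `participant_id`, `trait`, `raw_score`,
#'   `rescaled_score`.
#' @examples
#' g <- matrix(c(1, 2), 1, dimnames = list("p1", c("v1", "v2")))
#' s <- variant_spec(c("v1", "v2"), c("A", "A"), c("G", "G"),
#'                   beta = c(0.1, 0.3), eaf = c(0.5, 0.5))
#' compute_weighted_grs(g, s)  # raw 0.7, rescaled 3.5
#' @export
compute_weighted_grs <- function(genotypes, specs) {
  specs <- orient_to_increasing_allele(specs)
  missing <- setdiff(specs$variant_id, colnames(genotypes))
  if (length(missing)) {
    stopf("variants missing from the genotype matrix: %s",
          paste(missing, collapse = ", "))
  }
  d <- genotypes[, specs$variant_id, drop = FALSE]
  assert_that(all(d >= 0 & d <= 2), "dosages must lie in [0, 2]")
  if (any(specs$flipped)) {
    d[, specs$flipped] <- 2 - d[, specs$flipped]
  }
  raw <- as.numeric(d %*% specs$beta)
  data.frame(
    participant_id = rownames(genotypes),
    trait = specs$trait[1],
    raw_score = raw,
    rescaled_score = raw * nrow(specs) / sum(specs$beta),
    stringsAsFactors = FALSE
  )
}

#' First-stage instrument strength (F statistic)
#'
#' Fits a linear regression of the continuous exposure on the genetic
#' risk score plus covariates and returns the partial F statistic for the
#' score term (the squared t statistic, F on 1 numerator df). F > 10 is
#' the conventional weak-instrument bar.
#'
#' @param score Numeric genetic risk score.
#' @param exposure Continuous exposure, same length.
#' @param covariates Optional data.frame of covariates.
#' @return A list: `F`, `df_residual`, `r_squared_partial`.
#' @export
instrument_strength <- function(score, exposure, covariates = NULL) {
  assert_that(length(score) == length(exposure) && length(score) >= 30,
              "need matching score/exposure with >= 30 observations")
  assert_that(stats::sd(score) > 0, "constant score: instrument has no variance")
  dat <- data.frame(.exposure = exposure, .score = score)
  if (!is.null(covariates)) dat <- cbind(dat, covariates)
  fit <- stats::lm(.exposure ~ ., data = dat)
  tval <- summary(fit)$coefficients[".score", "t value"]
  Fstat <- tval^2
  list(F = Fstat, df_residual = fit$df.residual,
       r_squared_partial = Fstat / (Fstat + fit$df.residual))
}

#' Assign genetic-liability quartiles
#'
#' Labels 1-4 from the empirical quartile cut points of the full scored
#' population (cases and controls pooled). Scores exactly at a cut point
#' go to the lower quartile.
#'
#' @param scores Numeric vector, at least 4 values, not all equal.
#' @return Integer vector of labels in 1..4.
#' @export
assign_quartiles <- function(scores) {
  assert_that(length(scores) >= 4, "need at least 4 scores")
  q <- stats::quantile(scores, c(0.25, 0.5, 0.75), names = FALSE)
  assert_that(stats::sd(scores) > 0 && length(unique(q)) == 3,
              "degenerate score distribution: quartile cut points collide")
  1L + (scores > q[1]) + (scores > q[2]) + (scores > q[3])
}
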