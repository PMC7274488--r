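#' Harmonize summary statistics to the exposure-increasing allele
#'
#' Orients every variant so its exposure beta is non-negative: rows with
#' `beta_exp < 0` have both betas sign-flipped and their alleles swapped
#' (the Wald ratio is invariant; the orientation matters for Egger
#' regression). If the table carries separate outcome-study allele
#' columns (`effect_allele_out`, `other_allele_out`), they are checked
#' against the exposure alleles first, flipping the outcome beta where
#' the studies reported opposite alleles and failing loudly on genuine
#' mismatches. Strand-ambiguous palindromic variants (A/T, C/G) are kept
#' or dropped per policy.
#'
#' @param rows A `summary_stats` table.
#' @param palindromic `"keep"` or `"drop"` A/T and C/G variants.
#' @return The harmonized table (`harmonized = TRUE`); attribute
#'   `dropped_palindromic` lists removed variant ids.
#' @export
harmonize <- function(rows, palindromic = c("keep", "drop")) {
  palindromic <- match.arg(palindromic)
  needed <- c("variant_id", "effect_allele", "other_allele", "beta_exp",
              "se_exp", "beta_out", "se_out")
  assert_that(all(needed %in% names(rows)),
              "summary-stat table lacks columns: %s",
              paste(setdiff(needed, names(rows)), collapse = ", "))
  assert_that(all(rows$se_exp > 0) && all(rows$se_out > 0),
              "standard errors must be strictly positive")

  if (all(c("effect_allele_out", "other_allele_out") %in% names(rows))) {
    same <- rows$effect_allele_out == rows$effect_allele &
      rows$other_allele_out == rows$other_allele
    swapped <- rows$effect_allele_out == rows$other_allele &
      rows$other_allele_out == rows$effect_allele
    if (any(!same & !swapped)) {
      stopf("allele mismatch between exposure and outcome for: %s",
            paste(rows$variant_id[!same & !swapped], collapse = ", "))
    }
    rows$beta_out[swapped] <- -rows$beta_out[swapped]
    rows$effect_allele_out <- rows$effect_allele
    rows$other_allele_out <- rows$other_allele
  }

  pal <- paste0(rows$effect_allele, rows$other_allele) %in%
    c("AT", "TA", "CG", "GC")
  dropped <- character()
  if (palindromic == "drop" && any(pal)) {
    dropped <- rows$variant_id[pal]
    message(sprintf("dropping %d palindromic variant(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")))
    rows <- rows[!pal, , drop = FALSE]
  }

  flip <- rows$beta_exp < 0
  if (any(flip)) {
    ea <- rows$effect_allele[flip]
    rows$effect_allele[flip] <- rows$other_allele[flip]
    rows$other_allele[flip] <- ea
    rows$beta_exp[flip] <- -rows$beta_exp[flip]
    rows$beta_out[flip] <- -rows$beta_out[flip]
  }
  rows$harmonized <- rep(TRUE, nrow(rows))
  class(rows) <- c("summary_stats", "data.frame")
  attr(rows, "dropped_palindromic") <- dropped
  rows
}

#' Single-instrument Wald ratio
#'
#' The causal estimate from one variant: the outcome association divided
#' by the exposure association, with the first-order delta-method
#' standard error `se_out / |beta_exp|` (optionally the second-order
#' form, which adds the exposure-uncertainty term).
#'
#' @param beta_exp,se_exp,beta_out,se_out Per-allele associations.
#' @param second_order Include the `se_exp` term in the SE.
#' @return List: `ratio`, `se`.
#' @export
wald_ratio <- function(beta_exp, se_exp, beta_out, se_out,
                       second_order = FALSE) {
  assert_that(all(beta_exp != 0), "beta_exp = 0: Wald ratio undefined")
  ratio <- beta_out / beta_exp
  se <- if (second_order) {
    sqrt(se_out^2 / beta_exp^2 + beta_out^2 * se_exp^2 / beta_exp^4)
  } else {
    se_out / abs(beta_exp)
  }
  list(ratio = ratio, se = se)
}

#' Inverse-variance weighted estimator
#'
#' Pools all instruments assuming every one is valid: the weighted
#' regression of outcome betas on exposure betas through the origin with
#' weights `1/se_out^2`, in closed form
#' `beta = sum(bx * by / s^2) / sum(bx^2 / s^2)`. The default fixed-
#' effect standard error is `1 / sqrt(sum(bx^2 / s^2))`; the
#' multiplicative random-effects variant inflates it by the residual
#' scale when instruments are over-dispersed. Cochran's Q against the
#' pooled estimate is attached as the heterogeneity diagnostic.
#'
#' @param rows A harmonized `summary_stats` table.
#' @param random_effects Multiplicative random-effects SE (never below
#'   the fixed-effect SE).
#' @return An [mr_estimate()] (`method = "ivw"`) with attributes `Q`,
#'   `Q_df`, `Q_p`.
#' @export
mr_ivw <- function(rows, random_effects = FALSE) {
  m <- nrow(rows)
  assert_that(!is.null(m) && m >= 1, "need at least one instrument")
  w <- 1 / rows$se_out^2
  denom <- sum(rows$beta_exp^2 * w)
  b <- sum(rows$beta_exp * rows$beta_out * w) / denom
  se <- 1 / sqrt(denom)
  Q <- sum(w * (rows$beta_out - b * rows$beta_exp)^2)
  if (random_effects && m > 1) {
    se <- se * max(1, sqrt(Q / (m - 1)))
  }
  est <- mr_estimate("ivw", b, se, n_variants = m)
  attr(est, "Q") <- Q
  attr(est, "Q_df") <- m - 1L
  attr(est, "Q_p") <- if (m > 1) {
    stats::pchisq(Q, m - 1, lower.tail = FALSE)
  } else NA_real_
  est
}

#' MR-Egger regression
#'
#' Weighted linear regression of outcome betas on exposure betas with an
#' unconstrained intercept (weights `1/se_out^2`, exposure betas
#' oriented positive by [harmonize()]). The slope estimates the causal
#' effect under the InSIDE assumption; the intercept estimates average
#' directional pleiotropy, and its p-value is the pleiotropy test.
#' Standard errors follow the usual convention of not allowing
#' under-dispersion (residual scale floored at 1); inference uses the t
#' distribution on `m - 2` degrees of freedom.
#'
#' @param rows A harmonized `summary_stats` table with at least 3 rows.
#' @return An [mr_estimate()] (`method = "egger"`) carrying the
#'   intercept fields.
#' @export
mr_egger <- function(rows) {
  m <- nrow(rows)
  assert_that(!is.null(m) && m >= 3,
              "MR-Egger needs at least 3 instruments")
  fit <- stats::lm(beta_out ~ beta_exp, data = rows,
                   weights = 1 / rows$se_out^2)
  s <- summary(fit)
  infl <- max(min(1, s$sigma), 1e-300)  # floor the residual scale at 1
  b <- s$coefficients["beta_exp", "Estimate"]
  se <- s$coefficients["beta_exp", "Std. Error"] / infl
  i0 <- s$coefficients["(Intercept)", "Estimate"]
  i0_se <- s$coefficients["(Intercept)", "Std. Error"] / infl
  if (s$sigma < 1e-12) se <- i0_se <- 0  # exact fit
  tp <- function(est, sd) {
    if (sd > 0) 2 * stats::pt(abs(est / sd), df = m - 2, lower.tail = FALSE)
    else as.numeric(est == 0)
  }
  p <- tp(b, se)
  i0_p <- tp(i0, i0_se)
  mr_estimate("egger", b, se, p = p, n_variants = m,
              egger_intercept = i0, egger_intercept_se = i0_se,
              egger_intercept_p = i0_p)
}

# Weighted median of `values` with weights `w`: the interpolated value
# where standardized cumulative weight (cum_j - w_j/2) / W crosses 1/2.
weighted_median_core <- function(values, w) {
  o <- order(values)
  v <- values[o]; w <- w[o]
  cum <- (cumsum(w) - w / 2) / sum(w)
  if (0.5 <= cum[1]) return(v[1])
  if (0.5 >= cum[length(cum)]) return(v[length(v)])
  k <- max(which(cum <= 0.5))
  v[k] + (v[k + 1] - v[k]) * (0.5 - cum[k]) / (cum[k + 1] - cum[k])
}

boot_median <- function(rows, n_boot, seed, penalty = NULL) {
  m <- nrow(rows)
  with_seed(seed, vapply(seq_len(n_boot), function(i) {
    bx <- stats::rnorm(m, rows$beta_exp, rows$se_exp)
    by <- stats::rnorm(m, rows$beta_out, rows$se_out)
    r <- by / bx
    w <- bx^2 / rows$se_out^2
    if (is.null(penalty)) return(weighted_median_core(r, w))
    b0 <- weighted_median_core(r, w)
    Qj <- w * (r - b0)^2
    pj <- stats::pchisq(Qj, 1, lower.tail = FALSE)
    weighted_median_core(r, w * pmin(1, penalty * pj))
  }, numeric(1)))
}

#' Weighted median estimator
#'
#' The median of the inverse-variance-weighted empirical distribution of
#' per-variant Wald ratios: consistent as long as at least half the
#' total weight comes from valid instruments, hence robust to up to 50%
#' invalid variants. Weights are the inverse squared first-order ratio
#' SEs, `beta_exp^2 / se_out^2`; the standard error comes from a
#' parametric bootstrap (betas resampled from their normal sampling
#' distributions under a fixed seed).
#'
#' @param rows A harmonized `summary_stats` table with at least 3 rows.
#' @param n_boot Bootstrap resamples for the SE.
#' @param seed Integer seed for the bootstrap.
#' @return An [mr_estimate()] (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(rows, n_boot = 1000L, seed = 1L) {
  m <- nrow(rows)
  assert_that(!is.null(m) && m >= 3,
              "weighted median needs at least 3 instruments")
  r <- rows$beta_out / rows$beta_exp
  w <- rows$beta_exp^2 / rows$se_out^2
  b <- weighted_median_core(r, w)
  se <- stats::sd(boot_median(rows, n_boot, seed))
  mr_estimate("weighted_median", b, se, n_variants = m)
}

#' Penalized weighted median estimator
#'
#' Down-weights instruments that conflict with the weighted-median
#' estimate: each variant's heterogeneity contribution
#' `Q_j = w_j (ratio_j - beta_WM)^2` is referred to a one-degree-of-
#' freedom chi-square, and its weight is multiplied by
#' `min(1, penalty * p_j)` (default penalty constant 20), so concordant
#' variants are untouched while gross outliers lose nearly all weight.
#' The weighted-median procedure is then re-applied with the penalized
#' weights.
#'
#' @inheritParams mr_weighted_median
#' @param penalty Penalty constant applied to the per-variant p-values.
#' @return An [mr_estimate()] (`method = "penalized_weighted_median"`).
#' @export
mr_penalized_weighted_median <- function(rows, n_boot = 1000L, seed = 1L,
                                         penalty = 20) {
  m <- nrow(rows)
  assert_that(!is.null(m) && m >= 3,
              "penalized weighted median needs at least 3 instruments")
  r <- rows$beta_out / rows$beta_exp
  w <- rows$beta_exp^2 / rows$se_out^2
  b0 <- weighted_median_core(r, w)
  Qj <- w * (r - b0)^2
  pj <- stats::pchisq(Qj, 1, lower.tail = FALSE)
  w_pen <- w * pmin(1, penalty * pj)
  b <- weighted_median_core(r, w_pen)
  se <- stats::sd(boot_median(rows, n_boot, seed, penalty = penalty))
  est <- mr_estimate("penalized_weighted_median", b, se, n_variants = m)
  attr(est, "penalized_weights") <- w_pen
  attr(est, "raw_weights") <- w
  est
}

#' Run all two-sample estimators on one instrument set
#'
#' Convenience wrapper: harmonizes (if needed) and applies IVW, MR-Egger,
#' weighted median, and penalized weighted median.
#'
#' @inheritParams mr_weighted_median
#' @return A data.frame of stacked [mr_estimate()] rows.
#' @export
mr_all_methods <- function(rows, n_boot = 1000L, seed = 1L) {
  if (!isTRUE(all(rows$harmonized))) rows <- harmonize(rows)
  out <- rbind(
    mr_ivw(rows),
    mr_egger(rows),
    mr_weighted_median(rows, n_boot, seed),
    mr_penalized_weighted_median(rows, n_boot, seed)
  )
  class(out) <- "data.frame"
  out
}
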