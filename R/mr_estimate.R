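#' Container for a Mendelian randomization estimate
#'
#' One causal estimate on the log-odds (or SD-outcome) scale per SD of
#' exposure, with its standard error, Wald 95% interval exponentiated to
#' the odds-ratio scale, and p-value. Egger fits additionally carry the
#' intercept (average directional pleiotropy) and its p-value.
#'
#' @param method Estimator label (`"ivw"`, `"egger"`, `"weighted_median"`,
#'   `"penalized_weighted_median"`, `"two_stage"`, `"wald"`, `"quartile"`).
#' @param beta,se Causal estimate and standard error.
#' @param p P-value; computed from a normal Wald z when `NULL`.
#' @param n_variants,n_participants Problem sizes, when known.
#' @param egger_intercept,egger_intercept_se,egger_intercept_p Egger only.
#' @return One-row data.frame of class `mr_estimate`.
#' @export
mr_estimate <- function(method, beta, se, p = NULL,
                        n_variants = NA_integer_,
                        n_participants = NA_integer_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_p = NA_real_) {
  assert_that(is.finite(se) && se >= 0, "standard error must be non-negative")
  z <- stats::qnorm(0.975)
  if (is.null(p)) {
    # se = 0 only for exact (noise-free) fits; the test is then degenerate
    p <- if (se > 0) 2 * stats::pnorm(-abs(beta / se)) else
      as.numeric(beta == 0)
  }
  out <- data.frame(
    method = method, beta = beta, se = se,
    or = exp(beta),
    ci95_low = exp(beta - z * se), ci95_high = exp(beta + z * se),
    p = p,
    egger_intercept = egger_intercept,
    egger_intercept_se = egger_intercept_se,
    egger_intercept_p = egger_intercept_p,
    n_variants = n_variants, n_participants = n_participants,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mr_estimate", "data.frame")
  out
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %s, p = %s\n", x$method,
              format_or_ci(x$or, x$ci95_low, x$ci95_high), format_p(x$p)))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (p = %s)\n", x$egger_intercept,
                format_p(x$egger_intercept_p)))
  }
  invisible(x)
}
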