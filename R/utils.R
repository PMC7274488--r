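#' @keywords internal
"_PACKAGE"

# Fail with the caller's message if `cond` is not a single TRUE.
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_that <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stopf(fmt, ...)
  invisible(TRUE)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream (so seeded helpers can be used inside other simulations).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) && x >= 0
}

#' Format an odds ratio with its 95% confidence interval
#'
#' Renders `"1.45 (1.11-1.90)"`-style cells for results tables: the odds
#' ratio and both interval ends to two decimals, the interval joined by a
#' hyphen.
#'
#' @param or Odds ratio.
#' @param lo,hi Confidence interval ends on the odds-ratio scale.
#' @return A character scalar.
#' @export
format_or_ci <- function(or, lo, hi) {
  sprintf("%.2f (%.2f-%.2f)", or, lo, hi)
}

#' Format a p-value for a results table
#'
#' P-values at or above 0.001 are printed with two significant figures;
#' smaller values in scientific notation, e.g. `"1.2 x 10^-5"`.
#'
#' @param p P-value in \[0, 1\].
#' @return A character scalar.
#' @export
format_p <- function(p) {
  stopifnot(is.numeric(p), length(p) == 1L)
  if (is.na(p)) return(NA_character_)
  if (p >= 0.001) return(formatC(signif(p, 2), format = "fg"))
  e <- floor(log10(p))
  m <- p / 10^e
  sprintf("%.1f x 10^%d", m, as.integer(e))
}
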