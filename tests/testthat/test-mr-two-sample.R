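test_that("harmonization flips orientation without changing the ratio", {
  rows <- data.frame(
    variant_id = c("v1", "v2"), effect_allele = c("A", "C"),
    other_allele = c("G", "A"), beta_exp = c(-0.1, 0.2),
    se_exp = 0.01, beta_out = c(-0.05, 0.04), se_out = 0.01,
    harmonized = FALSE
  )
  h <- harmonize(rows)
  expect_equal(h$beta_exp, c(0.1, 0.2))
  expect_equal(h$beta_out, c(0.05, 0.04))
  expect_equal(h$effect_allele[1], "G")
  expect_true(all(h$harmonized))
  expect_equal(h$beta_out / h$beta_exp, rows$beta_out / rows$beta_exp)
})

test_that("palindromic variants are dropped on request and mismatches fail", {
  rows <- data.frame(
    variant_id = c("v1", "v2"), effect_allele = c("A", "C"),
    other_allele = c("T", "G"), beta_exp = c(0.1, 0.2), se_exp = 0.01,
    beta_out = c(0.05, 0.04), se_out = 0.01
  )
  expect_message(h <- harmonize(rows, palindromic = "drop"), "palindromic")
  expect_equal(h$variant_id, character(0))
  expect_equal(attr(h, "dropped_palindromic"), c("v1", "v2"))

  rows2 <- data.frame(
    variant_id = "v1", effect_allele = "G", other_allele = "A",
    effect_allele_out = "C", other_allele_out = "T",
    beta_exp = 0.1, se_exp = 0.01, beta_out = 0.05, se_out = 0.01
  )
  expect_error(harmonize(rows2), "allele mismatch.*v1")
  # swapped outcome alleles get their beta flipped
  rows3 <- rows2
  rows3$effect_allele_out <- "A"; rows3$other_allele_out <- "G"
  expect_equal(harmonize(rows3)$beta_out, -0.05)
})

test_that("the Wald ratio and its delta-method SE follow the formulas", {
  w <- wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(w$ratio, 0.5)
  expect_equal(w$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.02, 0, 0.01)$ratio, 0)
  expect_error(wald_ratio(0, 0.02, 0.05, 0.01), "undefined")
  # second-order SE collapses to first-order as se_exp -> 0
  w2 <- wald_ratio(0.1, 0, 0.05, 0.01, second_order = TRUE)
  expect_equal(w2$se, 0.1)
  w3 <- wald_ratio(0.1, 0.05, 0.05, 0.01, second_order = TRUE)
  expect_gt(w3$se, 0.1)
})

test_that("IVW matches the closed form and its single-instrument degeneracy", {
  rows <- rows_with_ratios(0.5, 100)
  rows$beta_exp <- 0.1; rows$beta_out <- 0.05; rows$se_out <- 0.01
  est <- mr_ivw(rows)
  expect_equal(est$beta, wald_ratio(0.1, 0, 0.05, 0.01)$ratio)
  expect_equal(est$se, 0.1)

  two <- data.frame(variant_id = c("a", "b"), effect_allele = "A",
                    other_allele = "G", beta_exp = c(0.1, 0.2),
                    se_exp = 0.01, beta_out = c(0.05, 0.04), se_out = 0.01,
                    harmonized = TRUE)
  expect_equal(mr_ivw(two)$beta, 0.26, tolerance = 1e-12)
})

test_that("IVW equals the inverse-variance meta-analysis of Wald ratios", {
  set.seed(10)
  ss <- simulate_summary_stats(test_panel(30), 0.2, 100000, 150000,
                               seed = 11)
  ss <- harmonize(ss)
  est <- mr_ivw(ss)
  wr <- wald_ratio(ss$beta_exp, ss$se_exp, ss$beta_out, ss$se_out)
  w <- 1 / wr$se^2
  expect_equal(est$beta, sum(w * wr$ratio) / sum(w), tolerance = 1e-10)
  expect_equal(est$se, 1 / sqrt(sum(w)), tolerance = 1e-10)
  # independent cross-check against a general-purpose meta-analysis fitter
  meta <- metafor::rma(yi = wr$ratio, sei = wr$se, method = "FE")
  expect_equal(est$beta, as.numeric(meta$beta), tolerance = 1e-8)
  expect_equal(est$se, meta$se, tolerance = 1e-8)
})

test_that("IVW is consistent with many valid instruments", {
  set.seed(12)
  ss <- harmonize(simulate_summary_stats(test_panel(50), 0.2,
                                         200000, 200000, seed = 13))
  est <- mr_ivw(ss)
  expect_lt(abs(est$beta - 0.2), 3 * est$se)
  # Cochran's Q behaves like chi-square(m-1) under homogeneity
  expect_gt(attr(est, "Q_p"), 1e-4)
})

test_that("Egger fits exact linear data exactly and refuses < 3 rows", {
  rows <- data.frame(variant_id = c("a", "b", "c"), effect_allele = "A",
                     other_allele = "G", beta_exp = c(0.1, 0.2, 0.3),
                     se_exp = 0.01, se_out = 0.01, harmonized = TRUE)
  rows$beta_out <- 0.01 + 0.4 * rows$beta_exp
  est <- mr_egger(rows)
  expect_equal(est$beta, 0.4, tolerance = 1e-10)
  expect_equal(est$egger_intercept, 0.01, tolerance = 1e-10)
  expect_equal(est$se, 0)
  expect_error(mr_egger(rows[1:2, ]), "at least 3")
  expect_error(mr_weighted_median(rows[1:2, ]), "at least 3")
})

test_that("Egger separates directional pleiotropy from the causal slope", {
  set.seed(14)
  specs <- variant_panel("BMI", n_variants = 200, seed = 15)
  ss <- harmonize(simulate_summary_stats(
    specs, causal_effect = 0.2, n_exp = 500000, n_out = 500000,
    pleiotropy_mode = "directional", pleiotropy_mean = 0.05,
    pleiotropy_sd = 0.01, seed = 16))
  ivw <- mr_ivw(ss)
  egger <- mr_egger(ss)
  # IVW absorbs the directional offset; Egger assigns it to the intercept
  expect_gt(ivw$beta - 0.2, 5 * ivw$se)
  expect_lt(abs(egger$egger_intercept - 0.05), 3 * egger$egger_intercept_se)
  expect_lt(abs(egger$beta - 0.2), 3 * egger$se)
})

test_that("the weighted median interpolates the weighted ratio distribution", {
  expect_equal(mr_weighted_median(rows_with_ratios(c(0.2, 0.5, 0.9),
                                                   rep(4, 3)),
                                  n_boot = 50, seed = 1)$beta, 0.5)
  est <- mr_weighted_median(rows_with_ratios(c(0.1, 0.4, 0.7),
                                             c(0.2, 0.3, 0.5)),
                            n_boot = 50, seed = 1)
  expect_equal(est$beta, 0.5125, tolerance = 1e-12)
})

test_that("the weighted median resists up to 40% invalid instruments", {
  set.seed(17)
  ss <- harmonize(simulate_summary_stats(test_panel(50), 0.2,
                                         200000, 200000, seed = 18))
  # 40% of instruments (a weight minority) get a large pleiotropic offset
  bad <- order(ss$beta_exp^2 / ss$se_out^2)[1:20]
  ss$beta_out[bad] <- ss$beta_out[bad] + 0.02
  wm <- mr_weighted_median(ss, n_boot = 500, seed = 19)
  ivw <- mr_ivw(ss)
  expect_lt(abs(wm$beta - 0.2), 3 * wm$se)
  expect_gt(ivw$beta - 0.2, 3 * ivw$se)
})

test_that("penalization only bites discordant instruments", {
  # homogeneous instruments: PWM equals WM
  set.seed(20)
  ss <- harmonize(simulate_summary_stats(test_panel(30), 0.1,
                                         500000, 500000, seed = 21))
  wm <- mr_weighted_median(ss, n_boot = 200, seed = 22)
  pwm <- mr_penalized_weighted_median(ss, n_boot = 200, seed = 22)
  expect_equal(pwm$beta, wm$beta, tolerance = 0.01)

  # one gross outlier among 20 concordant instruments loses its weight
  rows <- rows_with_ratios(c(rep(0.2, 20) + seq(-0.01, 0.01, length.out = 20),
                             5),
                           rep(1000, 21))
  pwm2 <- mr_penalized_weighted_median(rows, n_boot = 50, seed = 23)
  w_pen <- attr(pwm2, "penalized_weights")
  w_raw <- attr(pwm2, "raw_weights")
  expect_lt(w_pen[21] / w_raw[21], 0.01)
  expect_equal(pwm2$beta, 0.2, tolerance = 0.02)
})

test_that("all estimators are scale-equivariant in the exposure betas", {
  set.seed(24)
  ss <- harmonize(simulate_summary_stats(test_panel(25), 0.15,
                                         100000, 100000, seed = 25))
  k <- 3.7
  ss_k <- ss
  ss_k$beta_exp <- ss_k$beta_exp * k
  ss_k$se_exp <- ss_k$se_exp * k
  expect_equal(mr_ivw(ss_k)$beta, mr_ivw(ss)$beta / k, tolerance = 1e-12)
  expect_equal(mr_egger(ss_k)$beta, mr_egger(ss)$beta / k,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(ss_k, 50, 1)$beta,
               mr_weighted_median(ss, 50, 1)$beta / k, tolerance = 1e-12)
  expect_equal(mr_penalized_weighted_median(ss_k, 50, 1)$beta,
               mr_penalized_weighted_median(ss, 50, 1)$beta / k,
               tolerance = 1e-12)
})

test_that("with many strong valid instruments all estimators agree", {
  set.seed(26)
  ss <- harmonize(simulate_summary_stats(
    variant_panel("BMI", n_variants = 100, seed = 27), 0.2,
    2e6, 2e6, seed = 28))
  all4 <- mr_all_methods(ss, n_boot = 300, seed = 29)
  # agreement within Monte-Carlo error of the noisiest estimator
  expect_lt(max(all4$beta) - min(all4$beta), 4 * max(all4$se))
  expect_true(all(abs(all4$beta - 0.2) < 4 * all4$se + 0.01))
})
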