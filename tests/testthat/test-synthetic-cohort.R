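test_that("genotype dosages follow Hardy-Weinberg expectations", {
  spec <- variant_spec("v1", "A", "G", beta = 0.1, eaf = 0.5)
  g <- simulate_genotypes(spec, n = 10000, seed = 11)
  expect_true(all(g %in% 0:2))
  se <- sqrt(2 * 0.5 * 0.5 / 10000)
  expect_lt(abs(mean(g) - 1.0), 3 * se)

  near_fixed <- variant_spec("v2", "A", "G", beta = 0.1, eaf = 0.999999)
  g2 <- simulate_genotypes(near_fixed, n = 100, seed = 12)
  expect_true(all(g2 %in% 0:2))
  expect_gt(mean(g2 == 2L), 0.9)
})

test_that("allele frequencies are recovered within binomial error", {
  specs <- test_panel(m = 30, seed = 3)
  g <- simulate_genotypes(specs, n = 20000, seed = 4)
  freq <- colMeans(g) / 2
  se <- sqrt(specs$eaf * (1 - specs$eaf) / (2 * 20000))
  expect_true(all(abs(freq - specs$eaf) < 4 * se))
})

test_that("genotype simulation is deterministic and validates frequencies", {
  specs <- test_panel(m = 5)
  expect_identical(simulate_genotypes(specs, 50, seed = 9),
                   simulate_genotypes(specs, 50, seed = 9))
  bad <- specs
  bad$eaf[1] <- 1.2
  expect_error(simulate_genotypes(bad, 10), "frequencies")
})

test_that("cohort simulation calibrates prevalence and reproduces under seed", {
  cfg <- sim_config(n_participants = 20000, outcome_baseline_prevalence = 0.01,
                    outcome = "cancer", seed = 21)
  ch <- simulate_cohort(cfg)
  se <- sqrt(0.01 * 0.99 / 20000)
  expect_lt(abs(ch$truth$realized_prevalence - 0.01), 3 * se)
  expect_true(all(ch$genotypes >= 0 & ch$genotypes <= 2))
  expect_equal(mean(ch$participants$exposure), 0, tolerance = 1e-8)
  expect_equal(sd(ch$participants$exposure), 1, tolerance = 1e-8)
  # cases carry outcome-consistent registry codes
  cases <- ch$participants$participant_id[ch$participants$outcome == 1L]
  c73 <- ch$diagnoses[startsWith(ch$diagnoses$icd10_code, "C73"), ]
  expect_setequal(c73$participant_id, cases)

  ch2 <- simulate_cohort(cfg)
  expect_identical(ch$participants, ch2$participants)
  expect_identical(ch$genotypes, ch2$genotypes)
  expect_identical(ch$diagnoses, ch2$diagnoses)
})

test_that("an empty case set raises an actionable error", {
  cfg <- sim_config(n_participants = 30, outcome_baseline_prevalence = 1e-4,
                    outcome = "cancer", seed = 5)
  expect_error(simulate_cohort(cfg), "increase n_participants")
})

test_that("positive confounding biases the observational association under the null", {
  cfg <- sim_config(n_participants = 60000, causal_effect = 0,
                    confounder_effect_on_exposure = 0.5,
                    confounder_effect_on_outcome = 0.8,
                    outcome_baseline_prevalence = 0.02, seed = 31)
  ch <- simulate_cohort(cfg)
  obs <- logistic_association(ch$participants, "outcome", "exposure",
                              covariates = c("age_at_recruitment", "sex"))
  expect_gt(obs$odds_ratio, 1)
  expect_lt(obs$p_value, 0.01)
})

test_that("summary statistics hit the noise-free limit and reproduce", {
  specs <- test_panel(m = 20)
  ss <- simulate_summary_stats(specs, causal_effect = 0.3,
                               n_exp = 1e12, n_out = 1e12, seed = 41)
  expect_equal(ss$beta_out / ss$beta_exp, rep(0.3, 20), tolerance = 1e-3)
  expect_identical(ss, simulate_summary_stats(specs, 0.3, 1e12, 1e12,
                                              seed = 41))
  expect_equal(ss$se_exp, 1 / sqrt(2 * specs$eaf * (1 - specs$eaf) * 1e12))
})

test_that("balanced pleiotropy has mean zero over many variants", {
  specs <- variant_panel("BMI", n_variants = 10000, seed = 6)
  ss <- simulate_summary_stats(specs, causal_effect = 0.1,
                               n_exp = 1e10, n_out = 1e10,
                               pleiotropy_mode = "balanced",
                               pleiotropy_sd = 0.02, seed = 7)
  alpha_hat <- ss$beta_out - 0.1 * ss$beta_exp
  expect_lt(abs(mean(alpha_hat)), 3 * 0.02 / sqrt(10000))
})
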