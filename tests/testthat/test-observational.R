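test_that("per-SD standardization reports the population SD", {
  set.seed(1)
  bmi <- 27 + 4.8 * scale(rnorm(5000))  # exact SD by construction
  s <- standardize_per_sd(as.numeric(bmi))
  expect_equal(s$sd, 4.8)
  expect_equal(mean(s$values), 0, tolerance = 1e-12)
  expect_equal(sd(s$values), 1, tolerance = 1e-12)
  expect_error(standardize_per_sd(rep(3, 10)), "zero variance")
  expect_error(standardize_per_sd(c(1, NA, NA)), "at least 2")
})

test_that("inverse normal transform has the stated construction properties", {
  set.seed(2)
  x <- rlnorm(1000)
  z <- inverse_normal_transform(x)
  expect_lt(abs(mean(z)), 0.01)
  expect_true(sd(z) > 0.95 && sd(z) < 1.05)
  # monotone: near-perfect correlation with already-normal input
  g <- rnorm(1000)
  expect_gt(cor(inverse_normal_transform(g), g), 0.99)
  # complete ties share the average rank and map to the median, 0
  expect_equal(inverse_normal_transform(rep(7, 50)), rep(0, 50))
  # NAs pass through
  expect_equal(which(is.na(inverse_normal_transform(c(1, NA, 3)))), 2L)
})

test_that("logistic association recovers a known per-SD log odds ratio", {
  set.seed(3)
  n <- 100000
  x <- rnorm(n)
  age <- sample(40:69, n, replace = TRUE)
  eta <- -3.95 + 0.2 * x + 0.002 * (age - 55)
  d <- data.frame(y = rbinom(n, 1, plogis(eta)), x = x,
                  age_at_recruitment = age,
                  sex = sample(c("F", "M"), n, replace = TRUE))
  fit <- logistic_association(d, "y", "x",
                              covariates = c("age_at_recruitment", "sex"))
  se <- log(fit$ci95_high / fit$odds_ratio) / qnorm(0.975)
  expect_lt(abs(log(fit$odds_ratio) - 0.2), 3 * se)
  expect_true(fit$ci95_low <= fit$odds_ratio &&
                fit$odds_ratio <= fit$ci95_high)
})

test_that("the null distribution of the p-value is uniform", {
  set.seed(4)
  p <- replicate(400, {
    n <- 1500
    d <- data.frame(y = rbinom(n, 1, 0.1), x = rnorm(n))
    logistic_association(d, "y", "x", covariates = character())$p_value
  })
  reject <- mean(p < 0.05)
  expect_lt(abs(reject - 0.05), 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(ks.test(p, "punif")$p.value, 0.001)
})

test_that("an unadjusted binary fit matches the closed-form cross-product OR", {
  counts <- c(a = 40, b = 160, c = 25, d = 375)  # exposed/unexposed cases/controls
  d <- data.frame(
    y = rep(c(1, 0, 1, 0), counts),
    x = rep(c(1, 1, 0, 0), counts)
  )
  fit <- logistic_association(d, "y", "x", covariates = character())
  expect_equal(fit$odds_ratio, (40 * 375) / (160 * 25), tolerance = 1e-6)
})

test_that("per-SD and raw-unit fits share the same Wald p-value", {
  set.seed(6)
  n <- 20000
  bmi <- 27 + 4.8 * rnorm(n)
  d <- data.frame(y = rbinom(n, 1, plogis(-3 + 0.03 * (bmi - 27))),
                  bmi_raw = bmi,
                  bmi_sd = standardize_per_sd(bmi)$values)
  f1 <- logistic_association(d, "y", "bmi_raw", covariates = character())
  f2 <- logistic_association(d, "y", "bmi_sd", covariates = character())
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-9)
})

test_that("degenerate fits are refused with explicit errors", {
  set.seed(7)
  n <- 3000
  d <- data.frame(y = rbinom(n, 1, 0.05), x = rnorm(n))
  d$x_sep <- ifelse(d$y == 1, abs(d$x) + 10, -abs(d$x))  # perfect separation
  expect_error(logistic_association(d, "y", "x_sep",
                                    covariates = character()),
               "separation|non-convergence")
  d_few <- d[c(which(d$y == 1)[1:5], which(d$y == 0)), ]
  expect_error(logistic_association(d_few, "y", "x",
                                    covariates = character()),
               "cases")
})

test_that("stratified fits drop sex and filter rows", {
  set.seed(8)
  n <- 30000
  d <- data.frame(y = rbinom(n, 1, 0.05), x = rnorm(n),
                  sex = sample(c("F", "M"), n, replace = TRUE),
                  age_at_recruitment = sample(40:69, n, replace = TRUE))
  f <- logistic_association(d, "y", "x", stratum = "female")
  expect_equal(f$stratum, "female")
  expect_equal(f$n_cases + f$n_controls, sum(d$sex == "F"))
  expect_false(grepl("sex", f$covariate_set))
})
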