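test_that("imputation uses the analytic-sample mean, never the outcome", {
  cohort <- data.frame(
    id = 1:6,
    arm = factor(rep(c("low", "high"), 3), levels = c("low", "high")),
    site = rep(1:2, 3),
    hh_income = c(10, 20, 30, NA, 100, 200),
    race = factor(c("Black", NA, "Hispanic", "Black", "White", "White")),
    in_eeg_sample = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE)
  )
  analytic_ids <- 1:4
  out <- impute_covariates(cohort, analytic_ids, covariates = c("hh_income", "race"))

  # mean of analytic values {10, 20, 30}, not the full-cohort mean
  expect_equal(out$hh_income[4], 20)
  expect_true(mean(cohort$hh_income, na.rm = TRUE) != 20)
  expect_equal(as.character(out$race[2]), "(missing)")

  # identity when nothing is missing
  expect_identical(impute_covariates(out, analytic_ids, covariates = c("hh_income", "race")),
                   out)

  cohort$net_worth <- c(NA, NA, NA, NA, 5, 5)
  expect_error(impute_covariates(cohort, analytic_ids, covariates = "net_worth"),
               "entirely missing")
})

test_that("fit_itt returns the documented degenerate and error behavior", {
  fx <- analytic_fixture(small_config(seed = 41L))
  d <- fx$analytic

  # outcome equal to the treatment indicator: coefficient 1, SE collapses
  y <- as.numeric(d$arm == "high")
  f <- suppressWarnings(fit_itt(y, d, covariates = FALSE))  # perfect fit warns
  expect_equal(f$coef, 1, tolerance = 1e-10)
  expect_lt(f$se, 1e-8)

  # collinear design is reported with the offending column
  d2 <- d
  d2$mother_age <- 2 * d2$mother_edu_years
  d2$mother_edu_years <- d2$mother_age
  expect_error(fit_itt(fx$outcomes$abs_beta, d2, covariates = TRUE), "collinear")

  expect_error(fit_itt(c(NA, fx$outcomes$abs_beta[-1]), d, covariates = FALSE),
               "never imputed")
})

test_that("null simulation yields uniform p-values at nominal level", {
  n <- 200
  pvals <- vapply(1:500, function(r) {
    set.seed(5000 + r)
    d <- data.frame(arm = factor(sample(c("low", "high"), n, TRUE, c(0.6, 0.4)),
                                 levels = c("low", "high")),
                    site = sample(1:4, n, TRUE))
    fit_itt(rnorm(n), d, covariates = FALSE)$p
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 1.96 * sqrt(0.05 * 0.95 / 500) + 0.005)
})

test_that("robust SE approximates the classical SE under homoskedasticity", {
  set.seed(43)
  n <- 435
  d <- data.frame(arm = factor(sample(c("low", "high"), n, TRUE, c(0.58, 0.42)),
                               levels = c("low", "high")),
                  site = sample(1:4, n, TRUE))
  y <- rnorm(n)
  f <- fit_itt(y, d, covariates = FALSE)
  classical <- summary(lm(y ~ I(d$arm == "high") + factor(d$site)))$coefficients[2, 2]
  expect_lt(abs(f$se - classical) / classical, 0.10)
})

test_that("site fixed effects absorb site-level mean shifts", {
  fx <- analytic_fixture(small_config(seed = 47L))
  y <- fx$outcomes$abs_alpha
  f0 <- fit_itt(y, fx$analytic, covariates = FALSE)
  y_shift <- y + 50 * (fx$analytic$site == 2)
  f1 <- fit_itt(y_shift, fx$analytic, covariates = FALSE)
  expect_equal(f0$coef, f1$coef, tolerance = 1e-8)
})

test_that("standardized effect size is the coefficient over the low-arm SD", {
  expect_equal(round(effect_size(0.414, 1.592), 2), 0.26)
  expect_equal(round(effect_size(0.221, 0.947), 2), 0.23)
  expect_equal(round(effect_size(0.720, 4.213), 2), 0.17)
  expect_equal(effect_size(0, 2.5), 0)
  expect_error(effect_size(1, 0), "positive")
  expect_error(effect_size(1, -2), "positive")

  fx <- analytic_fixture(small_config(seed = 53L))
  f <- fit_itt(fx$outcomes$abs_beta, fx$analytic, covariates = TRUE)
  sd_low <- sd(fx$outcomes$abs_beta[fx$analytic$arm == "low"])
  expect_equal(effect_size(f), f$coef / sd_low)
})

test_that("balance table matches a closed-form two-proportion z-test", {
  n1 <- 100; n2 <- 90; x1 <- 30; x2 <- 45
  cohort <- data.frame(
    id = 1:(n1 + n2),
    arm = factor(rep(c("low", "high"), c(n1, n2)), levels = c("low", "high")),
    flag = c(rep(c(1, 0), c(x1, n1 - x1)), rep(c(1, 0), c(x2, n2 - x2)))
  )
  tab <- balance_table(cohort, analytic_ids = cohort$id, variables = "flag")

  p1 <- x1 / n1; p2 <- x2 / n2; pp <- (x1 + x2) / (n1 + n2)
  z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
  expect_equal(tab$p, 2 * pnorm(-abs(z)), tolerance = 1e-10)
  expect_equal(tab$mean_low, 30)
  expect_equal(tab$mean_high, 50)

  # identical proportions: difference zero, p = 1
  cohort$same <- rep(c(1, 0), length.out = n1 + n2)
  tab2 <- balance_table(cohort, cohort$id, variables = "same")
  expect_equal(tab2$mean_low, tab2$mean_high)

  # identical arms on a constant: p reported as 1
  cohort$const <- 1
  expect_equal(balance_table(cohort, cohort$id, variables = "const")$p, 1)

  expect_error(balance_table(cohort, cohort$id, variables = "nope"), "nope")
})

test_that("balance table covers the simulated cohort without imbalance", {
  cfg <- sim_config(seed = 61L)
  cohort <- generate_cohort(cfg)
  # sparse race levels can trip the chi-square small-count warning
  tab <- suppressWarnings(balance_table(cohort))
  expect_true(all(c("child_female", "child_age_months", "n_usable_epochs") %in%
                    sub(":.*", "", tab$variable)))
  expect_true(all(tab$n_low <= 251 & tab$n_high <= 184))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
})
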