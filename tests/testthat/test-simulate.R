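test_that("cohort respects the randomization and attrition contract", {
  cfg <- sim_config(n_dyads = 1000L, seed = 7L)
  cohort <- generate_cohort(cfg)

  expect_equal(nrow(cohort), 1000L)
  # Bernoulli(0.40) assignment: within 4 binomial SDs.
  expect_lt(abs(mean(cohort$arm == "high") - 0.40), 4 * sqrt(0.4 * 0.6 / 1000))
  # sites near-uniform
  expect_true(all(abs(table(cohort$site) - 250) <= 1))
  # exact per-arm analytic counts
  expect_identical(sum(cohort$in_eeg_sample & cohort$arm == "low"), 251L)
  expect_identical(sum(cohort$in_eeg_sample & cohort$arm == "high"), 184L)
  # age-at-visit window
  expect_true(all(cohort$child_age_months > 10 & cohort$child_age_months < 18))
  expect_true(all(cohort$hh_income >= 0, na.rm = TRUE))
  # usable-epoch counts only recorded at the visit
  expect_true(all(is.na(cohort$n_usable_epochs[!cohort$in_eeg_sample])))
  expect_true(all(cohort$n_usable_epochs[cohort$in_eeg_sample] >= 20))
})

test_that("zero missingness leaves no missing covariate cells", {
  cfg <- sim_config(n_dyads = 200L, attrition = c(low = 30L, high = 20L),
                    missing_covariate_rate = 0, seed = 3L)
  cohort <- generate_cohort(cfg)
  for (v in setdiff(names(cohort), "n_usable_epochs")) {
    expect_false(anyNA(cohort[[v]]), label = paste("no NA in", v))
  }
})

test_that("infeasible per-arm EEG counts raise an error naming the arm", {
  cfg <- sim_config(n_dyads = 500L, attrition = c(low = 400L, high = 50L), seed = 2L)
  expect_error(generate_cohort(cfg), "low")
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- small_config(seed = 5L)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)

  sub <- c1[c1$in_eeg_sample, ][1, ]
  r1 <- generate_recording(sub, cfg, duration_s = 5)
  r2 <- generate_recording(sub, cfg, duration_s = 5)
  expect_identical(r1$samples, r2$samples)

  # different subjects get different streams
  sub2 <- c1[c1$in_eeg_sample, ][2, ]
  r3 <- generate_recording(sub2, cfg, duration_s = 5)
  expect_false(isTRUE(all.equal(r1$samples[1, ], r3$samples[1, ])))
})

test_that("latent band powers match configured arm-level moments", {
  cfg <- sim_config(seed = 21L)
  cohort <- generate_cohort(cfg)
  bp <- simulate_band_powers(cohort, cfg, cohort$id)  # full cohort, n = 1000
  arm <- as.character(cohort$arm)
  for (b in c("theta", "alpha", "beta", "gamma")) {
    m <- cfg$band_means[[b]]; s <- cfg$band_sds[[b]]
    m_hi <- m + cfg$effect_sizes[[b]] * s
    tol_lo <- 4 * s / sqrt(sum(arm == "low"))
    tol_hi <- 4 * s / sqrt(sum(arm == "high"))
    expect_lt(abs(mean(bp[[b]][arm == "low"]) - m), tol_lo, label = paste(b, "low mean"))
    expect_lt(abs(mean(bp[[b]][arm == "high"]) - m_hi), tol_hi, label = paste(b, "high mean"))
    expect_true(all(bp[[b]] > 0))
  }
})

test_that("recording embeds latent band power recoverable from its spectrum", {
  cfg <- small_config(seed = 9L)
  sub <- list(id = 42L, arm = "low")

  # isolated beta band: in-band PSD integral within 10% of the latent power
  p_beta <- 2.5
  rec <- generate_recording(sub, cfg,
                            band_powers = c(theta = 0, alpha = 0, beta = p_beta, gamma = 0),
                            duration_s = 60)
  ep <- epoch_and_reject(rec, epoch_s = 4, overlap = 0.5, amp_uv = Inf)
  bp <- band_power(bin_spectrum(ep, channels = rec$channels))
  expect_lt(abs(bp$absolute[["beta"]] - p_beta) / p_beta, 0.10)

  # theta-only recording: other bands carry only the broadband floor
  rec2 <- generate_recording(sub, cfg,
                             band_powers = c(theta = 30, alpha = 0, beta = 0, gamma = 0),
                             duration_s = 60)
  ep2 <- epoch_and_reject(rec2, epoch_s = 4, overlap = 0.5, amp_uv = Inf)
  bp2 <- band_power(bin_spectrum(ep2, channels = rec2$channels))
  expect_lt(bp2$absolute[["alpha"]], 0.03 * bp2$absolute[["theta"]])
  expect_lt(bp2$absolute[["beta"]], 0.03 * bp2$absolute[["theta"]])
  expect_lt(bp2$absolute[["gamma"]], 0.03 * bp2$absolute[["theta"]])

  expect_error(generate_recording(sub, cfg,
                                  band_powers = c(theta = -1, alpha = 1, beta = 1, gamma = 1)),
               "non-negative")
})

test_that("artifact injection is masked, frontal-biased, and rate-0 safe", {
  cfg <- small_config(seed = 13L)
  sub <- list(id = 8L, arm = "low")
  rec <- generate_recording(sub, cfg, duration_s = 60)

  cfg0 <- small_config(seed = 13L, blink_rate_per_min = 0, movement_rate_per_min = 0)
  out0 <- inject_artifacts(rec, cfg0)
  expect_identical(out0$samples, rec$samples)
  expect_false(any(out0$artifact_mask))

  cfg_blink <- small_config(seed = 13L, blink_rate_per_min = 10, movement_rate_per_min = 0)
  rec1 <- generate_recording(sub, cfg_blink, duration_s = 60)
  out <- inject_artifacts(rec1, cfg_blink)
  expect_gt(sum(out$artifact_mask), 0)

  # contaminated spans are high-amplitude relative to clean spans
  m <- out$artifact_mask
  expect_gt(mean(abs(out$samples[, m])), mean(abs(out$samples[, !m])))

  # blinks land on frontal channels only: non-frontal channels unchanged
  nf <- setdiff(rec1$channels, c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"))
  expect_equal(out$samples[nf, ], rec1$samples[nf, ])
})

test_that("arm is independent of baseline covariates across cohorts", {
  # regression of a covariate on arm over repeated cohorts: p-values uniform
  pvals <- vapply(1:200, function(r) {
    cfg <- sim_config(n_dyads = 300L, attrition = c(low = 5L, high = 5L),
                      missing_covariate_rate = 0, seed = 1000L + r)
    cohort <- generate_cohort(cfg)
    summary(lm(mother_edu_years ~ arm, data = cohort))$coefficients[2, 4]
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.05)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(p_high = 1.2), "p_high")
  expect_error(sim_config(band_sds = c(theta = 0, alpha = 1, beta = 1, gamma = 1)), "band_sds")
  expect_error(sim_config(effect_sizes = c(theta = Inf, alpha = 0, beta = 0, gamma = 0)),
               "effect_sizes")
  expect_error(sim_config(n_dyads = 100L, attrition = c(low = 90L, high = 90L)),
               "exceeds")
  expect_error(sim_config(duration_s = 600), "420")
})
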