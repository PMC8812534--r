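# Shared fixtures, all generated in code.

# Small cohort configuration that keeps simulation-heavy tests fast.
small_config <- function(seed = 1L, ...) {
  sim_config(n_dyads = 300L, attrition = c(low = 60L, high = 40L),
             seed = seed, ...)
}

# Single- or multi-channel recording holding pure sinusoids.
sinusoid_recording <- function(freq, duration_s = 60, fs = 500, amp = 1,
                               channels = "Cz") {
  t <- seq(0, duration_s - 1 / fs, by = 1 / fs)
  x <- amp * sin(2 * pi * freq * t)
  new_recording(matrix(rep(x, each = length(channels)), nrow = length(channels)),
                channels, fs = fs)
}

# Epoch set built directly from a channels x samples matrix (one "recording"
# treated as clean), bypassing filtering.
epochs_from_matrix <- function(samples, channels, fs = 500, epoch_s = 1,
                               overlap = 0, reference = NULL) {
  rec <- new_recording(samples, channels, fs = fs)
  rec$reference <- reference
  epoch_and_reject(rec, epoch_s = epoch_s, overlap = overlap, amp_uv = Inf)
}

# Analytic-sample data frame with imputed covariates, plus direct band-power
# outcomes, for ITT-level tests.
analytic_fixture <- function(config = small_config()) {
  cohort <- generate_cohort(config)
  ids <- cohort$id[cohort$in_eeg_sample]
  bp <- simulate_band_powers(cohort, config, ids)
  analytic <- impute_covariates(cohort, ids)
  analytic <- analytic[match(ids, analytic$id), ]
  list(cohort = cohort, analytic = analytic, ids = ids,
       band_powers = bp, outcomes = band_outcomes(bp))
}
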