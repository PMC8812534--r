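#' Eight analysis outcomes from per-child band powers
#'
#' Converts per-child absolute band powers into the eight outcome columns
#' analyzed in the ITT table: absolute power per band and child-level
#' relative power (each band divided by the four-band sum).
#'
#' @param band_powers Data frame with columns `id`, `theta`, `alpha`,
#'   `beta`, `gamma` (absolute power, uV^2).
#' @return Data frame: `id`, `abs_theta` ... `abs_gamma`,
#'   `rel_theta` ... `rel_gamma`.
#' @export
band_outcomes <- function(band_powers) {
  need <- c("theta", "alpha", "beta", "gamma")
  missing_b <- setdiff(need, names(band_powers))
  if (length(missing_b)) stopf("band_powers lacks column(s): %s", paste(missing_b, collapse = ", "))
  M <- as.matrix(band_powers[need])
  total <- rowSums(M)
  out <- data.frame(id = band_powers$id)
  for (b in need) out[[paste0("abs_", b)]] <- band_powers[[b]]
  for (b in need) out[[paste0("rel_", b)]] <- band_powers[[b]] / total
  out
}

#' Preprocess one raw recording into artifact-free epochs
#'
#' The standard chain: re-reference to the T7/T8 average, zero-phase
#' band-pass filter, then epoch with amplitude-based rejection.
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Filter band edges.
#' @param epoch_s,overlap,amp_uv Epoching and rejection settings
#'   (see [epoch_and_reject()]).
#' @return An `epoch_set`.
#' @export
process_recording <- function(rec, low_hz = 0.3, high_hz = 50,
                              epoch_s = 1, overlap = 0.5, amp_uv = 100) {
  rec <- rereference(rec)
  rec <- filter_recording(rec, low_hz, high_hz)
  epoch_and_reject(rec, epoch_s = epoch_s, overlap = overlap, amp_uv = amp_uv)
}

#' Run the full simulated study
#'
#' Generates a cohort, obtains per-child band-power outcomes for the EEG
#' analytic sample — either directly from the latent band powers
#' (`mode = "direct"`, fast, exact) or by synthesizing raw EEG for each child
#' and running the preprocessing and spectral stages (`mode = "eeg"`) — then
#' mean-imputes covariates and produces the ITT results table.
#'
#' @param config A [sim_config()].
#' @param mode `"direct"` or `"eeg"`.
#' @param duration_s Per-child recording duration for `mode = "eeg"`
#'   (shorter recordings trade spectral precision for speed).
#' @param n_resamples Westfall-Young permutations.
#' @param artifacts Inject artifacts before preprocessing (`mode = "eeg"`)?
#' @return List: `cohort`, `analytic` (imputed analytic rows), `outcomes`
#'   (eight columns aligned to `analytic`), `table2`.
#' @export
run_study <- function(config = sim_config(), mode = c("direct", "eeg"),
                      duration_s = 60, n_resamples = 2000, artifacts = FALSE) {
  mode <- match.arg(mode)
  cohort <- generate_cohort(config)
  ids <- cohort$id[cohort$in_eeg_sample]
  if (mode == "direct") {
    bp <- simulate_band_powers(cohort, config, ids)
  } else {
    rows <- lapply(ids, function(i) {
      subject <- cohort[cohort$id == i, ]
      rec <- generate_recording(subject, config, duration_s = duration_s)
      if (artifacts) rec <- inject_artifacts(rec, config)
      ep <- process_recording(rec)
      bpw <- band_power(bin_spectrum(ep))
      data.frame(id = i, t(bpw$absolute))
    })
    bp <- do.call(rbind, rows)
    names(bp) <- c("id", "theta", "alpha", "beta", "gamma")
  }
  outcomes <- band_outcomes(bp)
  analytic <- impute_covariates(cohort, ids)
  analytic <- analytic[match(outcomes$id, analytic$id), ]
  tab <- make_table2(outcomes[-1], analytic, n_resamples = n_resamples,
                     seed = config$seed)
  list(cohort = cohort, analytic = analytic, outcomes = outcomes, table2 = tab)
}
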