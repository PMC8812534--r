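#' Simulation configuration
#'
#' Builds the configuration object consumed by every generator. Defaults
#' reproduce the emulated trial's design: 1,000 dyads, 40% high-cash
#' assignment across 4 sites, attrition to an EEG analytic sample of 251
#' low-cash / 184 high-cash infants, and band-power distributions anchored at
#' the trial's low-cash-group means/SDs with the reported standardized
#' treatment effects injected on the high-cash arm
#' (see [band_reference()]).
#'
#' @param n_dyads Number of mother/infant dyads enrolled.
#' @param p_high Probability of assignment to the high-cash arm.
#' @param n_sites Number of recruitment sites (assigned near-uniformly).
#' @param effect_sizes Named vector, standardized treatment effect on absolute
#'   power per band (high-arm mean shifted by `effect_size * sd`).
#' @param band_means,band_sds Named vectors: low-cash-arm mean and SD of
#'   absolute band power in uV^2. Band powers are drawn from moment-matched
#'   log-normal distributions (power is positive and right-skewed).
#' @param band_cor Common-factor correlation of the latent Gaussian scores
#'   across bands (EEG band powers are strongly positively correlated within
#'   child).
#' @param attrition Named vector `c(low=, high=)`: per-arm EEG analytic sample
#'   sizes after attrition.
#' @param missing_covariate_rate Proportion of baseline maternal covariate
#'   cells set to missing.
#' @param duration_s Recording duration in seconds (hardware maximum 420 s).
#' @param fs Sampling rate in Hz; the emulated amplifier records at 500 Hz.
#' @param floor_scale Scale of the 1/f broadband background: its one-sided PSD
#'   is `floor_scale / f^floor_exponent` uV^2/Hz.
#' @param floor_exponent Spectral exponent of the background (default 1).
#' @param channel_noise_sd SD (uV) of the independent white perturbation added
#'   per channel on top of the structured scalp signal.
#' @param channel_mix Proportion of each channel's band-limited variance
#'   carried by a scalp-wide common process (the rest is an independent
#'   per-channel realization of the same band power). Values strictly below 1
#'   keep the montage informative after reference-average subtraction;
#'   re-referencing rescales every band power by the same montage factor, so
#'   relative power and standardized effect sizes are unaffected.
#' @param blink_rate_per_min,movement_rate_per_min Artifact rates used by
#'   [inject_artifacts()].
#' @param epoch_mean,epoch_sd Mean/SD of the truncated-normal draw for the
#'   number of artifact-free epochs recorded per child at the visit.
#' @param seed Master seed; per-subject streams are derived by stable hashing
#'   of (seed, id).
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_dyads = 1000L,
                       p_high = 0.40,
                       n_sites = 4L,
                       effect_sizes = c(theta = 0.02, alpha = 0.17, beta = 0.26, gamma = 0.23),
                       band_means = c(theta = 40.268, alpha = 7.441, beta = 1.874, gamma = 0.986),
                       band_sds = c(theta = 23.317, alpha = 4.213, beta = 1.592, gamma = 0.947),
                       band_cor = 0.5,
                       attrition = c(low = 251L, high = 184L),
                       missing_covariate_rate = 0.03,
                       duration_s = 300,
                       fs = 500,
                       floor_scale = 0.02,
                       floor_exponent = 1,
                       channel_noise_sd = 0.2,
                       channel_mix = 0.5,
                       blink_rate_per_min = 2,
                       movement_rate_per_min = 0.5,
                       epoch_mean = 288.2,
                       epoch_sd = 183.7,
                       seed = 1L) {
  bands <- c("theta", "alpha", "beta", "gamma")
  cfg <- list(
    n_dyads = as.integer(n_dyads), p_high = p_high, n_sites = as.integer(n_sites),
    effect_sizes = effect_sizes[bands], band_means = band_means[bands],
    band_sds = band_sds[bands], band_cor = band_cor,
    attrition = c(low = as.integer(attrition[["low"]]), high = as.integer(attrition[["high"]])),
    missing_covariate_rate = missing_covariate_rate,
    duration_s = duration_s, fs = fs,
    floor_scale = floor_scale, floor_exponent = floor_exponent,
    channel_noise_sd = channel_noise_sd,
    channel_mix = channel_mix,
    blink_rate_per_min = blink_rate_per_min,
    movement_rate_per_min = movement_rate_per_min,
    epoch_mean = epoch_mean, epoch_sd = epoch_sd,
    seed = as.integer(seed)
  )
  if (cfg$p_high <= 0 || cfg$p_high >= 1) stopf("p_high must lie strictly in (0, 1)")
  if (anyNA(cfg$effect_sizes) || any(!is.finite(cfg$effect_sizes))) {
    stopf("effect_sizes must be finite and named for theta/alpha/beta/gamma")
  }
  if (anyNA(cfg$band_sds) || any(cfg$band_sds <= 0)) stopf("band_sds must all be > 0")
  if (anyNA(cfg$band_means) || any(cfg$band_means <= 0)) stopf("band_means must all be > 0")
  if (cfg$duration_s > 420) stopf("duration_s exceeds the 420 s hardware maximum")
  if (cfg$missing_covariate_rate < 0 || cfg$missing_covariate_rate >= 1) {
    stopf("missing_covariate_rate must lie in [0, 1)")
  }
  if (cfg$channel_mix < 0 || cfg$channel_mix > 1) stopf("channel_mix must lie in [0, 1]")
  if (sum(cfg$attrition) > cfg$n_dyads) {
    stopf("EEG analytic sample (%d) exceeds cohort size (%d)", sum(cfg$attrition), cfg$n_dyads)
  }
  class(cfg) <- "sim_config"
  cfg
}

# Scalp montage: 19 scalp signals from the 10-20 set for 20-channel hardware
# (the remaining hardware channel is the online reference).
eeg_channels <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "P7", "P3", "Pz", "P4", "P8", "O1", "O2")
}

frontal_channels <- function() c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8")

# Baseline maternal covariates eligible for missingness injection / imputation.
maternal_covariates <- function() {
  c("mother_age", "mother_edu_years", "hh_income", "net_worth",
    "mother_health", "mother_mental_health", "race", "married",
    "n_adults", "n_other_children", "smoked_pregnancy",
    "alcohol_pregnancy", "father_in_home")
}

#' Generate a synthetic randomized cohort
#'
#' Draws one cohort table: near-uniform site assignment, independent Bernoulli
#' treatment assignment (randomization holds by construction, so every
#' baseline covariate is independent of arm), baseline maternal and child
#' covariates from documented distribution families, attrition flags giving
#' exactly the configured per-arm EEG analytic sample sizes, and missingness
#' injected into baseline maternal covariates.
#'
#' @param config A [sim_config()] object.
#' @return A data frame, one row per dyad, with columns `id`, `site`, `arm`
#'   (factor low/high), baseline maternal covariates (`mother_age`,
#'   `mother_edu_years`, `hh_income`, `net_worth`, `mother_health`,
#'   `mother_mental_health`, `race`, `married`, `n_adults`,
#'   `n_other_children`, `smoked_pregnancy`, `alcohol_pregnancy`,
#'   `father_in_home`), child covariates (`child_female`, `birth_weight_g`,
#'   `gestational_age_wk`, `child_age_months`), `in_eeg_sample`, and
#'   `n_usable_epochs` (recorded only for the EEG sample).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_dyads
  with_seed(subject_seed(config$seed, 0L, stream = 1L), {
    arm <- factor(ifelse(stats::runif(n) < config$p_high, "high", "low"),
                  levels = c("low", "high"))
    site <- sample(rep_len(seq_len(config$n_sites), n))

    race <- factor(sample(c("White", "Black", "Multiple", "Other", "Hispanic"),
                          n, replace = TRUE,
                          prob = c(0.09, 0.42, 0.045, 0.04, 0.405)),
                   levels = c("White", "Black", "Multiple", "Other", "Hispanic"))
    cohort <- data.frame(
      id = seq_len(n),
      site = site,
      arm = arm,
      mother_age = pmin(pmax(stats::rnorm(n, 27, 5.8), 18), 45),
      mother_edu_years = pmin(pmax(round(stats::rnorm(n, 12, 3.1)), 4), 20),
      hh_income = stats::rlnorm(n, meanlog = log(21500^2 / sqrt(18000^2 + 21500^2)),
                                sdlog = sqrt(log(1 + (18000 / 21500)^2))),
      net_worth = stats::rnorm(n, 5000, 15000),
      mother_health = pmin(pmax(round(stats::rnorm(n, 3.5, 1)), 1), 5),
      mother_mental_health = pmin(pmax(round(stats::rnorm(n, 3.4, 1)), 1), 5),
      race = race,
      married = stats::runif(n) < 0.25,
      n_adults = 1L + stats::rpois(n, 1),
      n_other_children = stats::rpois(n, 1.4),
      smoked_pregnancy = stats::runif(n) < 0.10,
      alcohol_pregnancy = stats::runif(n) < 0.05,
      father_in_home = stats::runif(n) < 0.40,
      child_female = stats::runif(n) < 0.47,
      birth_weight_g = stats::rnorm(n, 3300, 450),
      gestational_age_wk = pmin(pmax(stats::rnorm(n, 39.1, 1.2), 37), 42),
      child_age_months = pmin(pmax(stats::rnorm(n, 12.8, 1.5), 10.5), 17),
      stringsAsFactors = FALSE
    )

    # Attrition: exactly the configured per-arm analytic counts.
    cohort$in_eeg_sample <- FALSE
    for (a in c("low", "high")) {
      want <- config$attrition[[a]]
      idx <- which(cohort$arm == a)
      if (want > length(idx)) {
        stopf("requested %d EEG-sample children in the %s-cash arm but only %d were randomized to it",
              want, a, length(idx))
      }
      cohort$in_eeg_sample[sample(idx, want)] <- TRUE
    }

    cohort$n_usable_epochs <- NA_real_
    n_eeg <- sum(cohort$in_eeg_sample)
    ep <- stats::rnorm(n_eeg, config$epoch_mean, config$epoch_sd)
    while (any(bad <- ep < 20)) ep[bad] <- stats::rnorm(sum(bad), config$epoch_mean, config$epoch_sd)
    cohort$n_usable_epochs[cohort$in_eeg_sample] <- round(ep)

    # Missingness in baseline maternal covariates only.
    if (config$missing_covariate_rate > 0) {
      for (v in maternal_covariates()) {
        miss <- stats::runif(n) < config$missing_covariate_rate
        cohort[[v]][miss] <- NA
      }
    }
    cohort
  })
}

# Log-normal parameters matched to a target mean/SD on the natural scale.
lnorm_params <- function(m, s) {
  list(meanlog = log(m^2 / sqrt(s^2 + m^2)), sdlog = sqrt(log(1 + (s / m)^2)))
}

# Latent band powers for one subject: equicorrelated Gaussian scores mapped
# through moment-matched log-normal margins; the high arm's target mean is
# shifted by effect_size * sd.
latent_powers_one <- function(id, arm, config) {
  with_seed(subject_seed(config$seed, id, stream = 2L), {
    rho <- config$band_cor
    f <- stats::rnorm(1)
    z <- sqrt(rho) * f + sqrt(1 - rho) * stats::rnorm(4)
    m <- config$band_means
    if (arm == "high") m <- m + config$effect_sizes * config$band_sds
    p <- vapply(seq_along(m), function(b) {
      par <- lnorm_params(m[[b]], config$band_sds[[b]])
      stats::qlnorm(stats::pnorm(z[b]), par$meanlog, par$sdlog)
    }, numeric(1))
    names(p) <- names(m)
    p
  })
}

#' Simulate per-child latent band powers directly
#'
#' The fast path for statistical experiments: returns each child's latent
#' whole-scalp absolute band powers without synthesizing raw EEG. The values
#' are identical to the ones [generate_recording()] embeds, so spectral
#' recovery can be checked against them.
#'
#' @param cohort A cohort from [generate_cohort()].
#' @param config The same [sim_config()] used for the cohort.
#' @param ids Subjects to include; defaults to the EEG analytic sample.
#' @return Data frame: `id`, `theta`, `alpha`, `beta`, `gamma` (uV^2).
#' @export
simulate_band_powers <- function(cohort, config, ids = cohort$id[cohort$in_eeg_sample]) {
  arm <- as.character(cohort$arm[match(ids, cohort$id)])
  out <- t(vapply(seq_along(ids),
                  function(i) latent_powers_one(ids[i], arm[i], config),
                  numeric(4)))
  data.frame(id = ids, out, row.names = NULL)
}

# Real-valued colored noise with one-sided PSD S(f); spectral synthesis.
colored_noise <- function(n, fs, psd_fun) {
  nf <- floor(n / 2)
  f <- (1:nf) * fs / n
  scale <- sqrt(psd_fun(f) * fs * n / 2)
  z <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) / sqrt(2) * scale
  spec <- complex(real = numeric(n))
  spec[2:(nf + 1)] <- z
  spec[n:(n - nf + 2)] <- Conj(z[seq_len(nf - 1)])
  Re(stats::fft(spec, inverse = TRUE)) / n
}

# Band-limited Gaussian process with realized variance exactly `power`.
# Realized by zero-phase brickwall filtering of white noise in the frequency
# domain (spectral synthesis): flat PSD strictly inside [lo, hi), zero
# outside, so no synthesis leakage into neighboring analysis bands.
band_process <- function(n, fs, lo, hi, power) {
  x <- colored_noise(n, fs, function(f) ifelse(f >= lo & f < hi, 1 / (hi - lo), 0))
  x * sqrt(power / stats::var(x))
}

#' Construct a recording object
#'
#' @param samples Numeric matrix, channels x time, in uV.
#' @param channels Channel labels (rownames of `samples` if missing).
#' @param fs Sampling rate in Hz.
#' @param id Optional subject id.
#' @return An object of class `eeg_recording`.
#' @export
new_recording <- function(samples, channels = rownames(samples), fs = 500, id = NA_integer_) {
  stopifnot(is.matrix(samples), length(channels) == nrow(samples))
  if (ncol(samples) / fs > 420) stopf("recording exceeds the 420 s maximum duration")
  if (!all(is.finite(samples))) stopf("recording contains non-finite samples")
  rownames(samples) <- channels
  structure(list(samples = samples, channels = channels, fs = fs, id = id,
                 units = "uV"),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %.1f s @ %g Hz (uV)\n",
              length(x$channels), ncol(x$samples) / x$fs, x$fs))
  invisible(x)
}

#' Synthesize one infant EEG recording
#'
#' Generates a multichannel recording as the sum of (a) 1/f-shaped broadband
#' background noise shared across the scalp and (b) four band-limited
#' Gaussian processes per channel, each rescaled so its realized variance
#' equals the subject's latent absolute band power. A channel's band-limited
#' content mixes a scalp-wide common realization (weight `channel_mix`) with
#' an independent per-channel realization, so channels are strongly
#' correlated yet the montage stays informative after re-referencing; a small
#' independent white perturbation is added per channel. Deterministic given
#' (config, subject id).
#'
#' @param subject One cohort row (needs `id` and `arm`).
#' @param config A [sim_config()].
#' @param band_powers Optional named vector theta/alpha/beta/gamma overriding
#'   the subject's latent powers (useful for controlled spectra in tests).
#' @param duration_s Override of `config$duration_s`.
#' @return An `eeg_recording` with 19 scalp channels at 500 Hz.
#' @export
generate_recording <- function(subject, config = sim_config(), band_powers = NULL,
                               duration_s = config$duration_s) {
  id <- subject$id
  if (is.null(band_powers)) {
    band_powers <- latent_powers_one(id, as.character(subject$arm), config)
  }
  if (any(band_powers < 0) || all(band_powers == 0)) {
    stopf("latent band powers must be non-negative with at least one positive band (subject %s)", id)
  }
  bands <- default_bands()
  n <- round(duration_s * config$fs)
  chans <- eeg_channels()
  with_seed(subject_seed(config$seed, id, stream = 3L), {
    floor_sig <- colored_noise(n, config$fs,
                               function(f) config$floor_scale / f^config$floor_exponent)
    w <- config$channel_mix
    common <- lapply(seq_len(nrow(bands)), function(b) {
      p <- band_powers[[bands$band[b]]]
      if (p > 0 && w > 0) band_process(n, config$fs, bands$lo_hz[b], bands$hi_hz[b], p)
      else numeric(n)
    })
    samples <- matrix(0, nrow = length(chans), ncol = n)
    for (ch in seq_along(chans)) {
      x <- floor_sig
      for (b in seq_len(nrow(bands))) {
        p <- band_powers[[bands$band[b]]]
        if (p <= 0) next
        own <- if (w < 1) band_process(n, config$fs, bands$lo_hz[b], bands$hi_hz[b], p)
               else numeric(n)
        x <- x + sqrt(w) * common[[b]] + sqrt(1 - w) * own
      }
      samples[ch, ] <- x
    }
    if (config$channel_noise_sd > 0) {
      samples <- samples + matrix(stats::rnorm(length(chans) * n, 0, config$channel_noise_sd),
                                  nrow = length(chans))
    }
    new_recording(samples, chans, fs = config$fs, id = id)
  })
}

#' Inject stereotyped artifacts into a recording
#'
#' Adds blink-like low-frequency high-amplitude transients on frontal channels
#' and broadband movement bursts across all channels, at Poisson rates taken
#' from the configuration. Returns the contaminated recording together with a
#' per-sample ground-truth mask (`$artifact_mask`) marking contaminated spans,
#' which the preprocessing tests use to score rejection sensitivity. Zero
#' rates leave the samples untouched.
#'
#' @param rec An `eeg_recording`.
#' @param config A [sim_config()] supplying `blink_rate_per_min` and
#'   `movement_rate_per_min`.
#' @return The recording with `$artifact_mask` (logical, one per sample).
#' @export
inject_artifacts <- function(rec, config = sim_config()) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$samples)
  fs <- rec$fs
  mins <- n / fs / 60
  mask <- rep(FALSE, n)
  id <- if (is.na(rec$id)) 0L else rec$id
  with_seed(subject_seed(config$seed, id, stream = 4L), {
    n_blink <- stats::rpois(1, config$blink_rate_per_min * mins)
    n_move <- stats::rpois(1, config$movement_rate_per_min * mins)
    front <- which(rec$channels %in% frontal_channels())
    blink_len <- round(0.3 * fs)
    blink_shape <- 400 * sin(pi * seq_len(blink_len) / blink_len)^2
    if (n_blink > 0) {
      for (s in sort(sample.int(n - blink_len, n_blink))) {
        span <- s:(s + blink_len - 1)
        amp <- stats::runif(length(front), 0.6, 1.2)
        rec$samples[front, span] <- rec$samples[front, span] +
          outer(amp, blink_shape)
        mask[span] <- TRUE
      }
    }
    move_len <- round(0.5 * fs)
    if (n_move > 0) {
      for (s in sort(sample.int(n - move_len, n_move))) {
        span <- s:(s + move_len - 1)
        rec$samples[, span] <- rec$samples[, span] +
          matrix(stats::rnorm(nrow(rec$samples) * move_len, 0, 150),
                 nrow = nrow(rec$samples))
        mask[span] <- TRUE
      }
    }
  })
  rec$artifact_mask <- mask
  rec
}
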