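#' Default frequency-band definitions
#'
#' The analyzed spectrum is divided into 48 one-hertz bins spanning 2-49 Hz
#' (bin k covers `[k, k+1)` Hz, lower edges 2..49). The four conventional
#' bands tile those bins exactly; boundaries are configurable but must remain
#' integer bin edges within `[2, 50]`.
#'
#' @return Data frame with columns `band`, `lo_hz`, `hi_hz` (lower inclusive,
#'   upper exclusive).
#' @export
default_bands <- function() {
  data.frame(band = c("theta", "alpha", "beta", "gamma"),
             lo_hz = c(2, 6, 10, 20),
             hi_hz = c(6, 10, 20, 50),
             stringsAsFactors = FALSE)
}

bin_edges <- function() 2:49

check_bands_tile <- function(bands) {
  if (!all(c("band", "lo_hz", "hi_hz") %in% names(bands))) {
    stopf("bands must have columns band, lo_hz, hi_hz")
  }
  b <- bands[order(bands$lo_hz), ]
  if (any(b$hi_hz <= b$lo_hz)) stopf("each band needs lo_hz < hi_hz")
  if (b$lo_hz[1] != 2 || b$hi_hz[nrow(b)] != 50 ||
      any(b$lo_hz[-1] != b$hi_hz[-nrow(b)])) {
    stopf("bands must be disjoint and tile the 48 analyzed bins (2-50 Hz)")
  }
  if (any(b$lo_hz != round(b$lo_hz)) || any(b$hi_hz != round(b$hi_hz))) {
    stopf("band boundaries must be integer bin edges")
  }
  b
}

#' Single-hertz-bin power spectrum of an epoch set
#'
#' Computes a Welch-style power spectral density: per epoch and channel a
#' Hann-windowed FFT periodogram, averaged over epochs and over the selected
#' scalp channels, then integrated into 48 one-hertz bins with lower edges
#' 2..49 Hz.
#'
#' @param ep An `epoch_set` with `n_usable >= 1`.
#' @param channels Channels to average over; defaults to all scalp channels
#'   excluding the reference pair recorded on the epoch set.
#' @return Object of class `bin_spectrum`: `power` (named numeric, 48 bins,
#'   uV^2), `freq_lo` (2..49), `n_epochs_used`, `channels`, `df` (frequency
#'   resolution in Hz).
#' @export
bin_spectrum <- function(ep, channels = NULL) {
  stopifnot(inherits(ep, "epoch_set"))
  if (ep$n_usable < 1) stopf("no usable epochs")
  if (is.null(channels)) channels <- scalp_channels(ep$channels, ep$reference)
  unknown <- setdiff(channels, ep$channels)
  if (length(unknown)) stopf("unknown channel(s): %s", paste(unknown, collapse = ", "))

  len <- dim(ep$epochs)[3]
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, len - 1) / len)  # periodic Hann
  u <- sum(w^2)
  nf <- floor(len / 2)
  freqs <- (1:nf) * ep$fs / len
  df <- ep$fs / len
  ci <- match(channels, ep$channels)

  acc <- numeric(nf)
  for (e in seq_len(ep$n_usable)) {
    for (ch in ci) {
      x <- ep$epochs[e, ch, ]
      X <- stats::fft((x - mean(x)) * w)
      p <- (2 / (ep$fs * u)) * Mod(X[2:(nf + 1)])^2
      if (len %% 2 == 0) p[nf] <- p[nf] / 2  # Nyquist bin is not doubled
      acc <- acc + p
    }
  }
  psd <- acc / (ep$n_usable * length(ci))

  lo <- bin_edges()
  power <- vapply(lo, function(k) sum(psd[freqs >= k & freqs < k + 1]) * df, numeric(1))
  names(power) <- as.character(lo)
  structure(list(power = power, freq_lo = lo, n_epochs_used = ep$n_usable,
                 channels = channels, df = df),
            class = "bin_spectrum")
}

#' Aggregate a bin spectrum into band absolute and relative power
#'
#' Absolute band power is the sum of the member bins; relative band power is
#' each band's absolute power divided by the sum over the four bands, so the
#' relative values sum to exactly 1 per child.
#'
#' @param spec A `bin_spectrum` (or any named 48-vector of bin powers).
#' @param bands Band definitions tiling the 48 bins (see [default_bands()]).
#' @return Object of class `band_power`: named numeric vectors `absolute`
#'   (uV^2) and `relative`.
#' @export
band_power <- function(spec, bands = default_bands()) {
  b <- check_bands_tile(bands)
  power <- if (inherits(spec, "bin_spectrum")) spec$power else spec
  if (length(power) != 48) stopf("expected 48 bin powers, got %d", length(power))
  lo <- bin_edges()
  absolute <- vapply(seq_len(nrow(b)), function(i) {
    sum(power[lo >= b$lo_hz[i] & lo < b$hi_hz[i]])
  }, numeric(1))
  names(absolute) <- b$band
  total <- sum(absolute)
  if (total <= 0) stopf("total band power is not positive")
  structure(list(absolute = absolute, relative = absolute / total),
            class = "band_power")
}

#' Regional band power
#'
#' Computes a separate bin spectrum per scalp region (averaging only that
#' region's channels) and aggregates each into band power. The reference pair
#' is never part of a region.
#'
#' @param ep An `epoch_set`.
#' @param bands Band definitions (see [default_bands()]).
#' @param region_map Named list mapping region name to channel labels; each
#'   channel may belong to at most one region.
#' @return Data frame: `region`, `band`, `absolute`, `relative`.
#' @export
region_band_power <- function(ep, bands = default_bands(), region_map = default_region_map()) {
  all_ch <- unlist(region_map, use.names = FALSE)
  if (anyDuplicated(all_ch)) {
    stopf("channel(s) mapped to more than one region: %s",
          paste(unique(all_ch[duplicated(all_ch)]), collapse = ", "))
  }
  out <- lapply(names(region_map), function(rg) {
    bp <- band_power(bin_spectrum(ep, channels = region_map[[rg]]), bands)
    data.frame(region = rg, band = names(bp$absolute),
               absolute = unname(bp$absolute), relative = unname(bp$relative),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Default scalp-region groupings (10-20 montage)
#'
#' Standard frontal/central/parietal/occipital groupings; the temporal pair
#' T7/T8 is excluded because it serves as the reference.
#'
#' @return Named list of channel vectors.
#' @export
default_region_map <- function() {
  list(frontal = c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "Fz"),
       central = c("C3", "C4", "Cz"),
       parietal = c("P3", "P4", "P7", "P8", "Pz"),
       occipital = c("O1", "O2"))
}

#' Standardize single-hertz-bin spectra over a cohort
#'
#' Z-scores each bin using the mean and SD of the full sample (both arms
#' pooled), then returns per-arm mean z curves and their difference. Because
#' standardization uses the pooled sample, the arm mean curves satisfy the
#' mirror identity `n_lo * zbar_lo + n_hi * zbar_hi = 0` in every bin.
#'
#' @param power_mat Numeric matrix, children x 48 bins (absolute power).
#' @param arm Factor/character of length `nrow(power_mat)` with levels
#'   low/high.
#' @return List: `z` (children x 48 z-score matrix), `curves` (data frame
#'   `freq_lo`, `z_low`, `z_high`, `diff`), `n` (named arm sizes).
#' @export
standardize_bins <- function(power_mat, arm) {
  stopifnot(is.matrix(power_mat), ncol(power_mat) == 48,
            nrow(power_mat) == length(arm), nrow(power_mat) >= 2)
  arm <- factor(as.character(arm), levels = c("low", "high"))
  sds <- apply(power_mat, 2, stats::sd)
  if (any(sds == 0)) {
    stopf("zero SD in bin(s): %s Hz",
          paste(bin_edges()[sds == 0], collapse = ", "))
  }
  z <- scale(power_mat)
  z_low <- colMeans(z[arm == "low", , drop = FALSE])
  z_high <- colMeans(z[arm == "high", , drop = FALSE])
  list(z = z,
       curves = data.frame(freq_lo = bin_edges(), z_low = z_low,
                           z_high = z_high, diff = z_high - z_low),
       n = c(low = sum(arm == "low"), high = sum(arm == "high")))
}

#' Per-channel band power for one child
#'
#' Used for topographic maps: band power computed channel by channel rather
#' than averaged over the scalp.
#'
#' @param ep An `epoch_set`.
#' @param bands Band definitions.
#' @param channels Channels to evaluate (default: scalp channels).
#' @return Data frame: `channel`, `band`, `absolute`.
#' @export
channel_band_power <- function(ep, bands = default_bands(),
                               channels = scalp_channels(ep$channels, ep$reference)) {
  out <- lapply(channels, function(ch) {
    bp <- band_power(bin_spectrum(ep, channels = ch), bands)
    data.frame(channel = ch, band = names(bp$absolute),
               absolute = unname(bp$absolute), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
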