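#' Re-reference a recording to the temporal-electrode average
#'
#' Subtracts the sample-wise mean of the T7 and T8 electrodes from every
#' channel. After re-referencing, T7/T8 carry only their half-difference and
#' are excluded from downstream whole-scalp averages (the recording's
#' `$reference` field records this).
#'
#' @param rec An `eeg_recording`.
#' @param ref_channels Reference pair, default `c("T7", "T8")`.
#' @return The re-referenced recording with `$reference` set.
#' @export
rereference <- function(rec, ref_channels = c("T7", "T8")) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(ref_channels, rec$channels)
  if (length(missing)) stopf("reference channel(s) missing from recording: %s",
                             paste(missing, collapse = ", "))
  ref <- colMeans(rec$samples[ref_channels, , drop = FALSE])
  rec$samples <- sweep(rec$samples, 2, ref)
  rec$reference <- ref_channels
  rec
}

# Channels contributing to scalp averages: everything except the reference pair.
scalp_channels <- function(rec_or_channels, reference = NULL) {
  if (inherits(rec_or_channels, "eeg_recording")) {
    reference <- rec_or_channels$reference
    ch <- rec_or_channels$channels
  } else {
    ch <- rec_or_channels
  }
  setdiff(ch, reference)
}

#' Zero-phase band-pass filter a recording
#'
#' Applies a forward-backward (zero-phase) Butterworth band-pass to every
#' channel, implemented as a 2nd-order high-pass at `low_hz` cascaded with a
#' 4th-order low-pass at `high_hz` (the cascade keeps the very low normalized
#' high-pass edge numerically stable). Forward-backward filtering applies the
#' magnitude response twice; repeated calls apply it again.
#'
#' @param rec An `eeg_recording`.
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @return The filtered recording (length preserved).
#' @export
filter_recording <- function(rec, low_hz = 0.3, high_hz = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rec$fs / 2)) {
    stopf("invalid band edges: need 0 < low_hz < high_hz < fs/2 (got %g-%g Hz at fs=%g)",
          low_hz, high_hz, rec$fs)
  }
  hp <- signal::butter(2, low_hz / (rec$fs / 2), type = "high")
  lp <- signal::butter(4, high_hz / (rec$fs / 2), type = "low")
  for (i in seq_len(nrow(rec$samples))) {
    x <- signal::filtfilt(hp, rec$samples[i, ])
    rec$samples[i, ] <- signal::filtfilt(lp, x)
  }
  rec$filter_band <- c(low_hz, high_hz)
  rec
}

#' Segment a recording into epochs and reject by amplitude
#'
#' Cuts the recording into fixed-length (optionally overlapping) epochs and
#' rejects any epoch in which any channel's absolute amplitude exceeds
#' `amp_uv`. Epochs shorter than `epoch_s` at the recording tail are dropped.
#' A recording shorter than one epoch yields an empty epoch set, not an
#' error.
#'
#' @param rec An `eeg_recording`.
#' @param epoch_s Epoch length in seconds.
#' @param overlap Fractional overlap between consecutive epochs in `[0, 1)`.
#' @param amp_uv Rejection threshold in uV (use `Inf` to retain everything).
#' @return An object of class `epoch_set`: `epochs` (array
#'   n_epochs x channels x samples, retained epochs only), `fs`, `channels`,
#'   `reference`, `n_usable`, and `log` (one row per candidate epoch with
#'   start time, peak absolute amplitude, and kept flag).
#' @export
epoch_and_reject <- function(rec, epoch_s = 1, overlap = 0.5, amp_uv = 100) {
  stopifnot(inherits(rec, "eeg_recording"), overlap >= 0, overlap < 1, epoch_s > 0)
  len <- round(epoch_s * rec$fs)
  step <- max(1L, round(len * (1 - overlap)))
  n <- ncol(rec$samples)
  starts <- if (n < len) integer(0) else seq(1L, n - len + 1L, by = step)

  keep <- logical(length(starts))
  peak <- numeric(length(starts))
  for (i in seq_along(starts)) {
    seg <- rec$samples[, starts[i]:(starts[i] + len - 1L), drop = FALSE]
    peak[i] <- max(abs(seg))
    keep[i] <- peak[i] <= amp_uv
  }
  kept <- which(keep)
  epochs <- array(0, dim = c(length(kept), nrow(rec$samples), len),
                  dimnames = list(NULL, rec$channels, NULL))
  for (j in seq_along(kept)) {
    epochs[j, , ] <- rec$samples[, starts[kept[j]]:(starts[kept[j]] + len - 1L)]
  }
  structure(list(
    epochs = epochs, fs = rec$fs, channels = rec$channels,
    reference = rec$reference, epoch_s = epoch_s, amp_uv = amp_uv,
    n_usable = length(kept),
    log = data.frame(epoch = seq_along(starts),
                     start_s = (starts - 1) / rec$fs,
                     peak_uv = peak, kept = keep)
  ), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d usable / %d candidate epochs of %g s, %d channels\n",
              x$n_usable, nrow(x$log), x$epoch_s, length(x$channels)))
  invisible(x)
}
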