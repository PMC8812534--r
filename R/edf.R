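# European Data Format (EDF) serialization for recordings.
#
# Minimal but standard-conforming EDF: fixed 256-byte global header,
# 256 bytes per signal, then 1-second data records of 16-bit little-endian
# integers. Each channel is scaled into the full digital range using a
# symmetric physical range, so quantization error is bounded by
# physical_range / 2^16 per sample. Partial trailing records (less than one
# record duration) are dropped on write.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width = 8) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  while (nchar(s) > width) {
    s <- formatC(x, format = "g", digits = max(1, nchar(gsub("[^0-9]", "", s)) - 1))
    x <- as.numeric(s)
  }
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' @param rec An `eeg_recording`.
#' @param path Output file path.
#' @param patient,recording_id Free-text EDF header fields.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path, patient = "X", recording_id = "synthetic") {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  ns <- length(rec$channels)
  n_records <- floor(ncol(rec$samples) / fs)
  if (n_records < 1) stopf("recording shorter than one 1-s EDF record")
  spr <- as.integer(fs)

  phys_max <- pmax(apply(abs(rec$samples), 1, max), 1)
  dig_max <- 32767
  con <- file(path, "wb")
  on.exit(close(con))

  writeChar(paste0(
    edf_pad("0", 8), edf_pad(patient, 80), edf_pad(recording_id, 80),
    edf_pad("01.01.20", 8), edf_pad("00.00.00", 8),
    edf_pad(as.character(256 * (1 + ns)), 8), edf_pad("", 44),
    edf_pad(as.character(n_records), 8), edf_pad("1", 8),
    edf_pad(as.character(ns), 4)
  ), con, eos = NULL)

  field <- function(vals, width) {
    writeChar(paste(vapply(vals, edf_pad, "", width = width), collapse = ""), con, eos = NULL)
  }
  field(rec$channels, 16)
  field(rep("", ns), 80)                                  # transducer
  field(rep("uV", ns), 8)                                 # physical dimension
  writeChar(paste(vapply(-phys_max, edf_num, ""), collapse = ""), con, eos = NULL)
  writeChar(paste(vapply(phys_max, edf_num, ""), collapse = ""), con, eos = NULL)
  field(rep(as.character(-dig_max), ns), 8)
  field(rep(as.character(dig_max), ns), 8)
  field(rep("", ns), 80)                                  # prefiltering
  field(rep(as.character(spr), ns), 8)
  field(rep("", ns), 32)

  scale <- dig_max / phys_max
  for (r in seq_len(n_records)) {
    idx <- ((r - 1) * spr + 1):(r * spr)
    for (ch in seq_len(ns)) {
      dig <- as.integer(round(rec$samples[ch, idx] * scale[ch]))
      writeBin(dig, con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file into a recording
#'
#' @param path Path to an EDF file with a uniform sampling rate across
#'   signals and 1-second records.
#' @return An `eeg_recording` in uV.
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8); rd(8); rd(44)
  n_records <- as.integer(rd(8))
  record_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))

  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), "")
  labels <- fields(16)
  fields(80)
  dims <- fields(8)
  phys_min <- as.numeric(fields(8))
  phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8))
  dig_max <- as.numeric(fields(8))
  fields(80)
  spr <- as.integer(fields(8))
  fields(32)
  if (length(unique(spr)) != 1) stopf("channels with differing samples-per-record are not supported")
  fs <- spr[1] / record_dur

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset <- phys_min - gain * dig_min
  samples <- matrix(0, ns, n_records * spr[1])
  for (r in seq_len(n_records)) {
    for (ch in seq_len(ns)) {
      dig <- readBin(con, "integer", n = spr[1], size = 2, endian = "little")
      samples[ch, ((r - 1) * spr[1] + 1):(r * spr[1])] <- dig * gain[ch] + offset[ch]
    }
  }
  if (!all(tolower(dims) %in% c("uv", ""))) {
    stopf("unsupported physical dimension(s): %s", paste(unique(dims), collapse = ", "))
  }
  new_recording(samples, labels, fs = fs)
}
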