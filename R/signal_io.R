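#' Construct a polysomnography recording
#'
#' Container for one animal-session's EEG and EMG traces plus sampling and
#' design metadata.
#'
#' @param eeg,emg numeric sample vectors, uV; must be the same length.
#' @param sampling_rate Hz (> 0).
#' @param animal_id,group,session metadata labels.
#' @return object of class `recording`.
#' @export
recording <- function(eeg, emg, sampling_rate, animal_id = "unknown",
                      group = NA_character_, session = NA_character_) {
  if (!is.numeric(eeg) || !is.numeric(emg))
    stop_input("eeg and emg must be numeric vectors")
  if (length(eeg) != length(emg))
    stop_input("eeg (%d) and emg (%d) must have equal length",
               length(eeg), length(emg))
  check_scalar_num(sampling_rate, "sampling_rate", 0, strict = TRUE)
  structure(list(eeg = as.numeric(eeg), emg = as.numeric(emg),
                 sampling_rate = sampling_rate, animal_id = animal_id,
                 group = group, session = session),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s %s/%s: %d samples @ %g Hz (%.1f min)\n",
              x$animal_id, x$group, x$session, length(x$eeg),
              x$sampling_rate, length(x$eeg) / x$sampling_rate / 60))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording a [recording()].
#' @return seconds.
#' @export
recording_duration <- function(recording) {
  length(recording$eeg) / recording$sampling_rate
}

#' Read / write recordings (CSV or EDF)
#'
#' CSV dialect: UTF-8, comma-separated, header `time_s,eeg_uV,emg_uV`.
#' EDF files follow the European Data Format: one data record per second,
#' two signals named `EEG` and `EMG`, 16-bit samples scaled between the
#' per-signal physical extrema.
#'
#' @param path file path.
#' @param format `"csv"` or `"edf"`; default guessed from the extension.
#' @param channels length-2 character vector naming the EEG and EMG channels
#'   expected in an EDF file.
#' @param sampling_rate required for CSV with fewer than two rows; otherwise
#'   inferred from the time column (CSV) or the header (EDF).
#' @param ... metadata passed on to [recording()].
#' @return `read_recording` returns a [recording()]; `write_recording`
#'   returns `path` invisibly.
#' @export
read_recording <- function(path, format = c("auto", "csv", "edf"),
                           channels = c("EEG", "EMG"), sampling_rate = NULL,
                           ...) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (!file.exists(path)) stop_input("file not found: %s", path)
  if (format == "csv") read_recording_csv(path, sampling_rate, ...)
  else read_recording_edf(path, channels, ...)
}

#' @rdname read_recording
#' @param rec a [recording()] to serialise.
#' @export
write_recording <- function(rec, path, format = c("auto", "csv", "edf")) {
  stopifnot(inherits(rec, "recording"))
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.edf$", path, ignore.case = TRUE)) "edf" else "csv"
  if (format == "csv") {
    df <- data.frame(time_s = (seq_along(rec$eeg) - 1L) / rec$sampling_rate,
                     eeg_uV = rec$eeg, emg_uV = rec$emg)
    utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  } else {
    write_recording_edf(rec, path)
  }
  invisible(path)
}

read_recording_csv <- function(path, sampling_rate = NULL, ...) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("time_s", "eeg_uV", "emg_uV")
  if (!all(need %in% names(df)))
    stop_input("CSV %s must have header %s (found: %s)", path,
               paste(need, collapse = ","), paste(names(df), collapse = ","))
  if (is.null(sampling_rate)) {
    if (nrow(df) < 2L)
      stop_input("cannot infer sampling rate from %d row(s); pass sampling_rate", nrow(df))
    dt <- diff(df$time_s)
    if (any(abs(dt - dt[1L]) > 1e-6 * dt[1L]))
      stop_input("non-uniform time column in %s", path)
    sampling_rate <- 1 / dt[1L]
  }
  recording(df$eeg_uV, df$emg_uV, sampling_rate, ...)
}

# --- minimal EDF (16-bit, one-second records, two signals) ------------------

edf_pad <- function(x, width) formatC(as.character(x), width = width, flag = "-")

# shortest "g" representation fitting an 8-character EDF header field
edf_num8 <- function(v) vapply(v, function(x) {
  for (d in 7:1) {
    s <- formatC(x, format = "g", digits = d)
    if (nchar(s) <= 8L) return(s)
  }
  "0"
}, character(1))

write_recording_edf <- function(rec, path) {
  fs <- rec$sampling_rate
  if (abs(fs - round(fs)) > 1e-9)
    stop_input("EDF writer requires an integer sampling rate (got %g)", fs)
  fs <- as.integer(round(fs))
  n_rec <- floor(length(rec$eeg) / fs)
  sig <- list(EEG = rec$eeg[seq_len(n_rec * fs)],
              EMG = rec$emg[seq_len(n_rec * fs)])
  ns <- 2L
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8), edf_pad(rec$animal_id, 80), edf_pad("recording", 80),
    edf_pad("01.01.01", 8), edf_pad("00.00.00", 8),
    edf_pad(256L + 256L * ns, 8), edf_pad("", 44),
    edf_pad(n_rec, 8), edf_pad(1, 8), edf_pad(ns, 4))
  writeChar(hdr, con, eos = NULL)
  pmin_ <- vapply(sig, function(s) min(s, -1), numeric(1))
  pmax_ <- vapply(sig, function(s) max(s, 1), numeric(1))
  field <- function(vals, width) for (v in vals) writeChar(edf_pad(v, width), con, eos = NULL)
  field(names(sig), 16)                                   # label
  field(rep("", ns), 80)                                  # transducer
  field(rep("uV", ns), 8)                                 # physical dimension
  field(edf_num8(pmin_), 8)                               # physical min
  field(edf_num8(pmax_), 8)                               # physical max
  field(rep(-32768L, ns), 8)                              # digital min
  field(rep(32767L, ns), 8)                               # digital max
  field(rep("", ns), 80)                                  # prefiltering
  field(rep(fs, ns), 8)                                   # samples per record
  field(rep("", ns), 32)                                  # reserved
  for (r in seq_len(n_rec)) for (j in seq_len(ns)) {
    s <- sig[[j]][seq.int((r - 1L) * fs + 1L, r * fs)]
    d <- round((s - pmin_[j]) / (pmax_[j] - pmin_[j]) * 65535 - 32768)
    writeBin(as.integer(pmin(pmax(d, -32768), 32767)), con, size = 2L,
             endian = "little")
  }
  invisible(path)
}

read_recording_edf <- function(path, channels = c("EEG", "EMG"), ...) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); animal_id <- rd(80); rd(80); rd(8); rd(8)
  rd(8); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (is.na(ns) || ns < 1L) stop_input("unreadable EDF header in %s", path)
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fields(16); fields(80); fields(8)
  pmin_ <- as.numeric(fields(8)); pmax_ <- as.numeric(fields(8))
  dmin_ <- as.numeric(fields(8)); dmax_ <- as.numeric(fields(8))
  fields(80); spr <- as.integer(fields(8)); fields(32)
  idx <- match(channels, labels)
  if (anyNA(idx))
    stop_input("EDF %s lacks channel(s) %s; present: %s", path,
               paste(channels[is.na(idx)], collapse = ", "),
               paste(labels, collapse = ", "))
  if (length(unique(spr[idx])) != 1L)
    stop_input("EDF %s: configured channels have inconsistent sampling (%s)",
               path, paste(spr[idx], collapse = ", "))
  out <- lapply(idx, function(i) numeric(n_rec * spr[i]))
  for (r in seq_len(n_rec)) for (j in seq_len(ns)) {
    d <- readBin(con, "integer", n = spr[j], size = 2L, signed = TRUE,
                 endian = "little")
    k <- match(j, idx)
    if (!is.na(k))
      out[[k]][seq.int((r - 1L) * spr[j] + 1L, r * spr[j])] <-
        pmin_[j] + (d - dmin_[j]) / (dmax_[j] - dmin_[j]) * (pmax_[j] - pmin_[j])
  }
  recording(out[[1L]], out[[2L]], spr[idx[1L]] / rec_dur,
            animal_id = animal_id, ...)
}

#' Zero-phase Butterworth band filtering
#'
#' Forward-backward (zero-phase) filtering with a 4th-order Butterworth
#' design, so that event timing is not distorted. A lower edge of 0 Hz is
#' interpreted as a pure low-pass (a 0 Hz high-pass being undefined); the
#' acquisition bands of the emulated system are EEG 0-40 Hz and EMG
#' 1-400 Hz.
#'
#' @param x numeric sample vector.
#' @param sampling_rate Hz.
#' @param low,high band edges in Hz; `0 <= low < high < sampling_rate / 2`.
#' @param order filter order (default 4).
#' @return filtered samples, same length as `x`.
#' @export
bandpass_filter <- function(x, sampling_rate, low, high, order = 4) {
  check_scalar_num(low, "low", 0)
  check_scalar_num(high, "high", 0, strict = TRUE)
  if (low >= high || high >= sampling_rate / 2)
    stop_input("need 0 <= low < high < Nyquist (%g Hz); got [%g, %g]",
               sampling_rate / 2, low, high)
  bf <- if (low == 0)
    signal::butter(order, high / (sampling_rate / 2), type = "low")
  else
    signal::butter(order, c(low, high) / (sampling_rate / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Decimate a recording to a lower sampling rate
#'
#' Anti-alias filtered downsampling (default target 250 Hz), used before
#' staging and spindle detection: the analysis content lies below 40 Hz, so
#' the 3000 Hz acquisition rate only costs runtime.
#'
#' @param rec a [recording()].
#' @param to_hz target rate; must divide the current rate.
#' @return a [recording()] at `to_hz`.
#' @export
downsample_recording <- function(rec, to_hz = 250) {
  stopifnot(inherits(rec, "recording"))
  q <- rec$sampling_rate / to_hz
  if (abs(q - round(q)) > 1e-9 || q < 1)
    stop_input("target rate %g Hz must divide the sampling rate %g Hz",
               to_hz, rec$sampling_rate)
  q <- as.integer(round(q))
  if (q == 1L) return(rec)
  keep <- seq(1L, length(rec$eeg), by = q)
  eeg <- bandpass_filter(rec$eeg, rec$sampling_rate, 0, 0.4 * to_hz)[keep]
  emg <- bandpass_filter(rec$emg, rec$sampling_rate, 0, 0.4 * to_hz)[keep]
  recording(eeg, emg, to_hz, animal_id = rec$animal_id,
            group = rec$group, session = rec$session)
}

#' Cut a recording into fixed-length scoring epochs
#'
#' Consecutive, non-overlapping, half-open epochs; a trailing partial epoch
#' is discarded.
#'
#' @param rec a [recording()].
#' @param epoch_length seconds (default 5, the scoring granularity).
#' @return object of class `epoch_set`: list with `eeg` and `emg` (matrices,
#'   one column per epoch), `epoch_length`, `sampling_rate`, `n_epochs`.
#' @export
epoch_signal <- function(rec, epoch_length = 5) {
  stopifnot(inherits(rec, "recording"))
  check_scalar_num(epoch_length, "epoch_length", 0, strict = TRUE)
  ep_n <- round(epoch_length * rec$sampling_rate)
  n_epochs <- floor(length(rec$eeg) / ep_n)
  take <- seq_len(n_epochs * ep_n)
  structure(list(
    eeg = matrix(rec$eeg[take], nrow = ep_n, ncol = n_epochs),
    emg = matrix(rec$emg[take], nrow = ep_n, ncol = n_epochs),
    epoch_length = epoch_length, sampling_rate = rec$sampling_rate,
    n_epochs = n_epochs), class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  cat(sprintf("<epoch_set> %d epochs of %g s @ %g Hz\n",
              x$n_epochs, x$epoch_length, x$sampling_rate))
  invisible(x)
}
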