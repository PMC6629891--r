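# Preprocessing: zero-phase Butterworth band-pass filtering, resampling to
# the analysis rate, per-epoch quality statistics, and the 4-MAD artifact
# rejection rule.

#' Band-pass filter specification
#'
#' 4th-order Butterworth with -3 dB cutoffs per pass, applied forward and
#' reverse in time (zero phase, -6 dB at the cutoffs after both passes).
#' The conventional specs are 0.3-35 Hz for EEG and 0.3-10 Hz for EOG.
#'
#' @param low_hz,high_hz Cutoff frequencies in Hz (0 < low < high).
#' @param order Filter order per pass.
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz, high_hz, order = 4L) {
  if (!(low_hz > 0 && high_hz > low_hz)) {
    stop_param("cutoffs must satisfy 0 < low_hz < high_hz")
  }
  structure(list(order = as.integer(order), low_hz = low_hz, high_hz = high_hz),
            class = "filter_spec")
}

#' @rdname filter_spec
#' @export
eeg_filter_spec <- function() filter_spec(0.3, 35)

#' @rdname filter_spec
#' @export
eog_filter_spec <- function() filter_spec(0.3, 10)

#' Zero-phase Butterworth band-pass
#'
#' Filters forward and reverse in time with odd (reflection) extension at
#' both ends to suppress edge transients, giving zero phase distortion and
#' the squared Butterworth magnitude response.
#'
#' @param x Numeric signal (microvolt).
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered signal, same length as `x`.
#' @export
zero_phase_bandpass <- function(x, fs, spec = eeg_filter_spec()) {
  if (spec$high_hz >= fs / 2) stop_param("high cutoff must be below Nyquist")
  rng <- suppressWarnings(range(x))
  if (anyNA(rng) || any(is.infinite(rng))) {
    stop("signal contains NA or non-finite values", call. = FALSE)
  }
  bf <- signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / (fs / 2),
                       type = "pass")
  n <- length(x)
  if (n <= 3L * spec$order) stop_param("signal too short for the filter order")
  filtfilt_cpp(bf$b, bf$a, x, 30L * (length(bf$a) - 1L))
}

#' Resample (downsample) a signal
#'
#' Applies an antialiasing low-pass (8th-order Butterworth, zero phase) at
#' `antialias_hz` -- capped below the output Nyquist -- and then maps to the
#' output grid by linear interpolation. Upsampling is not supported.
#'
#' @param x Numeric signal.
#' @param fs_in,fs_out Input/output sampling rates (Hz), `fs_out <= fs_in`.
#' @param antialias_hz Antialiasing cutoff (default 80 Hz, the conventional
#'   choice for a 1000 -> 250 Hz reduction).
#' @return Signal of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_to <- function(x, fs_in, fs_out, antialias_hz = 80) {
  if (fs_out > fs_in) stop_param("`fs_out` must not exceed `fs_in` (no upsampling)")
  if (fs_out == fs_in) return(x)
  cutoff <- min(antialias_hz, 0.45 * fs_out)
  bf <- signal::butter(8L, cutoff / (fs_in / 2), type = "low")
  n <- length(x)
  y <- filtfilt_cpp(bf$b, bf$a, x, 30L * (length(bf$a) - 1L))
  n_out <- round(n * fs_out / fs_in)
  t_out <- (seq_len(n_out) - 1L) * fs_in / fs_out + 1
  approx(seq_len(n), y, xout = pmin(t_out, n))$y
}

#' Per-epoch signal-quality statistics
#'
#' For every complete 30-s epoch and channel: the standard deviation and
#' range of the signal and the range of its first difference.
#'
#' @param rec A [psg_recording()].
#' @return Data frame with columns `epoch`, `channel`, `sd`, `range`,
#'   `d1_range`.
#' @export
epoch_statistics <- function(rec) {
  ne <- n_epochs(rec)
  if (ne < 1L) stop("recording holds no complete epoch", call. = FALSE)
  out <- lapply(names(rec$signals), function(ch) {
    m <- epoch_matrix(rec, ch)
    st <- col_quality_stats_cpp(m)
    data.frame(
      epoch = seq_len(ne),
      channel = ch,
      sd = st$sd,
      range = st$range,
      d1_range = st$d1_range,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' MAD-based artifact rejection
#'
#' For each of the three quality statistics, the per-epoch mean across
#' channels is compared against `median + n_mad * MAD` computed over all
#' epochs of the recording (unscaled MAD, upper one-sided). An epoch is
#' rejected when any statistic exceeds its threshold. A degenerate MAD of 0
#' is floored at `mad_floor` so that exact ties survive.
#'
#' @param stats Output of [epoch_statistics()].
#' @param n_mad Threshold multiplier (4 by convention).
#' @param mad_floor Lower bound for the MAD, in the statistic's units.
#' @return Logical keep flags, one per epoch.
#' @export
reject_artifacts <- function(stats, n_mad = 4, mad_floor = 1e-12) {
  epochs <- sort(unique(stats$epoch))
  if (length(epochs) < 5L) {
    warning("fewer than 5 epochs; keeping all")
    return(rep(TRUE, length(epochs)))
  }
  keep <- rep(TRUE, length(epochs))
  for (stat in c("sd", "range", "d1_range")) {
    v <- tapply(stats[[stat]], stats$epoch, mean)
    v <- as.numeric(v[as.character(epochs)])
    med <- median(v)
    madv <- max(median(abs(v - med)), mad_floor)
    keep <- keep & (v <= med + n_mad * madv)
  }
  keep
}

#' Preprocess a recording for symbolization
#'
#' Resamples to the analysis rate if needed, applies the zero-phase EEG and
#' EOG band-pass filters, computes per-epoch quality statistics and the
#' MAD keep flags, and optionally trims leading/trailing epochs (the
#' automated stand-in for visual removal of contaminated night edges).
#'
#' @param rec A [psg_recording()].
#' @param fs_out Analysis sampling rate (default 250 Hz).
#' @param trim_epochs Number of epochs to drop at each end of the night.
#' @param eeg_spec,eog_spec Filter specifications.
#' @return An object of class `psg_preprocessed`: list with the filtered
#'   `recording`, logical `keep` flags and the `stats` data frame.
#' @export
preprocess_recording <- function(rec, fs_out = 250, trim_epochs = 0L,
                                 eeg_spec = eeg_filter_spec(),
                                 eog_spec = eog_filter_spec()) {
  if (rec$fs != fs_out) {
    ratio <- fs_out / rec$fs
    signals <- lapply(rec$signals, resample_to, fs_in = rec$fs, fs_out = fs_out)
    rec <- psg_recording(signals, fs = fs_out,
                         lights_off_idx = max(1L, round((rec$lights_off_idx - 1L) * ratio) + 1L),
                         lights_on_idx = min(length(signals[[1L]]),
                                             round(rec$lights_on_idx * ratio)),
                         epoch_len_s = rec$epoch_len_s)
  }
  filt <- rec
  filt$signals$C3A2 <- zero_phase_bandpass(rec$signals$C3A2, rec$fs, eeg_spec)
  filt$signals$O1A2 <- zero_phase_bandpass(rec$signals$O1A2, rec$fs, eeg_spec)
  filt$signals$EOGL <- zero_phase_bandpass(rec$signals$EOGL, rec$fs, eog_spec)
  filt$signals$EOGR <- zero_phase_bandpass(rec$signals$EOGR, rec$fs, eog_spec)
  stats <- epoch_statistics(filt)
  keep <- reject_artifacts(stats)
  if (trim_epochs > 0L) {
    ne <- length(keep)
    k <- min(trim_epochs, ne)
    keep[seq_len(k)] <- FALSE
    keep[seq.int(ne - k + 1L, ne)] <- FALSE
  }
  structure(list(recording = filt, keep = keep, stats = stats),
            class = "psg_preprocessed")
}

#' Write keep flags as two-column delimited text
#'
#' @param keep Logical keep flags.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_keep_flags <- function(keep, path) {
  write.table(data.frame(epoch_index = seq_along(keep), keep = as.integer(keep)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
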