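#' Four-channel polysomnography recording
#'
#' Container for the analyzed derivations C3-A2, O1-A2, EOGL-A2 and EOGR-A1,
#' together with the sampling rate, lights-off/lights-on sample bounds and
#' the 30-s epoch grid derived from them.
#'
#' @param signals Named list of four equal-length numeric vectors (microvolt)
#'   with names `C3A2`, `O1A2`, `EOGL`, `EOGR`.
#' @param fs Sampling rate in Hz (> 0).
#' @param lights_off_idx,lights_on_idx Sample indices bounding the analyzed
#'   span; defaults cover the whole signal.
#' @param epoch_len_s Epoch length in seconds (30 by convention).
#' @return An object of class `psg_recording`.
#' @export
psg_recording <- function(signals, fs,
                          lights_off_idx = 1L,
                          lights_on_idx = length(signals[[1L]]),
                          epoch_len_s = 30) {
  wanted <- c("C3A2", "O1A2", "EOGL", "EOGR")
  if (!is.list(signals) || !setequal(names(signals), wanted)) {
    stop_param("`signals` must be a named list with channels ",
               paste(wanted, collapse = ", "))
  }
  signals <- signals[wanted]
  n <- unique(vapply(signals, length, integer(1)))
  if (length(n) != 1L) stop_param("all channels must have the same length")
  if (!is.numeric(fs) || fs <= 0) stop_param("`fs` must be a positive number")
  if (lights_off_idx < 1L || lights_on_idx > n || lights_off_idx > lights_on_idx) {
    stop_param("lights bounds must lie within the signal")
  }
  structure(
    list(signals = signals, fs = fs,
         lights_off_idx = as.integer(lights_off_idx),
         lights_on_idx = as.integer(lights_on_idx),
         epoch_len_s = epoch_len_s),
    class = "psg_recording")
}

#' Number of complete epochs between lights off and lights on
#'
#' @param rec A [psg_recording()].
#' @return Integer count of complete `epoch_len_s` epochs; a trailing
#'   incomplete epoch is dropped.
#' @export
n_epochs <- function(rec) {
  spe <- samples_per_epoch(rec)
  as.integer((rec$lights_on_idx - rec$lights_off_idx + 1L) %/% spe)
}

samples_per_epoch <- function(rec) as.integer(round(rec$epoch_len_s * rec$fs))

# Matrix view of one channel cut into complete epochs
# (samples_per_epoch x n_epochs).
epoch_matrix <- function(rec, channel) {
  spe <- samples_per_epoch(rec)
  ne <- n_epochs(rec)
  if (ne < 1L) stop_param("recording holds no complete epoch")
  idx <- rec$lights_off_idx - 1L + seq_len(spe * ne)
  matrix(rec$signals[[channel]][idx], nrow = spe, ncol = ne)
}

#' @export
print.psg_recording <- function(x, ...) {
  cat(sprintf("<psg_recording> %d channels, fs = %g Hz, %d complete %g-s epochs\n",
              length(x$signals), x$fs, n_epochs(x), x$epoch_len_s))
  invisible(x)
}

#' Write / read a recording as delimited text
#'
#' One column per channel with a two-line header carrying the channel names
#' and the sampling-rate / lights metadata. Values are microvolt.
#'
#' @param rec A [psg_recording()].
#' @param path Output file path.
#' @return `write_recording_txt()` returns `path` invisibly;
#'   `read_recording_txt()` returns a [psg_recording()].
#' @export
write_recording_txt <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g lights_off_idx=%d lights_on_idx=%d epoch_len_s=%g",
                     rec$fs, rec$lights_off_idx, rec$lights_on_idx,
                     rec$epoch_len_s), con)
  df <- as.data.frame(rec$signals)
  write.table(format(df, digits = 7, trim = TRUE, scientific = FALSE),
              con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_recording_txt
#' @export
read_recording_txt <- function(path) {
  hdr <- readLines(path, n = 1L)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[0-9.eE+-]+", hdr))[[1L]]
  meta <- as.list(setNames(as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv)))
  df <- read.table(path, header = TRUE, sep = "\t", skip = 1L)
  psg_recording(as.list(df), fs = meta$fs,
                lights_off_idx = meta$lights_off_idx,
                lights_on_idx = meta$lights_on_idx,
                epoch_len_s = meta$epoch_len_s)
}

#' Write / read a hypnogram as two-column delimited text
#'
#' Columns are `epoch_index` (1-based) and `stage` (W/N1/N2/N3/REM).
#'
#' @param hypnogram Character vector of stage labels.
#' @param path File path.
#' @return `write_hypnogram_txt()` returns `path` invisibly;
#'   `read_hypnogram_txt()` returns the stage vector.
#' @export
write_hypnogram_txt <- function(hypnogram, path) {
  write.table(data.frame(epoch_index = seq_along(hypnogram), stage = hypnogram),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hypnogram_txt
#' @export
read_hypnogram_txt <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", colClasses = c("integer", "character"))
  df$stage[order(df$epoch_index)]
}
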