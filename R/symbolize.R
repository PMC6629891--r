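# Symbolization: 1-s band power (and EOG cross-correlation), quantile
# letters, 3-letter words from moving 3-s windows, and per-epoch word
# counts over the composite 1,192-word vocabulary.

EEG_LETTERS <- c("V", "L", "M", "H", "E")
EOG_LETTERS <- c("V", "L", "H", "E")

#' Frequency band definitions
#'
#' Half-open intervals `[low, high)` in Hz. EEG uses the classical clinical
#' bands delta `[0.5, 4)`, theta `[4, 8)`, alpha `[8, 13)`, beta `[13, 35)`;
#' the EOG power stream uses `[0.3, 5)`.
#'
#' @return Named list of length-2 numeric vectors.
#' @export
default_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 35),
       eog_low = c(0.3, 5))
}

#' The 11 symbol streams
#'
#' Eight EEG streams (two channels x four bands, 5-letter alphabet), two
#' EOG power streams and one EOG cross-correlation stream (4-letter
#' alphabet).
#'
#' @return Data frame with columns `stream_id`, `channel`, `band`,
#'   `alphabet_size`.
#' @export
stream_table <- function() {
  eeg <- expand.grid(channel = c("C3A2", "O1A2"),
                     band = c("delta", "theta", "alpha", "beta"),
                     stringsAsFactors = FALSE)
  eeg <- eeg[order(eeg$channel), ]
  df <- rbind(
    data.frame(stream_id = paste(eeg$channel, eeg$band, sep = "."),
               channel = eeg$channel, band = eeg$band, alphabet_size = 5L,
               stringsAsFactors = FALSE),
    data.frame(stream_id = c("EOGL.pow", "EOGR.pow", "EOG.xcorr"),
               channel = c("EOGL", "EOGR", "EOG"),
               band = c("eog_low", "eog_low", NA),
               alphabet_size = 4L, stringsAsFactors = FALSE)
  )
  rownames(df) <- NULL
  df
}

# |FFT|^2 of non-overlapping 1-s rectangular windows: fs x n_bins matrix.
bin_spectrum <- function(x, fs) {
  fs <- as.integer(round(fs))
  nbins <- length(x) %/% fs
  if (nbins < 1L) stop_param("signal shorter than one 1-s bin")
  m <- matrix(x[seq_len(fs * nbins)], nrow = fs)
  abs2_cpp(mvfft(m))
}

band_bins <- function(fs, low, high) {
  f <- 0:(fs - 1L)
  fmir <- pmin(f, fs - f)
  which(fmir >= low & fmir < high & f != 0L)
}

#' Per-1-s band power
#'
#' Fast Fourier transform of each non-overlapping 1-s rectangular window;
#' power is the sum of squared spectral magnitudes over the (two-sided)
#' frequency bins inside `[low, high)`, normalized by the squared bin
#' count, so that it estimates the band's variance contribution
#' (microvolt^2). A trailing partial second is dropped.
#'
#' @param x Numeric signal (microvolt).
#' @param fs Integer sampling rate (Hz).
#' @param band Length-2 numeric `[low, high)` in Hz, `high <= fs / 2`.
#' @return One power value per complete 1-s bin.
#' @export
band_power_series <- function(x, fs, band) {
  if (band[2L] > fs / 2) stop_param("band extends above Nyquist")
  if (length(x) < fs) stop_param("signal shorter than 1 s")
  px <- bin_spectrum(x, fs)
  sel <- band_bins(as.integer(round(fs)), band[1L], band[2L])
  colSums(px[sel, , drop = FALSE]) / as.integer(round(fs))^2
}

# Band power for all bands from one spectrum evaluation (internal fast path).
band_power_multi <- function(x, fs, bands) {
  px <- bin_spectrum(x, fs)
  fs <- as.integer(round(fs))
  lapply(bands, function(bd) colSums(px[band_bins(fs, bd[1L], bd[2L]), ,
                                        drop = FALSE]) / fs^2)
}

#' Per-1-s EOG cross-correlation
#'
#' Zero-lag Pearson correlation of the two EOG channels within each
#' non-overlapping 1-s bin; bins where either channel is (numerically)
#' constant yield 0.
#'
#' @param eogL,eogR Equal-length numeric signals.
#' @param fs Integer sampling rate (Hz).
#' @return One correlation value in `[-1, 1]` per complete 1-s bin.
#' @export
eog_crosscorr_series <- function(eogL, eogR, fs) {
  if (length(eogL) != length(eogR)) {
    stop("EOG channels differ in length", call. = FALSE)
  }
  fs <- as.integer(round(fs))
  nbins <- length(eogL) %/% fs
  l <- matrix(eogL[seq_len(fs * nbins)], nrow = fs)
  r <- matrix(eogR[seq_len(fs * nbins)], nrow = fs)
  l <- sweep(l, 2L, colMeans(l))
  r <- sweep(r, 2L, colMeans(r))
  num <- colSums(l * r)
  den <- sqrt(colSums(l^2) * colSums(r^2))
  out <- ifelse(den > 0, num / den, 0)
  pmin(1, pmax(-1, out))
}

#' Quantile categorization of a value series
#'
#' Cutoffs are the `k / n_categories` empirical quantiles (inverse-ECDF,
#' type 1) of `values` -- or of `reference` when the participant-specific
#' distribution should come from a subset such as artifact-free bins.
#' The mapping is monotone; values equal to a cutoff fall in the lower
#' category.
#'
#' @param values Numeric series to categorize.
#' @param n_categories 5 for EEG streams, 4 for EOG streams.
#' @param reference Optional series from which the cutoffs are computed.
#' @return Integer vector in `1..n_categories` with a `letters` attribute
#'   giving the category labels (V/L/M/H/E for 5, V/L/H/E for 4).
#' @export
quantile_letters <- function(values, n_categories = 5L, reference = values) {
  n_categories <- as.integer(n_categories)
  if (!n_categories %in% c(4L, 5L)) stop_param("`n_categories` must be 4 or 5")
  if (length(reference) < n_categories) {
    stop("fewer values than categories", call. = FALSE)
  }
  cutoffs <- quantile(reference, probs = seq_len(n_categories - 1L) / n_categories,
                      type = 1L, names = FALSE)
  idx <- findInterval(values, cutoffs, left.open = TRUE) + 1L
  labels <- if (n_categories == 5L) EEG_LETTERS else EOG_LETTERS
  structure(idx, letters = labels)
}

#' Category labels of a categorized series
#'
#' @param idx Output of [quantile_letters()].
#' @return Character vector of letters.
#' @export
letters_of <- function(idx) attr(idx, "letters")[as.integer(idx)]

#' 3-letter words of one epoch
#'
#' Concatenates letters from moving 3-s windows with 1-s steps, confined to
#' the epoch: 30 letters yield 28 words.
#'
#' @param letters Character (or categorized integer) vector of exactly 30
#'   letters.
#' @return Character vector of 28 words in temporal order.
#' @export
words_for_epoch <- function(letters) {
  if (!is.null(attr(letters, "letters"))) letters <- letters_of(letters)
  n <- length(letters)
  if (n != 30L) stop("an epoch must contribute exactly 30 letters", call. = FALSE)
  sliding_words(letters)
}

# The moving-window rule itself, for any letter count >= 3.
sliding_words <- function(letters) {
  n <- length(letters)
  paste0(letters[1:(n - 2L)], letters[2:(n - 1L)], letters[3:n])
}

#' The composite word vocabulary
#'
#' Every stream is namespaced, so identical letter triplets from different
#' streams are distinct entries: 5^3 = 125 words for each of the 8 EEG
#' streams and 4^3 = 64 for each of the 3 EOG streams, 1,192 words in
#' total.
#'
#' @return Data frame with columns `word_id`, `stream_id`, `word` (the
#'   letter triplet).
#' @export
build_vocabulary <- function() {
  st <- stream_table()
  blocks <- lapply(seq_len(nrow(st)), function(i) {
    letters <- if (st$alphabet_size[i] == 5L) EEG_LETTERS else EOG_LETTERS
    g <- expand.grid(l3 = letters, l2 = letters, l1 = letters,
                     stringsAsFactors = FALSE)
    data.frame(stream_id = st$stream_id[i],
               word = paste0(g$l1, g$l2, g$l3), stringsAsFactors = FALSE)
  })
  vocab <- do.call(rbind, blocks)
  data.frame(word_id = seq_len(nrow(vocab)), vocab, stringsAsFactors = FALSE)
}

#' Per-epoch word counts from letter streams
#'
#' Counts, for every kept epoch, how often each vocabulary word occurs in
#' each stream's 28 epoch-confined 3-s windows.
#'
#' @param streams Named list of 11 letter vectors (categorized integers or
#'   characters), one per stream of [stream_table()], all of length
#'   `30 * n_epochs`.
#' @param keep Logical keep flags, one per epoch.
#' @param vocab The [build_vocabulary()] table.
#' @return An object of class `word_counts`: list with `counts` (data frame
#'   `epoch`, `word_id`, `count`), `n_epochs`, `keep`, `vocab`.
#' @export
word_distribution <- function(streams, keep, vocab = build_vocabulary()) {
  st <- stream_table()
  if (!setequal(names(streams), st$stream_id)) {
    stop("streams must be named after stream_table()$stream_id", call. = FALSE)
  }
  nbin <- unique(vapply(streams, length, integer(1)))
  if (length(nbin) != 1L) stop("misaligned streams", call. = FALSE)
  ne <- nbin %/% 30L
  if (length(keep) != ne) stop("keep flags misaligned with epoch grid", call. = FALSE)
  kept <- which(keep)

  # words are encoded arithmetically: the vocabulary lists, per stream, all
  # triplets with the first letter slowest, so a triplet (i1, i2, i3) of
  # 1-based letter indices has word id
  # offset + (i1-1)*s^2 + (i2-1)*s + i3 for alphabet size s.
  offsets <- cumsum(c(0L, st$alphabet_size^3))[seq_len(nrow(st))]
  wid_all <- vector("list", length(st$stream_id))
  for (s in seq_along(st$stream_id)) {
    sid <- st$stream_id[s]
    lt <- streams[[sid]]
    a <- st$alphabet_size[s]
    labels <- if (a == 5L) EEG_LETTERS else EOG_LETTERS
    lt <- if (is.character(lt)) match(lt, labels) else as.integer(lt)
    if (anyNA(lt)) stop("unknown letters in stream ", sid, call. = FALSE)
    m <- matrix(lt[seq_len(30L * ne)], nrow = 30L)
    wid_all[[s]] <- offsets[s] +
      (m[1:28, kept, drop = FALSE] - 1L) * a^2 +
      (m[2:29, kept, drop = FALSE] - 1L) * a +
      m[3:30, kept, drop = FALSE]
  }
  nv <- nrow(vocab)
  epoch_of <- rep(rep(kept, each = 28L), times = length(wid_all))
  key <- (as.numeric(epoch_of) - 1) * nv + as.numeric(unlist(wid_all))
  r <- rle(sort(key))
  agg <- data.frame(
    epoch = as.integer((r$values - 1) %/% nv) + 1L,
    word_id = as.integer((r$values - 1) %% nv) + 1L,
    count = r$lengths
  )
  structure(list(counts = agg, n_epochs = ne, keep = keep, vocab = vocab),
            class = "word_counts")
}

#' Symbolize a preprocessed recording
#'
#' Runs the full symbolization chain: per-1-s band power for the eight
#' EEG streams and two EOG power streams, the EOG cross-correlation
#' stream, participant-specific quantile letters (cutoffs over the bins of
#' kept epochs by default), and per-epoch word counts.
#'
#' @param prep A [preprocess_recording()] result.
#' @param bands Band definitions, see [default_bands()].
#' @param cutoff_scope `"kept"` (default) computes quantile cutoffs over
#'   artifact-free bins only; `"all"` uses the whole recording.
#' @return A `word_counts` object (see [word_distribution()]).
#' @export
symbolize_recording <- function(prep, bands = default_bands(),
                                cutoff_scope = c("kept", "all")) {
  cutoff_scope <- match.arg(cutoff_scope)
  rec <- prep$recording
  fs <- as.integer(round(rec$fs))
  ne <- n_epochs(rec)
  span <- rec$lights_off_idx - 1L + seq_len(ne * samples_per_epoch(rec))
  keep <- prep$keep
  bin_keep <- rep(keep, each = 30L)

  eeg_bands <- bands[c("delta", "theta", "alpha", "beta")]
  streams <- list()
  for (ch in c("C3A2", "O1A2")) {
    bp <- band_power_multi(rec$signals[[ch]][span], fs, eeg_bands)
    for (bn in names(eeg_bands)) {
      streams[[paste(ch, bn, sep = ".")]] <- bp[[bn]]
    }
  }
  streams[["EOGL.pow"]] <- band_power_series(rec$signals$EOGL[span], fs, bands$eog_low)
  streams[["EOGR.pow"]] <- band_power_series(rec$signals$EOGR[span], fs, bands$eog_low)
  streams[["EOG.xcorr"]] <- eog_crosscorr_series(rec$signals$EOGL[span],
                                                 rec$signals$EOGR[span], fs)

  st <- stream_table()
  letters <- lapply(st$stream_id, function(sid) {
    v <- streams[[sid]]
    ref <- if (cutoff_scope == "kept") v[bin_keep] else v
    quantile_letters(v, st$alphabet_size[st$stream_id == sid], reference = ref)
  })
  names(letters) <- st$stream_id
  word_distribution(letters, keep)
}

#' Write word counts as sparse triplet text
#'
#' @param wc A `word_counts` object.
#' @param path Output file for the (epoch_index, word_id, count) triplets.
#' @param vocab_path Optional output file for the vocabulary table.
#' @return `path`, invisibly.
#' @export
write_word_counts <- function(wc, path, vocab_path = NULL) {
  write.table(wc$counts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(vocab_path)) {
    write.table(wc$vocab, vocab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
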