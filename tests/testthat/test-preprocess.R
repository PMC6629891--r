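test_that("zero-phase band-pass has the designed frequency response", {
  fs <- 250
  t <- seq(0, 60, by = 1 / fs)
  interior <- 3000:12000  # avoid edge transients when measuring gain

  # DC sits in the stopband
  y <- zero_phase_bandpass(rep(5, fs * 60), fs, eeg_filter_spec())
  expect_lt(abs(mean(y[interior])), 1e-6)

  # 50 Hz through the 0.3-35 Hz spec: two passes of a 4th-order Butterworth
  # at 35 Hz attenuate by well over 24 dB
  s50 <- sin(2 * pi * 50 * t)
  y50 <- zero_phase_bandpass(s50, fs, eeg_filter_spec())
  att_db <- 20 * log10(sd(y50[interior]) / sd(s50[interior]))
  expect_lt(att_db, -24)

  # 10 Hz is mid-passband: amplitude preserved within 5%
  s10 <- sin(2 * pi * 10 * t)
  y10 <- zero_phase_bandpass(s10, fs, eeg_filter_spec())
  expect_lt(abs(sd(y10[interior]) / sd(s10[interior]) - 1), 0.05)

  # filtering is idempotent in the passband: a second pass changes the
  # passband tone RMS by < 1%
  y10b <- zero_phase_bandpass(y10, fs, eeg_filter_spec())
  expect_lt(abs(sd(y10b[interior]) / sd(y10[interior]) - 1), 0.01)

  expect_error(zero_phase_bandpass(c(1, NA, 3, rep(0, 50)), fs),
               "NA or non-finite")
  expect_error(zero_phase_bandpass(s10, fs, filter_spec(0.3, 200)), "Nyquist")
})

test_that("zero-phase filtering introduces no phase shift", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  s <- sin(2 * pi * 10 * t)
  y <- zero_phase_bandpass(s, fs, eeg_filter_spec())
  interior <- 1000:4000
  # zero phase: filtered tone stays aligned with the input
  expect_gt(cor(s[interior], y[interior]), 0.999)
})

test_that("resampling decimates with amplitude preservation", {
  fs_in <- 1000
  t <- seq(0, 20, by = 1 / fs_in)
  x <- sin(2 * pi * 20 * t)
  expect_identical(resample_to(x, 250, 250), x)
  y <- resample_to(x, fs_in, 250)
  expect_equal(length(y), round(length(x) / 4))
  expect_lt(abs(sd(y[500:4500]) / sd(x[2000:18000]) - 1), 0.02)
  expect_equal(resample_to(rep(3.5, 1000), 1000, 250), rep(3.5, 250),
               tolerance = 1e-6)
  expect_error(resample_to(x, 250, 1000), "no upsampling")
})

test_that("epoch statistics are exact on analytic fixtures", {
  fs <- 100; spe <- 30 * fs
  mk <- function(x) {
    psg_recording(list(C3A2 = x, O1A2 = x, EOGL = x, EOGR = x), fs = fs)
  }
  st <- epoch_statistics(mk(rep(2, spe)))
  expect_true(all(st$sd == 0 & st$range == 0 & st$d1_range == 0))

  ramp <- seq_len(spe) * 1.0
  st <- epoch_statistics(mk(ramp))
  expect_equal(unique(st$range), spe - 1)
  expect_equal(unique(st$d1_range), 0)

  sine <- sin(2 * pi * 5 * seq_len(spe) / fs)
  st <- epoch_statistics(mk(sine))
  expect_equal(unique(st$range), 2, tolerance = 1e-3)

  expect_error(epoch_statistics(mk(rep(0, 10))), "no complete epoch")
})

test_that("the 4-MAD rule rejects exactly the contaminated epochs", {
  # 50 identical epochs: all deviations zero, nothing rejected
  st0 <- data.frame(epoch = rep(1:50, 4), channel = rep(c("a", "b", "c", "d"),
                                                        each = 50),
                    sd = 1, range = 4, d1_range = 2)
  expect_true(all(reject_artifacts(st0)))

  # 49 noise epochs plus one scaled 100x: only the scaled epoch goes
  fs <- 100; spe <- 30 * fs
  set.seed(3)
  x <- rnorm(50 * spe)
  x[(29 * spe + 1):(30 * spe)] <- x[(29 * spe + 1):(30 * spe)] * 100
  rec <- psg_recording(list(C3A2 = x, O1A2 = rnorm(50 * spe),
                            EOGL = rnorm(50 * spe), EOGR = rnorm(50 * spe)),
                       fs = fs)
  keep <- reject_artifacts(epoch_statistics(rec))
  expect_identical(which(!keep), 30L)

  # a constant channel leaves the decisions unchanged
  rec2 <- rec
  rec2$signals$EOGR <- rep(0, 50 * spe)
  expect_identical(reject_artifacts(epoch_statistics(rec2))[-30], keep[-30])

  expect_warning(keep4 <- reject_artifacts(st0[st0$epoch <= 4, ]), "fewer than 5")
  expect_true(all(keep4))
})

test_that("rejection is invariant to channel order and uniform rescaling", {
  fs <- 100; spe <- 30 * fs
  set.seed(5)
  sig <- lapply(1:4, function(i) rnorm(20 * spe, sd = sample(1:5, 1)))
  names(sig) <- c("C3A2", "O1A2", "EOGL", "EOGR")
  rec <- psg_recording(sig, fs = fs)
  keep <- reject_artifacts(epoch_statistics(rec))

  rec_scaled <- rec
  rec_scaled$signals <- lapply(rec$signals, function(x) x * 12.5)
  expect_identical(reject_artifacts(epoch_statistics(rec_scaled)), keep)

  rec_perm <- rec
  rec_perm$signals <- rec$signals[c("EOGR", "C3A2", "EOGL", "O1A2")]
  names(rec_perm$signals) <- names(rec$signals)
  st <- epoch_statistics(psg_recording(rec_perm$signals, fs = fs))
  expect_identical(reject_artifacts(st), keep)
})

test_that("keep flags equal a brute-force median/MAD recomputation", {
  fs <- 100; spe <- 30 * fs
  for (seed in 1:3) {
    set.seed(seed)
    sig <- lapply(1:4, function(i) rnorm(15 * spe) * exp(rnorm(1)))
    names(sig) <- c("C3A2", "O1A2", "EOGL", "EOGR")
    st <- epoch_statistics(psg_recording(sig, fs = fs))
    keep <- reject_artifacts(st)
    brute <- rep(TRUE, 15)
    for (stat in c("sd", "range", "d1_range")) {
      v <- sapply(1:15, function(e) mean(st[[stat]][st$epoch == e]))
      thr <- median(v) + 4 * max(median(abs(v - median(v))), 1e-12)
      brute <- brute & (v <= thr)
    }
    expect_identical(keep, brute)
  }
})

test_that("preprocess_recording trims edges and reports quality", {
  hyp <- simulate_hypnogram(12, seed = 3)
  rec <- synthesize_recording(hyp, fs = 100, seed = 4)
  prep <- preprocess_recording(rec, fs_out = 100, trim_epochs = 2)
  expect_length(prep$keep, 12L)
  expect_false(any(prep$keep[c(1, 2, 11, 12)]))
  expect_s3_class(prep, "psg_preprocessed")
  # resampling path: generate at 200 Hz, analyze at 100 Hz
  rec2 <- synthesize_recording(hyp, fs = 200, seed = 4)
  prep2 <- preprocess_recording(rec2, fs_out = 100)
  expect_equal(prep2$recording$fs, 100)
  expect_length(prep2$keep, 12L)
})
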