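# Synthetic polysomnography: stage-dependent band-limited noise on two EEG
# derivations, low-frequency noise plus paired eye-movement deflections on
# two EOG derivations, hypnogram dynamics from a Markov chain, and an
# injectable "light-sleep-inside-deep-sleep" intrusion that blends the
# variance profiles of two stages.

#' Stage-dependent spectral profile
#'
#' Per-stage standard deviations of the band-limited noise components that
#' make up a synthetic recording, plus the EOG eye-movement burst model.
#'
#' @param stage One of `r paste(sleep_stages(), collapse = ", ")`.
#' @param band_sd 2 x 4 numeric matrix of noise SDs (microvolt), rows
#'   `C3A2`/`O1A2`, columns `delta`/`theta`/`alpha`/`beta`.
#' @param eog_sd Low-frequency EOG noise SD (microvolt).
#' @param eog_burst_rate Expected eye-movement deflections per 30-s epoch.
#' @param eog_burst_sign Sign of the paired deflection on EOGR relative to
#'   EOGL (-1 gives negatively correlated eye movements).
#' @param eog_burst_dur_s Deflection duration in seconds (slow rolling eye
#'   movements ~1.5 s, rapid REM saccades ~0.35 s).
#' @return An object of class `stage_profile`.
#' @export
stage_profile <- function(stage, band_sd, eog_sd, eog_burst_rate = 0,
                          eog_burst_sign = -1, eog_burst_dur_s = 1.0) {
  stage <- match.arg(stage, sleep_stages())
  band_sd <- as.matrix(band_sd)
  if (!all(dim(band_sd) == c(2L, 4L))) stop_param("`band_sd` must be 2 x 4")
  dimnames(band_sd) <- list(c("C3A2", "O1A2"), c("delta", "theta", "alpha", "beta"))
  if (any(band_sd < 0) || eog_sd < 0 || eog_burst_rate < 0) {
    stop_param("SDs and burst rate must be non-negative")
  }
  structure(list(stage = stage, band_sd = band_sd, eog_sd = eog_sd,
                 eog_burst_rate = eog_burst_rate,
                 eog_burst_sign = sign(eog_burst_sign),
                 eog_burst_dur_s = eog_burst_dur_s),
            class = "stage_profile")
}

#' Default stage profiles
#'
#' Spectral calibration follows the qualitative per-stage semantics of the
#' vigilance-state literature: deep sleep has high, consistent delta/theta
#' power and EEG delta spill into the EOG leads; light sleep (N1) has low
#' delta/theta, intermediate alpha and intermediate-to-high beta with slow
#' eye movements; REM has globally low power with frequent rapid eye
#' movements; wakefulness has high alpha (occipital-dominant) and beta with
#' eye movements. Values are noise SDs in microvolt.
#'
#' @return Named list of five [stage_profile()] objects.
#' @export
default_stage_profiles <- function() {
  p <- function(...) matrix(c(...), nrow = 2, byrow = TRUE)
  list(
    W   = stage_profile("W",   p(5, 8, 13, 10,   5, 7, 15, 10), eog_sd = 12,
                        eog_burst_rate = 3, eog_burst_dur_s = 0.6),
    N1  = stage_profile("N1",  p(7, 13, 8, 8,    7, 12, 8, 8),  eog_sd = 10,
                        eog_burst_rate = 2, eog_burst_dur_s = 1.5),
    N2  = stage_profile("N2",  p(13, 9, 9, 5,    12, 8, 9, 5),  eog_sd = 9,
                        eog_burst_rate = 0.2, eog_burst_dur_s = 1.0),
    N3  = stage_profile("N3",  p(17, 9, 4, 3,    15, 8, 4, 3),  eog_sd = 13,
                        eog_burst_dur_s = 1.2),
    REM = stage_profile("REM", p(8, 8, 6, 6,     7, 7, 6, 6),   eog_sd = 8,
                        eog_burst_rate = 5, eog_burst_dur_s = 0.35)
  )
}

#' Concomitance (stage-intrusion) specification
#'
#' Selected epochs of `base_stage` are contaminated with the
#' `intruder_stage`: a fraction `w` of the epoch's 1-s bins (Bernoulli per
#' bin) carries the intruder's EEG variance profile outright, so the
#' epoch-wise expected variance is the blend
#' `(1 - w) * var_base + w * var_intruder` per band while the epoch's word
#' distribution is a genuine mixture of the two states' word types --
#' concomitance in the sequential-within-the-epoch sense that a
#' bag-of-words mixture model can detect. (A spectrally uniform blend
#' would instead resemble the nearest single state.) The EOG noise
#' variance, burst rate and burst duration are blended at the epoch level.
#'
#' @param base_stage Stage whose epochs are contaminated (default N3).
#' @param intruder_stage Stage whose profile intrudes (default N1).
#' @param weight Mean intrusion fraction `w` in `[0, 1]`.
#' @param placement Fraction of eligible epochs affected, in `[0, 1]`.
#' @param heterogeneity Beta concentration of the per-epoch intrusion
#'   fraction around `weight` (intrusions are intermittent: most affected
#'   epochs are lightly touched, occasional ones nearly completely).
#'   `Inf` applies the same fraction to every affected epoch.
#' @return An object of class `concomitance_spec`.
#' @export
concomitance_spec <- function(base_stage = "N3", intruder_stage = "N1",
                              weight = 0, placement = 1,
                              heterogeneity = 3) {
  base_stage <- match.arg(base_stage, sleep_stages())
  intruder_stage <- match.arg(intruder_stage, sleep_stages())
  if (!is.numeric(weight) || weight < 0 || weight > 1) {
    stop_param("`weight` must lie in [0, 1]")
  }
  if (!is.numeric(placement) || placement < 0 || placement > 1) {
    stop_param("`placement` must lie in [0, 1]")
  }
  if (!is.numeric(heterogeneity) || heterogeneity <= 0) {
    stop_param("`heterogeneity` must be positive (or Inf)")
  }
  structure(list(base_stage = base_stage, intruder_stage = intruder_stage,
                 weight = weight, placement = placement,
                 heterogeneity = heterogeneity),
            class = "concomitance_spec")
}

#' Default stage transition matrix and initial distribution
#'
#' A 5 x 5 row-stochastic matrix over (W, N1, N2, N3, REM) at the 30-s epoch
#' scale, tuned to give realistic overnight stage fractions (roughly 10% W,
#' 5% N1, 45% N2, 20% N3, 20% REM) with consolidated deep-sleep and REM
#' runs.
#'
#' @return `default_transition_matrix()`: the matrix;
#'   `default_initial_dist()`: the start-of-night stage distribution.
#' @export
default_transition_matrix <- function() {
  m <- rbind(
    W   = c(0.880, 0.080, 0.030, 0.000, 0.010),
    N1  = c(0.060, 0.600, 0.300, 0.000, 0.040),
    N2  = c(0.015, 0.030, 0.870, 0.055, 0.030),
    N3  = c(0.005, 0.005, 0.090, 0.880, 0.020),
    REM = c(0.020, 0.040, 0.050, 0.000, 0.890)
  )
  colnames(m) <- sleep_stages()
  m
}

#' @rdname default_transition_matrix
#' @export
default_initial_dist <- function() {
  setNames(c(0.70, 0.20, 0.10, 0, 0), sleep_stages())
}

#' Simulate a hypnogram from a stage Markov chain
#'
#' @param n_epochs Number of 30-s epochs (>= 1).
#' @param transition_matrix 5 x 5 row-stochastic matrix over
#'   (W, N1, N2, N3, REM).
#' @param initial_dist Probability vector over the five stages for the
#'   first epoch.
#' @param seed Integer seed; the same seed yields the identical sequence.
#' @return Character vector of `n_epochs` stage labels.
#' @export
simulate_hypnogram <- function(n_epochs,
                               transition_matrix = default_transition_matrix(),
                               initial_dist = default_initial_dist(),
                               seed = 1L) {
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 1L) stop_param("`n_epochs` must be >= 1")
  tm <- as.matrix(transition_matrix)
  if (!all(dim(tm) == c(5L, 5L))) stop_param("`transition_matrix` must be 5 x 5")
  if (any(tm < 0)) stop_param("`transition_matrix` has negative entries")
  if (any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop_param("rows of `transition_matrix` must sum to 1")
  }
  if (any(initial_dist < 0) || abs(sum(initial_dist) - 1) > 1e-9) {
    stop_param("`initial_dist` must be a probability vector")
  }
  stages <- sleep_stages()
  with_seed(seed, {
    out <- integer(n_epochs)
    out[1L] <- sample.int(5L, 1L, prob = initial_dist)
    if (n_epochs > 1L) {
      for (i in 2L:n_epochs) {
        out[i] <- sample.int(5L, 1L, prob = tm[out[i - 1L], ])
      }
    }
    stages[out]
  })
}

# Two-pass Butterworth squared-magnitude gain at frequencies f (Hz), i.e.
# the power gain of zero-phase (forward-reverse) filtering.
butter_twopass_power_gain <- function(f, fs, low, high, order = 4L) {
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  Mod(filter_freq_response(bf$b, bf$a, f, fs))^4
}

# Spectral synthesis envelope: for an epoch of length n at rate fs, the
# per-FFT-bin squared gain of each generator band, normalized so that unit
# white noise shaped by sqrt(gain) has unit variance.
generator_band_gains <- function(n, fs, bands = generator_bands()) {
  f <- (seq_len(n) - 1L) * fs / n
  f <- pmin(f, fs - f)
  out <- lapply(bands, function(bd) {
    g <- butter_twopass_power_gain(f, fs, bd[1L], bd[2L])
    g / mean(g)
  })
  out
}

# The band edges used by the noise generator (Hz); the EOG component uses
# the low-frequency band that the analysis side also evaluates.
generator_bands <- function() {
  list(delta = c(0.5, 4), theta = c(4, 8), alpha = c(8, 13), beta = c(13, 35),
       eog = c(0.3, 5))
}

# Per-epoch band variances (4 x n_epochs) for one EEG channel given the
# hypnogram, the profiles, and the per-epoch intrusion weights.
blend_band_var <- function(hypnogram, profiles, channel, w_epoch, intruder_stage,
                           depth = NULL) {
  sd_by_stage <- vapply(profiles, function(p) p$band_sd[channel, ],
                        numeric(4))  # 4 x 5, columns named by stage
  v <- sd_by_stage[, hypnogram, drop = FALSE]^2
  if (!is.null(depth)) v["delta", ] <- v["delta", ] * depth
  idx <- which(w_epoch > 0)
  if (length(idx)) {
    vi <- profiles[[intruder_stage]]$band_sd[channel, ]^2
    v[, idx] <- sweep(v[, idx, drop = FALSE], 2L, 1 - w_epoch[idx], "*") +
      outer(vi, w_epoch[idx])
  }
  v
}

#' Synthesize a four-channel recording from a hypnogram
#'
#' Every epoch of each EEG channel is a sum of four independent band-limited
#' Gaussian noise components whose SDs come from the epoch's stage profile;
#' band-limiting uses the squared-magnitude (zero-phase two-pass) response
#' of the same 4th-order Butterworth designs used in preprocessing, applied
#' spectrally. Within N3 runs a slowly varying two-state depth factor
#' scales the delta variance, emulating waxing and waning slow-wave
#' activity. EOG channels carry low-frequency noise plus paired
#' eye-movement deflections with opposite polarity on the two leads. In
#' epochs selected by the concomitance spec, a per-epoch fraction of 1-s
#' bins carries the intruder stage's profile (see [concomitance_spec()]).
#'
#' @param hypnogram Character vector of stage labels (one per 30-s epoch).
#' @param profiles Named list of five [stage_profile()] objects.
#' @param concomitance A [concomitance_spec()] or `NULL` (no intrusion;
#'   identical to `weight = 0`).
#' @param fs Sampling rate in Hz (>= 100).
#' @param epoch_jitter_sd Log-scale SD of the multiplicative per-epoch,
#'   per-band variance fluctuation emulating the natural epoch-to-epoch
#'   variability of band power within a stage (0 disables it).
#' @param n3_depth_factors Length-2 vector `c(deep, light)` of multipliers
#'   applied to the N3 delta variance (and the EOG delta spill):
#'   slow-wave activity waxes and wanes, so deep sleep itself alternates
#'   between deeper and lighter N3. Set both to 1 to disable.
#' @param n3_depth_stay Probability that consecutive N3 epochs keep the
#'   same depth state (depth varies slowly within an N3 run).
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A [psg_recording()].
#' @export
synthesize_recording <- function(hypnogram,
                                 profiles = default_stage_profiles(),
                                 concomitance = NULL,
                                 fs = 250,
                                 epoch_jitter_sd = 0.3,
                                 n3_depth_factors = c(deep = 1.5, light = 0.6),
                                 n3_depth_stay = 0.9,
                                 seed = 1L) {
  if (fs < 100) stop_param("`fs` must be >= 100 Hz")
  if (!length(hypnogram)) stop_param("`hypnogram` is empty")
  if (!all(hypnogram %in% sleep_stages())) {
    stop("unknown stage label in hypnogram: ",
         paste(setdiff(unique(hypnogram), sleep_stages()), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(concomitance)) concomitance <- concomitance_spec(weight = 0)
  ne <- length(hypnogram)
  spe <- as.integer(round(30 * fs))
  gains <- generator_band_gains(spe, fs)

  with_seed(seed, {
    eligible <- which(hypnogram == concomitance$base_stage)
    affected <- if (concomitance$placement >= 1) eligible else {
      sort(sample(eligible, round(concomitance$placement * length(eligible))))
    }
    # intermittent intrusion: per-epoch weights drawn around the mean
    # weight (quantile transform keeps them monotone in `weight` under
    # common random numbers), then realized as a per-1-s-bin mask -- a
    # fraction w of the epoch's seconds carry the intruder state outright,
    # so the epoch's word distribution is a genuine mixture of the two
    # states' word types
    w_epoch <- numeric(ne)
    bin_mask <- NULL
    if (length(affected) && concomitance$weight > 0) {
      w <- concomitance$weight
      h <- concomitance$heterogeneity
      w_epoch[affected] <- if (!is.finite(h) || w >= 1) w else {
        stats::qbeta(runif(length(affected)), w * h, (1 - w) * h)
      }
      bin_mask <- matrix(FALSE, 30L, length(affected))
      for (j in seq_along(affected)) {
        bin_mask[, j] <- runif(30L) < w_epoch[affected[j]]
      }
    }

    # slowly varying slow-wave depth within N3 runs: a two-state Markov
    # chain scaling the delta variance (and EOG spill)
    depth <- rep(1, ne)
    is_n3 <- hypnogram == "N3"
    state <- 1L
    for (i in seq_len(ne)) {
      if (is_n3[i]) {
        if (i == 1L || !is_n3[i - 1L]) {
          state <- sample(1:2, 1L)
        } else if (runif(1L) > n3_depth_stay) {
          state <- 3L - state
        }
        depth[i] <- n3_depth_factors[state]
      }
    }

    # per-epoch, per-band variance fluctuation, shared by the two EEG
    # channels (row 5 drives the EOG noise)
    jitter <- matrix(exp(rnorm(5L * ne, 0, epoch_jitter_sd)), 5L, ne)

    # Gaussian noise with per-epoch spectral envelope, synthesized as a
    # Hermitian white spectrum shaped by sqrt of the envelope: half the FFT
    # work of a filter-the-noise implementation, identical distribution.
    half <- spe %/% 2L
    synth_channel <- function(var_per_epoch, band_names) {
      # var_per_epoch: length(band_names) x n_cols matrix of variances
      nc <- ncol(var_per_epoch)
      G <- do.call(cbind, gains[band_names])
      amp <- sqrt(G %*% var_per_epoch)  # spe x nc
      re <- rnorm(half * nc); dim(re) <- c(half, nc)  # bins 1..half
      im <- rnorm(half * nc); dim(im) <- c(half, nc)
      dc <- rnorm(nc)
      z <- hermitian_spectrum_cpp(re, im, dc, amp)
      Re(mvfft(z, inverse = TRUE)) / spe
    }

    eeg_bands <- c("delta", "theta", "alpha", "beta")
    sample_mask <- if (!is.null(bin_mask)) {
      m <- bin_mask[rep(seq_len(30L), each = fs), , drop = FALSE]
      which(m)  # linear indices into the (spe x n_affected) submatrix
    }
    eeg <- lapply(c(C3A2 = "C3A2", O1A2 = "O1A2"), function(ch) {
      v <- blend_band_var(hypnogram, profiles, ch, numeric(ne),
                          concomitance$intruder_stage, depth)
      v <- v * jitter[1:4, , drop = FALSE]
      x <- synth_channel(v, eeg_bands)
      if (!is.null(bin_mask)) {
        vi <- profiles[[concomitance$intruder_stage]]$band_sd[ch, ]^2
        v_int <- vi * jitter[1:4, affected, drop = FALSE]
        y <- synth_channel(v_int, eeg_bands)
        xa <- x[, affected, drop = FALSE]
        xa[sample_mask] <- y[sample_mask]
        x[, affected] <- xa
      }
      as.vector(x)
    })

    eog_sd_by_stage <- vapply(profiles, function(p) p$eog_sd, numeric(1))
    eog_var <- eog_sd_by_stage[hypnogram]^2 * depth  # EOG delta spill deepens too
    rate_by_stage <- vapply(profiles, function(p) p$eog_burst_rate, numeric(1))
    rate <- rate_by_stage[hypnogram]
    dur_by_stage <- vapply(profiles, function(p) p$eog_burst_dur_s, numeric(1))
    dur_s <- dur_by_stage[hypnogram]
    if (any(w_epoch > 0)) {
      vi <- profiles[[concomitance$intruder_stage]]$eog_sd^2
      ri <- profiles[[concomitance$intruder_stage]]$eog_burst_rate
      di <- profiles[[concomitance$intruder_stage]]$eog_burst_dur_s
      eog_var <- (1 - w_epoch) * eog_var + w_epoch * vi
      rate <- (1 - w_epoch) * rate + w_epoch * ri
      dur_s <- (1 - w_epoch) * dur_s + w_epoch * di
    }
    eog_var <- eog_var * jitter[5L, ]
    eogL <- as.vector(synth_channel(rbind(eog_var), "eog"))
    eogR <- as.vector(synth_channel(rbind(eog_var), "eog"))

    # Eye-movement bursts: smoothed deflections, opposite sign on the two
    # leads, ~1 s long, absent where the stage profile has zero rate.
    burst_sign <- profiles[[1L]]$eog_burst_sign
    nb <- rpois(ne, rate)
    for (ep in which(nb > 0L)) {
      dur <- max(2L, as.integer(round(dur_s[ep] * fs)))
      bump_shape <- 0.5 - 0.5 * cos(2 * pi * seq_len(dur) / (dur + 1))
      for (b in seq_len(nb[ep])) {
        onset <- (ep - 1L) * spe + sample.int(spe - dur, 1L)
        amp <- runif(1L, 30, 70) * sample(c(-1, 1), 1L)
        idx <- onset + seq_len(dur)
        eogL[idx] <- eogL[idx] + amp * bump_shape
        eogR[idx] <- eogR[idx] + burst_sign * amp * bump_shape
      }
    }

    psg_recording(list(C3A2 = eeg$C3A2, O1A2 = eeg$O1A2,
                       EOGL = eogL, EOGR = eogR), fs = fs)
  })
}

# Analytic mean 1-s band power of a synthetic channel for a given stage
# profile. The generator draws each 30-s epoch as circularly stationary
# Gaussian noise with per-bin variance A^2(f); the expected 1-s rectangular
# window periodogram then follows from the process autocovariance with the
# triangular (Bartlett) lag window. Used as the oracle for generator
# calibration checks.
analytic_band_power <- function(profile, channel, fs, band,
                                epoch_jitter_sd = 0.3, epoch_len_s = 30) {
  spe <- as.integer(round(epoch_len_s * fs))
  gains <- generator_band_gains(spe, fs)
  sds <- profile$band_sd[channel, ]
  A2 <- numeric(spe)
  for (bn in c("delta", "theta", "alpha", "beta")) {
    A2 <- A2 + sds[bn]^2 * gains[[bn]]
  }
  r <- Re(fft(A2)) / spe            # circular autocovariance, lag 0..spe-1
  N <- as.integer(fs)               # 1-s analysis window
  taus <- 0:(N - 1L)
  wts <- ifelse(taus == 0L, N, 2 * (N - taus))
  f <- 0:(N - 1L)
  fmir <- pmin(f, N - f) * fs / N
  sel <- f[fmir >= band[1L] & fmir < band[2L] & f != 0L]
  expow <- vapply(sel, function(k) {
    sum(wts * r[taus + 1L] * cos(2 * pi * k * taus / N))
  }, numeric(1))
  # lognormal variance jitter inflates the mean by exp(sd^2 / 2)
  sum(expow) / N^2 * exp(epoch_jitter_sd^2 / 2)
}
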