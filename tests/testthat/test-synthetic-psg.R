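test_that("hypnogram simulation follows the chain and the seed", {
  # absorbing chain: identity transitions keep the initial stage forever
  hyp <- simulate_hypnogram(25, diag(5), c(0, 0, 1, 0, 0), seed = 3)
  expect_true(all(hyp == "N2"))

  # single epoch drawn from the initial distribution
  expect_identical(simulate_hypnogram(1, diag(5), c(0, 0, 0, 0, 1), seed = 1),
                   "REM")

  # same seed, same sequence; different seed differs somewhere
  h1 <- simulate_hypnogram(200, seed = 9)
  h2 <- simulate_hypnogram(200, seed = 9)
  h3 <- simulate_hypnogram(200, seed = 10)
  expect_identical(h1, h2)
  expect_false(identical(h1, h3))

  # law of large numbers: uniform chain visits each stage ~20%
  u <- matrix(1 / 5, 5, 5)
  hyp <- simulate_hypnogram(50000, u, rep(1 / 5, 5), seed = 7)
  frac <- table(factor(hyp, sleep_stages())) / 50000
  expect_true(all(abs(frac - 0.2) < 0.01))
})

test_that("hypnogram simulation rejects malformed chains", {
  bad <- diag(5); bad[1, 1] <- 0.5
  expect_error(simulate_hypnogram(10, bad), "sum to 1")
  neg <- matrix(1 / 5, 5, 5); neg[2, 1] <- -0.2; neg[2, 2] <- 0.6
  expect_error(simulate_hypnogram(10, neg), "negative")
  expect_error(simulate_hypnogram(0), ">= 1")
})

test_that("synthesized recordings honor the stage variance allocation", {
  profiles <- default_stage_profiles()
  rec <- synthesize_recording(rep("N3", 40), profiles, fs = 250, seed = 21,
                              n3_depth_factors = c(1, 1))
  # delta power dwarfs beta power in essentially every deep-sleep epoch
  d <- band_power_series(rec$signals$C3A2, 250, c(0.5, 4))
  b <- band_power_series(rec$signals$C3A2, 250, c(13, 35))
  expect_gte(mean(d > b), 0.99)

  # measured mean band power tracks the analytic variance allocation
  for (band in list(c(0.5, 4), c(4, 8), c(8, 13), c(13, 35))) {
    target <- sleeptopics:::analytic_band_power(profiles$N3, "C3A2", 250, band)
    expect_lt(abs(mean(band_power_series(rec$signals$C3A2, 250, band)) - target) /
                target, 0.10)
  }
  wrec <- synthesize_recording(rep("W", 40), profiles, fs = 250, seed = 22)
  for (band in list(c(0.5, 4), c(8, 13))) {
    target <- sleeptopics:::analytic_band_power(profiles$W, "O1A2", 250, band)
    expect_lt(abs(mean(band_power_series(wrec$signals$O1A2, 250, band)) - target) /
                target, 0.10)
  }
})

test_that("degenerate profiles give identically zero signals", {
  silent <- lapply(default_stage_profiles(), function(p) {
    p$band_sd[] <- 0; p$eog_sd <- 0; p$eog_burst_rate <- 0; p
  })
  rec <- synthesize_recording(rep("N2", 3), silent, fs = 100, seed = 1)
  expect_true(all(vapply(rec$signals, function(x) all(x == 0), logical(1))))
})

test_that("the generator is deterministic and weight 0 is a no-op", {
  hyp <- simulate_hypnogram(12, seed = 5)
  r1 <- synthesize_recording(hyp, fs = 100, seed = 8)
  r2 <- synthesize_recording(hyp, fs = 100, seed = 8)
  expect_identical(r1, r2)
  r3 <- synthesize_recording(hyp, fs = 100, seed = 8,
                             concomitance = concomitance_spec(weight = 0))
  expect_identical(r1, r3)
  expect_error(synthesize_recording(c("N2", "XX"), fs = 100, seed = 1),
               "unknown stage")
  expect_error(synthesize_recording(hyp, fs = 50, seed = 1), ">= 100")
})

test_that("the intrusion blends variance toward the intruder profile", {
  hyp <- rep("N3", 60)
  conc <- concomitance_spec(weight = 0.5, placement = 1, heterogeneity = Inf)
  rec0 <- synthesize_recording(hyp, fs = 100, seed = 31)
  rec1 <- synthesize_recording(hyp, fs = 100, seed = 31, concomitance = conc)
  d0 <- mean(band_power_series(rec0$signals$C3A2, 100, c(0.5, 4)))
  d1 <- mean(band_power_series(rec1$signals$C3A2, 100, c(0.5, 4)))
  b0 <- mean(band_power_series(rec0$signals$C3A2, 100, c(13, 35)))
  b1 <- mean(band_power_series(rec1$signals$C3A2, 100, c(13, 35)))
  expect_lt(d1, d0)  # delta pulled down toward the light-sleep profile
  expect_gt(b1, b0)  # beta pulled up
})

test_that("cohorts are reproducible with consistent metadata", {
  spec <- cohort_spec(n_control = 3, n_id = 2, n_epochs = 40, fs = 100)
  c1 <- make_cohort(spec, seed = 4, signals = FALSE)
  c2 <- make_cohort(spec, seed = 4, signals = FALSE)
  expect_identical(c1, c2)
  expect_length(c1$participants, 5L)
  tab <- cohort_table(c1)
  expect_identical(tab$group, rep(c("control", "ID"), c(3, 2)))
  expect_equal(tab$isi_total,
               rowSums(tab[paste0("isi_", 1:7)]), ignore_attr = TRUE)
  expect_true(all(vapply(c1$participants, function(p) length(p$hypnogram),
                         integer(1)) == 40L))
  # realized recordings match the signals = TRUE path
  c3 <- make_cohort(spec, seed = 4, signals = TRUE)
  expect_identical(realize_recording(c1$participants[[2]], spec),
                   c3$participants[[2]]$recording)
})

test_that("ID draws systematically stronger intrusion weights", {
  spec <- cohort_spec(n_control = 30, n_id = 30, n_epochs = 1, fs = 100)
  for (seed in 1:20) {
    coh <- make_cohort(spec, seed = seed, signals = FALSE)
    tab <- cohort_table(coh)
    expect_gt(mean(tab$true_concomitance[tab$group == "ID"]),
              mean(tab$true_concomitance[tab$group == "control"]))
  }
})

test_that("ISI totals correlate with the intrusion weight within groups", {
  spec <- cohort_spec(n_control = 200, n_id = 200, n_epochs = 1, fs = 100)
  tab <- cohort_table(make_cohort(spec, seed = 11, signals = FALSE))
  for (g in c("control", "ID")) {
    sub <- tab[tab$group == g, ]
    expect_gt(cor(sub$true_concomitance, sub$isi_total), 0.2)
  }
})

test_that("recording and hypnogram text round-trips preserve the data", {
  hyp <- simulate_hypnogram(6, seed = 2)
  rec <- synthesize_recording(hyp, fs = 100, seed = 3)
  tmp <- tempfile(fileext = ".tsv")
  write_recording_txt(rec, tmp)
  back <- read_recording_txt(tmp)
  expect_equal(back$fs, rec$fs)
  expect_equal(back$signals$C3A2, rec$signals$C3A2, tolerance = 1e-5)
  tmp2 <- tempfile(fileext = ".tsv")
  write_hypnogram_txt(hyp, tmp2)
  expect_identical(read_hypnogram_txt(tmp2), hyp)
  unlink(c(tmp, tmp2))
})
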