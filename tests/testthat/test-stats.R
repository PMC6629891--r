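test_that("the rank-sum test matches hand enumeration and symmetry", {
  # identical samples: perfectly symmetric, z = 0 and p = 1
  gc <- wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(gc$z, 0)
  expect_equal(gc$p, 1)

  # x = (1,2), y = (3,4): W = 3; exact two-sided p = 2/6
  gc <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_equal(gc$W, 3)
  expect_equal(gc$p, 1 / 3)
  expect_identical(gc$method, "exact")

  # strong location shift is detected
  set.seed(700)
  x <- rnorm(50); y <- rnorm(50) + 3
  expect_lt(wilcoxon_ranksum(x, y)$p, 0.001)
  expect_error(wilcoxon_ranksum(numeric(0), 1:3), "empty")
})

test_that("exact enumeration covers all small sample splits", {
  # every (n, m) with n + m <= 10, random integer data with ties
  set.seed(701)
  for (rep in 1:200) {
    n <- sample(1:9, 1); m <- sample(seq_len(10 - n), 1)
    x <- sample(1:6, n, replace = TRUE)
    y <- sample(1:6, m, replace = TRUE)
    gc <- wilcoxon_ranksum(x, y)
    # independent enumeration
    r <- rank(c(x, y)); mu <- n * (n + m + 1) / 2
    sets <- utils::combn(n + m, n)
    sums <- colSums(matrix(r[sets], nrow = n))
    p_ref <- mean(abs(sums - mu) >= abs(sum(r[seq_len(n)]) - mu) - 1e-12)
    expect_equal(gc$p, p_ref)
    expect_equal(gc$W, sum(r[seq_len(n)]))
  }
})

test_that("the normal approximation agrees with the base implementation", {
  set.seed(702)
  x <- rnorm(30); y <- rnorm(25) + 0.5
  gc <- wilcoxon_ranksum(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  # base reports the Mann-Whitney U; convert our rank sum
  expect_equal(gc$W - length(x) * (length(x) + 1) / 2,
               unname(ref$statistic))
  expect_equal(gc$p, ref$p.value, tolerance = 1e-10)
})

test_that("mixed models recover noise-free fixed effects exactly", {
  set.seed(55)
  d <- expand.grid(participant_id = sprintf("P%02d", 1:12), rep = 1:5)
  d$group <- ifelse(as.integer(factor(d$participant_id)) <= 6, "control", "ID")
  d$age <- rep(runif(12, 30, 60), times = 5)
  d$sex <- rep(sample(c("M", "F"), 12, TRUE), times = 5)
  d$y <- 2 + 1 * (d$group == "ID")
  fit <- fit_mixed_model(d, "y")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "group_id"], 1, tolerance = 1e-6)
  expect_equal(cf$estimate[cf$term == "(Intercept)"], 2, tolerance = 1e-6)
  expect_identical(fit$n_participants, 12L)
  expect_identical(unique(cf$df), nrow(d) - nrow(cf))
  expect_error(fit_mixed_model(d[d$participant_id == "P01", ], "y"),
               "two participants")
})

test_that("with no between-participant variance the fit matches OLS", {
  # seed chosen so the ML random-intercept variance hits the boundary (0):
  # the property under test concerns exactly that regime
  set.seed(1)
  n <- 40
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:20), each = 2))
  d$group <- rep(c("control", "ID"), each = n / 2)
  d$age <- runif(n, 30, 60)
  d$sex <- sample(c("M", "F"), n, TRUE)
  d$y <- 0.3 * (d$group == "ID") + 0.01 * d$age + rnorm(n, sd = 0.3)
  fit <- fit_mixed_model(d, "y")
  expect_lt(fit$ranef_var, 1e-10)
  ols <- lm(y ~ I(group == "ID") + I(age - mean(age)) + I(sex == "F"), data = d)
  expect_equal(unname(fit$coefficients$estimate),
               unname(coef(ols)), tolerance = 1e-6)
})

test_that("rank-deficient designs raise an informative error", {
  d <- data.frame(participant_id = rep(c("a", "b", "c"), each = 4),
                  group = "control", age = 50, sex = "F",
                  y = rnorm(12))
  d$x1 <- rep(c(1, 2, 3), each = 4)
  d$x2 <- 2 * d$x1
  expect_error(fit_mixed_model(d, "y", fixed = c("x1", "x2")), "rank-deficient")
})

test_that("partial correlation reduces to Pearson and respects residuals", {
  set.seed(704)
  x <- rnorm(100); y <- 0.5 * x + rnorm(100)
  pc <- partial_correlation(x, y)
  expect_equal(pc$r, cor(x, y), tolerance = 1e-12)
  z <- rnorm(100)
  pc2 <- suppressWarnings(partial_correlation(x, z, covariates = data.frame(z = z)))
  expect_true(isTRUE(pc2$degenerate))
  expect_lt(abs(pc2$r), 1e-10)
  expect_warning(partial_correlation(x, 2 * x, covariates = data.frame(x = x)),
                 "constant residuals")
})

test_that("partial correlation estimates the generating value", {
  # trivariate normal: x and y share a confounder c plus direct coupling;
  # the partial correlation given c has a closed form from the covariance
  set.seed(705)
  n <- 10000
  cv <- rnorm(n)
  ex <- rnorm(n); ey <- rnorm(n)
  x <- cv + ex
  y <- cv + (ex + sqrt(3) * ey) / 2
  # residual covariance: cov(ex, (ex + sqrt(3) ey)/2) = 1/2, sds 1 and 1
  # -> partial r = 0.5
  pc <- partial_correlation(x, y, covariates = data.frame(c = cv))
  expect_lt(abs(pc$r - 0.5), 0.03)
  expect_lt(pc$p, 1e-10)
})

test_that("ISI item regressions identify the driving item", {
  set.seed(706)
  n_p <- 20
  d <- data.frame(participant_id = rep(sprintf("P%02d", 1:n_p), each = 6))
  items <- matrix(sample(0:4, n_p * 7, TRUE), n_p, 7)
  colnames(items) <- paste0("isi_", 1:7)
  d <- cbind(d, items[rep(1:n_p, each = 6), ])
  d$age <- rep(runif(n_p, 30, 60), each = 6)
  d$sex <- rep(sample(c("M", "F"), n_p, TRUE), each = 6)
  d$y <- 0.5 * d$isi_2
  fit <- isi_item_regression(d, "y")
  cf <- fit$coefficients
  expect_equal(cf$estimate[cf$term == "isi_2"], 0.5, tolerance = 1e-6)
  others <- cf$estimate[grepl("^isi_", cf$term) & cf$term != "isi_2"]
  expect_true(all(abs(others) < 1e-6))
  # collinear items error out naming the offender
  d2 <- d; d2$isi_7 <- d2$isi_1
  expect_error(isi_item_regression(d2, "y"), "rank-deficient")
})

test_that("stage band power averages kept epochs within stages", {
  profiles <- default_stage_profiles()
  hyp <- rep("N3", 30)
  rec <- synthesize_recording(hyp, profiles, fs = 100, seed = 41,
                              n3_depth_factors = c(1, 1))
  prep_keep <- rep(TRUE, 30)
  sbp <- stage_band_power(rec, hyp, prep_keep)
  d <- sbp$power[sbp$stage == "N3" & sbp$channel == "C3A2" & sbp$band == "delta"]
  target <- sleeptopics:::analytic_band_power(profiles$N3, "C3A2", 100, c(0.5, 4))
  expect_lt(abs(d - target) / target, 0.10)
  # stages absent from the night are missing, not zero
  expect_true(all(is.na(sbp$power[sbp$stage == "REM"])))
  expect_identical(sbp$n_epochs[sbp$stage == "REM"][1], 0L)
  # quadratic amplitude scaling
  rec2 <- rec
  rec2$signals <- lapply(rec$signals, function(x) 2 * x)
  sbp2 <- stage_band_power(rec2, hyp, prep_keep)
  expect_equal(sbp2$power[sbp$stage == "N3"], 4 * sbp$power[sbp$stage == "N3"],
               tolerance = 1e-9)
  expect_error(stage_band_power(rec, hyp[-1]), "aligned")
})
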