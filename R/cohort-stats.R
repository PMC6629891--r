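# Cohort-level statistics: Wilcoxon rank-sum with tie-corrected normal
# approximation (exact enumeration for small samples), mixed-effects
# models for epoch-level dominance/co-occurrence, partial correlations,
# ISI-item regressions, and per-stage absolute band power.

#' Wilcoxon rank-sum test
#'
#' `W` is the rank sum of the first sample (mid-ranks for ties). The
#' normal approximation uses tie-corrected variance and a continuity
#' correction; for `n + m <= 10` (configurable) the two-sided p value is
#' computed by exact enumeration over all rank assignments of the observed
#' (possibly tied) ranks.
#'
#' @param x,y Numeric samples (nonempty).
#' @param exact Use exact enumeration; default when `n + m <= 10`.
#' @param continuity Apply the 0.5 continuity correction in the normal
#'   approximation.
#' @return List of class `group_comparison`: `W`, `z`, `p`, `method`, and
#'   per-group `means`/`sds`/`n`.
#' @export
wilcoxon_ranksum <- function(x, y, exact = (length(x) + length(y)) <= 10L,
                             continuity = TRUE) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample", call. = FALSE)
  n <- length(x); m <- length(y); N <- n + m
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n)])
  mu <- n * (N + 1) / 2
  ties <- table(r)
  tiecor <- sum(ties^3 - ties) / ((N) * (N - 1))
  sigma2 <- n * m / 12 * ((N + 1) - tiecor)
  dev <- W - mu
  cc <- if (continuity) 0.5 * sign(dev) else 0
  z <- if (sigma2 > 0) (dev - cc) / sqrt(sigma2) else 0
  if (exact) {
    sets <- utils::combn(N, n)
    sums <- colSums(matrix(r[sets], nrow = n))
    p <- mean(abs(sums - mu) >= abs(dev) - 1e-12)
    method <- "exact"
  } else {
    p <- if (sigma2 > 0) 2 * pnorm(-abs(z)) else 1
    method <- "normal"
  }
  structure(list(W = W, z = z, p = min(1, p), method = method,
                 means = c(x = mean(x), y = mean(y)),
                 sds = c(x = sd(x), y = sd(y)), n = c(x = n, y = m)),
            class = "group_comparison")
}

# Shared mixed-model machinery: outcome ~ fixed effects + (1 | participant),
# maximum likelihood, with t/p from residual degrees of freedom
# (observations - fixed parameters), matching epoch-level denominators.
fit_lmm <- function(records, outcome, fixed_terms) {
  d <- records
  required <- c(outcome, fixed_terms_vars(fixed_terms), "participant_id")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols)) {
    stop_param("missing columns: ", paste(missing_cols, collapse = ", "))
  }
  d <- d[complete.cases(d[required]), , drop = FALSE]
  if (length(unique(d$participant_id)) < 2L) {
    stop("at least two participants are required for a random intercept",
         call. = FALSE)
  }
  if ("age" %in% names(d)) d$age_c <- d$age - mean(d$age)
  if ("sex" %in% names(d)) d$sex_f <- as.integer(d$sex == "F")
  if ("group" %in% names(d)) d$group_id <- as.integer(d$group == "ID")
  term_map <- c(age = "age_c", sex = "sex_f", group = "group_id")
  terms <- ifelse(fixed_terms %in% names(term_map),
                  term_map[fixed_terms], fixed_terms)
  fixed_rhs <- paste(terms, collapse = " + ")
  X <- model.matrix(stats::as.formula(paste("~", fixed_rhs)), d)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient fixed-effect design; offending columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  fml <- stats::as.formula(paste(outcome, "~", fixed_rhs, "+ (1 | participant_id)"))
  fit <- lme4::lmer(fml, data = d, REML = FALSE,
                    control = lme4::lmerControl(check.conv.singular = "ignore",
                                                calc.derivs = FALSE))
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  tval <- beta / se
  n_obs <- nrow(d)
  df <- n_obs - length(beta)
  pval <- 2 * pt(-abs(tval), df)
  vc <- as.data.frame(lme4::VarCorr(fit))
  coefs <- data.frame(term = names(beta), estimate = beta, se = se,
                      t = tval, df = df, p = pval, row.names = NULL)
  structure(list(outcome = outcome, coefficients = coefs,
                 ranef_var = vc$vcov[vc$grp == "participant_id"],
                 resid_var = vc$vcov[vc$grp == "Residual"],
                 n_obs = n_obs,
                 n_participants = length(unique(d$participant_id)),
                 fit = fit),
            class = "mixed_model_fit")
}

fixed_terms_vars <- function(terms) {
  map <- c(age = "age", sex = "sex", group = "group")
  ifelse(terms %in% names(map), map[terms], terms)
}

#' Mixed-effects model for epoch-level outcomes
#'
#' Fits `outcome ~ fixed effects + (1 | participant)` by maximum likelihood
#' to epoch-level records nested in participants, as appropriate when the
#' number of stable epochs differs across participants. Coefficient p
#' values use residual degrees of freedom (observations minus fixed
#' parameters). Sex enters as a female indicator and age is centered.
#'
#' @param records Data frame with one row per (stable) epoch carrying the
#'   outcome and the participant-level covariates (`participant_id` plus
#'   the fixed-effect columns; `group`/`age`/`sex` are encoded
#'   automatically).
#' @param outcome Name of the outcome column (e.g. a dominance or
#'   co-occurrence probability).
#' @param fixed Character vector of fixed-effect terms (default
#'   `c("group", "age", "sex")`; use e.g. `c("isi_total", "age", "sex")`
#'   for severity models).
#' @return An object of class `mixed_model_fit` with a `coefficients`
#'   table, variance components and the underlying `lmer` fit.
#' @export
fit_mixed_model <- function(records, outcome, fixed = c("group", "age", "sex")) {
  fit_lmm(records, outcome, fixed)
}

#' @export
print.mixed_model_fit <- function(x, ...) {
  cat(sprintf("<mixed_model_fit> %s: %d obs in %d participants\n",
              x$outcome, x$n_obs, x$n_participants))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' ISI-item mixed-effects regression
#'
#' Replaces the ISI total with the seven individual item scores as
#' regressors (plus age and sex), to identify which insomnia symptom best
#' explains the outcome. Perfectly collinear items raise an error naming
#' the offending columns.
#'
#' @param records Epoch-level records with columns `isi_1..isi_7`, `age`,
#'   `sex`, `participant_id` and the outcome.
#' @param outcome Name of the outcome column.
#' @return A `mixed_model_fit`.
#' @export
isi_item_regression <- function(records, outcome) {
  items <- paste0("isi_", 1:7)
  fit_lmm(records, outcome, c(items, "age", "sex"))
}

#' Partial correlation
#'
#' Pearson correlation of the least-squares residuals of `x` and `y` on
#' the covariates (with intercept); the p value uses the t transform with
#' `n - k - 2` degrees of freedom. With no covariates this is the plain
#' Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame or matrix of covariates.
#' @return List of class `partial_corr`: `r`, `p`, `df`, `n`. `r` is `NA`
#'   (flagged undefined) when either residual is constant.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- data.frame(row.names = seq_along(x))
    k <- 0L
  } else {
    covariates <- as.data.frame(covariates)
    k <- ncol(covariates)
  }
  if (length(x) != length(y) || (k > 0 && nrow(covariates) != length(x))) {
    stop("inputs differ in length", call. = FALSE)
  }
  ok <- if (k > 0) complete.cases(x, y, covariates) else complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  if (n <= k + 2L) stop_param("need n > number of covariates + 2")
  if (k > 0) {
    num <- as.data.frame(lapply(covariates, function(v) {
      if (is.numeric(v)) v else as.integer(factor(v))
    }))
    X <- cbind(1, as.matrix(num))
    rx <- residuals(stats::lm.fit(X, x))
    ry <- residuals(stats::lm.fit(X, y))
  } else {
    rx <- x - mean(x); ry <- y - mean(y)
  }
  if (sd(rx) < 1e-14 || sd(ry) < 1e-14) {
    # a variable fully explained by the covariates is orthogonal to every
    # residual: report 0, flag that no test is possible
    warning("constant residuals; partial correlation degenerate")
    return(structure(list(r = 0, p = NA_real_, df = n - k - 2L, n = n,
                          degenerate = TRUE),
                     class = "partial_corr"))
  }
  r <- cor(rx, ry)
  df <- n - k - 2L
  tval <- r * sqrt(df / max(1 - r^2, 1e-300))
  structure(list(r = r, p = 2 * pt(-abs(tval), df), df = df, n = n),
            class = "partial_corr")
}

#' Per-stage absolute band power
#'
#' For every 30-s epoch the band power is the mean of its thirty 1-s band
#' power values; epochs are then averaged within each sleep stage over
#' kept epochs. Stages with no kept epochs are `NA`.
#'
#' @param rec A (filtered) [psg_recording()].
#' @param hypnogram Stage labels aligned with the recording's epochs.
#' @param keep Logical keep flags (default: all kept).
#' @param bands Band definitions for the EEG channels.
#' @return Data frame with columns `stage`, `channel`, `band`, `power`
#'   (microvolt^2) and `n_epochs`.
#' @export
stage_band_power <- function(rec, hypnogram, keep = NULL,
                             bands = default_bands()[c("delta", "theta",
                                                       "alpha", "beta")]) {
  ne <- n_epochs(rec)
  if (length(hypnogram) != ne) {
    stop("hypnogram not aligned with the recording's epochs", call. = FALSE)
  }
  if (is.null(keep)) keep <- rep(TRUE, ne)
  fs <- as.integer(round(rec$fs))
  span <- rec$lights_off_idx - 1L + seq_len(ne * samples_per_epoch(rec))
  out <- list()
  for (ch in c("C3A2", "O1A2")) {
    bp <- band_power_multi(rec$signals[[ch]][span], fs, bands)
    for (bn in names(bands)) {
      per_epoch <- colMeans(matrix(bp[[bn]], nrow = 30L))
      for (stg in sleep_stages()) {
        sel <- keep & hypnogram == stg
        out[[length(out) + 1L]] <- data.frame(
          stage = stg, channel = ch, band = bn,
          power = if (any(sel)) mean(per_epoch[sel]) else NA_real_,
          n_epochs = sum(sel), stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}
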