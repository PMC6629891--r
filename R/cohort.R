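# Synthetic cohorts: insomnia-disorder (ID) cases and controls with
# group-specific intrusion-weight distributions, Insomnia Severity Index
# scores correlated with the intrusion weight, and per-participant nights.

#' Cohort simulation specification
#'
#' Defaults mirror a typical case-control polysomnography study: 64
#' controls and 55 ID cases, ~8-h nights of 30-s epochs, control/ID ages of
#' about 45/48 years, and ISI totals near 4 (controls) versus 16 (ID).
#' The concomitance (light-sleep-intrusion) weight `w` is Beta-distributed
#' per group with a higher ID mean, and the ISI total is generated with a
#' configurable positive latent correlation with `w`, so the downstream
#' co-occurrence/ISI association is recoverable by construction.
#'
#' @param n_control,n_id Group sizes (>= 1).
#' @param n_epochs Epochs per night (default 960 = 8 h).
#' @param fs Sampling rate in Hz.
#' @param w_mean_control,w_mean_id Group means of the intrusion weight.
#' @param w_concentration Beta concentration (a + b) of the weight
#'   distributions; larger is tighter.
#' @param placement Fraction of deep-sleep epochs affected by the intrusion.
#' @param w_heterogeneity Beta concentration of the per-epoch intrusion
#'   weight (see [concomitance_spec()]).
#' @param isi_mean_control,isi_sd_control,isi_mean_id,isi_sd_id Group
#'   ISI-total distributions (truncated to 0..28).
#' @param isi_w_cor Latent correlation between the intrusion weight and the
#'   ISI total within each group.
#' @param age_mean_control,age_sd_control,age_mean_id,age_sd_id Group age
#'   distributions (years).
#' @param p_female_control,p_female_id Probability of sex = "F".
#' @param transition_matrix,initial_dist Hypnogram Markov-chain parameters.
#' @param profiles Stage profiles passed to [synthesize_recording()].
#' @param base_stage,intruder_stage Stages blended by the intrusion.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_control = 64L, n_id = 55L,
                        n_epochs = 960L, fs = 250,
                        w_mean_control = 0.05, w_mean_id = 0.45,
                        w_concentration = 20,
                        placement = 0.55,
                        w_heterogeneity = 3,
                        isi_mean_control = 3.8, isi_sd_control = 3.7,
                        isi_mean_id = 16.5, isi_sd_id = 4.3,
                        isi_w_cor = 0.6,
                        age_mean_control = 45.3, age_sd_control = 14.6,
                        age_mean_id = 47.8, age_sd_id = 12.9,
                        p_female_control = 42 / 64, p_female_id = 41 / 55,
                        transition_matrix = default_transition_matrix(),
                        initial_dist = default_initial_dist(),
                        profiles = default_stage_profiles(),
                        base_stage = "N3", intruder_stage = "N1") {
  if (n_control < 1L || n_id < 1L) stop_param("group sizes must be >= 1")
  for (m in c(w_mean_control, w_mean_id)) {
    if (m < 0 || m > 1) stop_param("weight means must lie in [0, 1]")
  }
  if (w_concentration <= 0) stop_param("`w_concentration` must be positive")
  if (abs(isi_w_cor) > 1) stop_param("`isi_w_cor` must lie in [-1, 1]")
  spec <- as.list(environment())
  structure(spec, class = "cohort_spec")
}

# Bounded multinomial-style allocation of an ISI total over the 7 items
# (each 0..4): points are placed one at a time on a uniformly chosen item
# that still has headroom, so items always sum to the total.
allocate_isi_items <- function(isi_total) {
  items <- integer(7L)
  for (p in seq_len(isi_total)) {
    open <- which(items < 4L)
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}

draw_beta_from_latent <- function(z, mean, concentration) {
  a <- mean * concentration
  b <- (1 - mean) * concentration
  stats::qbeta(pnorm(z), a, b)
}

#' Simulate a case-control cohort
#'
#' Draws per-participant demographics, ISI scores, intrusion weights and
#' hypnograms, and (optionally) synthesizes the four-channel recordings.
#' ID participants draw the intrusion weight from a distribution with a
#' higher mean than controls, and the ISI total has positive latent
#' correlation with the drawn weight, so group differences and
#' weight-severity associations are recoverable downstream.
#'
#' With `signals = FALSE` the returned participants carry their hypnogram
#' and a stored seed instead of the (memory-heavy) signals; use
#' [realize_recording()] to build a participant's night on demand. A full
#' default night is about 230 MB, so cohort-scale analyses should stream
#' participants rather than materialize all recordings at once.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; the full cohort is reproducible from it.
#' @param signals If `TRUE`, synthesize and attach each recording.
#' @return An object of class `psg_cohort`: a list of participants, each a
#'   list with `participant_id`, `group`, `age`, `sex`, `isi_total`,
#'   `isi_items`, `true_concomitance`, `hypnogram`, `recording` (or `NULL`)
#'   and `recording_seed`.
#' @export
make_cohort <- function(spec = cohort_spec(), seed = 1L, signals = TRUE) {
  n <- spec$n_control + spec$n_id
  group <- rep(c("control", "ID"), c(spec$n_control, spec$n_id))
  seeds <- derive_seeds(seed, 2L * n + 1L)
  hyp_seeds <- seeds[seq_len(n)]
  rec_seeds <- seeds[n + seq_len(n)]

  meta <- with_seed(seeds[2L * n + 1L], {
    z_w <- rnorm(n)
    z_e <- rnorm(n)
    is_id <- group == "ID"
    w <- ifelse(is_id,
                draw_beta_from_latent(z_w, spec$w_mean_id, spec$w_concentration),
                draw_beta_from_latent(z_w, spec$w_mean_control, spec$w_concentration))
    rho <- spec$isi_w_cor
    z_isi <- rho * z_w + sqrt(1 - rho^2) * z_e
    isi <- ifelse(is_id,
                  spec$isi_mean_id + spec$isi_sd_id * z_isi,
                  spec$isi_mean_control + spec$isi_sd_control * z_isi)
    isi <- pmin(28L, pmax(0L, as.integer(round(isi))))
    age <- ifelse(is_id,
                  rnorm(n, spec$age_mean_id, spec$age_sd_id),
                  rnorm(n, spec$age_mean_control, spec$age_sd_control))
    age <- round(pmin(80, pmax(18, age)), 1)
    sex <- ifelse(runif(n) < ifelse(is_id, spec$p_female_id,
                                    spec$p_female_control), "F", "M")
    items <- lapply(isi, allocate_isi_items)
    list(w = w, isi = isi, age = age, sex = sex, items = items)
  })

  participants <- vector("list", n)
  for (i in seq_len(n)) {
    hyp <- simulate_hypnogram(spec$n_epochs, spec$transition_matrix,
                              spec$initial_dist, seed = hyp_seeds[i])
    p <- list(
      participant_id = sprintf("P%03d", i),
      group = group[i],
      age = meta$age[i],
      sex = meta$sex[i],
      isi_total = meta$isi[i],
      isi_items = meta$items[[i]],
      true_concomitance = meta$w[i],
      hypnogram = hyp,
      recording_seed = rec_seeds[i],
      recording = NULL
    )
    participants[[i]] <- p
  }
  cohort <- structure(list(participants = participants, spec = spec),
                      class = "psg_cohort")
  if (signals) {
    cohort$participants <- lapply(cohort$participants, function(p) {
      p$recording <- realize_recording(p, spec)
      p
    })
  }
  cohort
}

#' Synthesize one participant's recording on demand
#'
#' @param participant One element of a [make_cohort()] cohort.
#' @param spec The [cohort_spec()] the cohort was built with.
#' @return A [psg_recording()], identical to the one `make_cohort(signals =
#'   TRUE)` would have attached.
#' @export
realize_recording <- function(participant, spec) {
  conc <- concomitance_spec(base_stage = spec$base_stage,
                            intruder_stage = spec$intruder_stage,
                            weight = participant$true_concomitance,
                            placement = spec$placement,
                            heterogeneity = spec$w_heterogeneity)
  synthesize_recording(participant$hypnogram, profiles = spec$profiles,
                       concomitance = conc, fs = spec$fs,
                       seed = participant$recording_seed)
}

#' Participant-level table of a simulated cohort
#'
#' @param cohort A [make_cohort()] result.
#' @return Data frame with one row per participant: id, group, age, sex,
#'   ISI total, the seven ISI items and the true intrusion weight.
#' @export
cohort_table <- function(cohort) {
  ps <- cohort$participants
  items <- t(vapply(ps, function(p) p$isi_items, integer(7)))
  colnames(items) <- paste0("isi_", 1:7)
  data.frame(
    participant_id = vapply(ps, `[[`, character(1), "participant_id"),
    group = vapply(ps, `[[`, character(1), "group"),
    age = vapply(ps, `[[`, numeric(1), "age"),
    sex = vapply(ps, `[[`, character(1), "sex"),
    isi_total = vapply(ps, `[[`, integer(1), "isi_total"),
    items,
    true_concomitance = vapply(ps, `[[`, numeric(1), "true_concomitance"),
    stringsAsFactors = FALSE
  )
}

#' Write a cohort table as delimited text
#'
#' @param cohort A [make_cohort()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(cohort, path) {
  write.table(cohort_table(cohort), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @export
print.psg_cohort <- function(x, ...) {
  tab <- table(vapply(x$participants, `[[`, character(1), "group"))
  cat(sprintf("<psg_cohort> %d participants (%s), %d epochs/night\n",
              length(x$participants),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", "),
              x$spec$n_epochs))
  invisible(x)
}
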