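# End-to-end orchestration: recording -> preprocessing -> words -> topic
# mixtures -> vigilance metrics, for single nights and whole cohorts, plus
# topic/stage matching and the cohort-level group comparisons.

#' Analyze one night
#'
#' Symbolizes a preprocessed recording, infers per-epoch topic mixtures
#' with a trained model, and derives all stable-epoch measures.
#'
#' @param prep A [preprocess_recording()] result.
#' @param model A trained [train_lda()] model.
#' @param seed Seed for the (fold-in) inference.
#' @param n_burnin,n_samples Inference sweeps per document.
#' @return List with `diagram`, `labeling`, `records` (stable-epoch
#'   dominance/co-occurrence), `transitions`, `overall` (mean mixture) and
#'   `stable_pct`.
#' @export
analyze_recording <- function(prep, model, seed = 1L,
                              n_burnin = 50L, n_samples = 20L) {
  wc <- symbolize_recording(prep)
  theta <- infer_mixtures(wc, model, n_burnin = n_burnin,
                          n_samples = n_samples, seed = seed)
  diagram <- build_topic_diagram(theta, n_epochs = wc$n_epochs)
  labeling <- find_stable_epochs(dominant_topic(theta_matrix(diagram)),
                                 diagram$epoch)
  list(diagram = diagram,
       labeling = labeling,
       records = dominance_and_cooccurrence(diagram, labeling),
       transitions = transition_probabilities(labeling, K = model$K),
       overall = overall_topic_means(diagram),
       stable_pct = stable_time_percentages(labeling, K = model$K))
}

#' Analyze a simulated cohort
#'
#' Runs the full pipeline for every participant (streaming recordings that
#' were not materialized), optionally training the topic model on the
#' cohort's pooled word counts first. Mirrors the study design in which a
#' model trained once is applied to every night.
#'
#' @param cohort A [make_cohort()] result.
#' @param model A trained model, or `NULL` to train on this cohort.
#' @param seed Master seed for training/inference.
#' @param fs_out Analysis sampling rate passed to
#'   [preprocess_recording()].
#' @param train_args,infer_args Extra arguments for [train_lda()] /
#'   [infer_mixtures()] when training here.
#' @return An object of class `cohort_analysis`: list with `model`,
#'   `participants` (per-night analysis results), `records` (pooled
#'   stable-epoch rows with participant covariates), `summary`
#'   (participant x (overall means, stable percentages)), `transitions`
#'   (participant x source x destination array).
#' @export
analyze_cohort <- function(cohort, model = NULL, seed = 1L, fs_out = NULL,
                           train_args = list(), infer_args = list()) {
  ps <- cohort$participants
  n <- length(ps)
  seeds <- derive_seeds(seed, n + 1L)
  if (is.null(fs_out)) fs_out <- cohort$spec$fs

  # preprocess + symbolize every night (streaming non-materialized
  # recordings), train if needed, then infer all nights in one pooled
  # fold-in pass (documents are conditionally independent given phi)
  wcs <- vector("list", n)
  for (i in seq_len(n)) {
    rec <- ps[[i]]$recording
    if (is.null(rec)) rec <- realize_recording(ps[[i]], cohort$spec)
    prep <- preprocess_recording(rec, fs_out = fs_out)
    wcs[[i]] <- symbolize_recording(prep)
  }
  if (is.null(model)) {
    model <- do.call(train_lda,
                     c(list(corpus = wcs, seed = seeds[n + 1L]), train_args))
  }

  theta_all <- do.call(infer_mixtures,
                       c(list(corpus = wcs, model = model, seed = seeds[1L]),
                         infer_args))
  n_docs <- vapply(wcs, function(w) length(unique(w$counts$epoch)), integer(1))
  doc_end <- cumsum(n_docs)
  participants <- vector("list", n)
  for (i in seq_len(n)) {
    theta <- theta_all[seq.int(doc_end[i] - n_docs[i] + 1L, doc_end[i]), ,
                       drop = FALSE]
    diagram <- build_topic_diagram(theta,
                                   epoch_index = sort(unique(wcs[[i]]$counts$epoch)),
                                   n_epochs = wcs[[i]]$n_epochs)
    labeling <- find_stable_epochs(dominant_topic(theta_matrix(diagram)),
                                   diagram$epoch)
    participants[[i]] <- list(
      diagram = diagram,
      labeling = labeling,
      records = dominance_and_cooccurrence(diagram, labeling),
      transitions = transition_probabilities(labeling, K = model$K),
      overall = overall_topic_means(diagram),
      stable_pct = stable_time_percentages(labeling, K = model$K))
  }
  names(participants) <- vapply(ps, `[[`, character(1), "participant_id")

  covars <- cohort_table(cohort)
  records <- do.call(rbind, lapply(seq_len(n), function(i) {
    r <- participants[[i]]$records
    if (!nrow(r)) return(NULL)
    cbind(covars[i, , drop = FALSE], r, row.names = NULL)
  }))

  K <- model$K
  transitions <- array(NA_real_, dim = c(n, K, K),
                       dimnames = list(covars$participant_id,
                                       paste0("T", 1:K), paste0("T", 1:K)))
  for (i in seq_len(n)) {
    transitions[i, , ] <- participants[[i]]$transitions$probabilities
  }

  summary_df <- cbind(
    covars,
    do.call(rbind, lapply(participants, function(a) {
      c(setNames(a$overall, paste0("overall_", names(a$overall))),
        setNames(a$stable_pct$by_topic,
                 paste0("stable_pct_", names(a$stable_pct$by_topic))),
        stable_pct_total = a$stable_pct$total,
        n_kept = a$stable_pct$n_kept)
    }))
  )
  rownames(summary_df) <- NULL

  structure(list(model = model, participants = participants,
                 records = records, summary = summary_df,
                 transitions = transitions),
            class = "cohort_analysis")
}

#' Train a reference topic model on stage-balanced synthetic sleep
#'
#' Builds a training corpus of good-sleeper nights in which every stage is
#' equally represented (consolidated runs of each stage in randomized
#' order), trains the K = 6 model on the pooled word counts, and identifies
#' each stage's topic. Equal stage representation matters: under realistic
#' stage prevalences N1 (a few percent of epochs) is too rare to earn its
#' own topic and the model splits an abundant stage instead. With balanced
#' training and the slow-wave depth structure of the generator, the six
#' topics align with deep N3, light N3, N2, N1, REM and W.
#'
#' @param n_nights Number of training nights.
#' @param epochs_per_block Epochs per consolidated stage run.
#' @param blocks_per_stage How many runs of each stage per night.
#' @param fs Sampling rate (Hz).
#' @param profiles Stage profiles for the generator.
#' @param seed Integer seed.
#' @param train_args Extra arguments for [train_lda()].
#' @return List with `model` (an `lda_model`), `stage_map` (topic index per
#'   stage, see [match_topics_to_stages()]) and `hypnograms`.
#' @export
train_reference_model <- function(n_nights = 8L, epochs_per_block = 10L,
                                  blocks_per_stage = 6L, fs = 100,
                                  profiles = default_stage_profiles(),
                                  seed = 1L, train_args = list()) {
  stages <- sleep_stages()
  seeds <- derive_seeds(seed, 2L * n_nights + 1L)
  wcs <- vector("list", n_nights)
  hyps <- vector("list", n_nights)
  stage_of_doc <- vector("list", n_nights)
  for (i in seq_len(n_nights)) {
    hyp <- with_seed(seeds[i], {
      blocks <- rep(stages, blocks_per_stage)
      unlist(lapply(sample(blocks), rep, times = epochs_per_block))
    })
    rec <- synthesize_recording(hyp, profiles = profiles, fs = fs,
                                seed = seeds[n_nights + i])
    prep <- preprocess_recording(rec, fs_out = fs)
    wcs[[i]] <- symbolize_recording(prep)
    hyps[[i]] <- hyp
    stage_of_doc[[i]] <- hyp[sort(unique(wcs[[i]]$counts$epoch))]
  }
  model <- do.call(train_lda, c(list(corpus = wcs, seed = seeds[2L * n_nights + 1L]),
                                train_args))
  theta <- model$theta_train[, model$ranking, drop = FALSE]
  stg <- unlist(stage_of_doc)
  score <- t(vapply(stages, function(s) colMeans(theta[stg == s, , drop = FALSE]),
                    numeric(model$K)))
  perms <- permutations_of(seq_len(model$K), length(stages))
  best <- perms[[which.max(vapply(perms, function(p) {
    sum(score[cbind(seq_along(stages), p)])
  }, numeric(1)))]]
  list(model = model, stage_map = setNames(best, stages), hypnograms = hyps)
}

#' Match topics to sleep stages
#'
#' Assigns each of the five stages the topic with the greatest mean
#' probability over that stage's kept epochs (over the supplied nights),
#' using the assignment that maximizes the total matched probability so no
#' topic is used twice. Useful for identifying e.g. the deep-sleep-related
#' and light-sleep-related topics of a freshly trained model.
#'
#' @param analysis A `cohort_analysis`.
#' @param cohort The cohort it was computed from (for the hypnograms).
#' @return Named integer vector: topic index per stage.
#' @export
match_topics_to_stages <- function(analysis, cohort) {
  stages <- sleep_stages()
  K <- analysis$model$K
  score <- matrix(0, length(stages), K, dimnames = list(stages, NULL))
  cnt <- setNames(numeric(length(stages)), stages)
  for (i in seq_along(analysis$participants)) {
    a <- analysis$participants[[i]]
    hyp <- cohort$participants[[i]]$hypnogram
    th <- theta_matrix(a$diagram)
    stg <- hyp[a$diagram$epoch]
    for (s in stages) {
      sel <- stg == s
      if (any(sel)) {
        score[s, ] <- score[s, ] + colSums(th[sel, , drop = FALSE])
        cnt[s] <- cnt[s] + sum(sel)
      }
    }
  }
  score <- score / pmax(cnt, 1)
  # exhaustive assignment (5 stages among K topics, K small)
  perms <- permutations_of(seq_len(K), length(stages))
  best <- perms[[which.max(vapply(perms, function(p) {
    sum(score[cbind(seq_along(stages), p)])
  }, numeric(1)))]]
  setNames(best, stages)
}

# All injective mappings of `k` slots into `v` (list of integer vectors).
permutations_of <- function(v, k) {
  if (k == 0L) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v)) {
    rest <- permutations_of(v[-i], k - 1L)
    out <- c(out, lapply(rest, function(r) c(v[i], r)))
  }
  out
}

#' Cohort-level group comparisons
#'
#' The statistical battery applied to an analyzed cohort: Wilcoxon
#' rank-sum tests for the participant-level measures (overall topic
#' probabilities, stable-time percentages, transition probabilities) and
#' epoch-level mixed-effects models (group + age + sex, random intercept
#' per participant) for dominance and co-occurrence within each stable
#' epoch type. No multiplicity correction is applied by default; set
#' `p_adjust = "BH"` for a Benjamini-Hochberg variant.
#'
#' @param analysis A `cohort_analysis`.
#' @param p_adjust `"none"` (default) or a method of [stats::p.adjust()].
#' @return List with data frames `overall`, `stable_pct`, `transitions`
#'   (Wilcoxon rows) and `dominance`, `cooccurrence` (mixed-model rows).
#' @export
compare_cohort_groups <- function(analysis, p_adjust = "none") {
  sm <- analysis$summary
  is_id <- sm$group == "ID"
  K <- analysis$model$K
  wilcox_row <- function(measure, values) {
    # measures can be missing for whole groups (e.g. a stable type nobody
    # expressed); those yield no comparison row
    if (!sum(!is.na(values[!is_id])) || !sum(!is.na(values[is_id]))) {
      return(NULL)
    }
    gc <- wilcoxon_ranksum(values[!is_id], values[is_id])
    data.frame(measure = measure,
               mean_control = gc$means[["x"]], sd_control = gc$sds[["x"]],
               mean_id = gc$means[["y"]], sd_id = gc$sds[["y"]],
               n_control = gc$n[["x"]], n_id = gc$n[["y"]],
               W = gc$W, z = gc$z, p = gc$p, stringsAsFactors = FALSE)
  }

  overall <- do.call(rbind, lapply(paste0("T", 1:K), function(t) {
    wilcox_row(paste0("overall_", t), sm[[paste0("overall_", t)]])
  }))
  stable_pct <- do.call(rbind, lapply(c(paste0("T", 1:K), "total"), function(t) {
    col <- if (t == "total") "stable_pct_total" else paste0("stable_pct_", t)
    wilcox_row(col, sm[[col]])
  }))

  trans <- NULL
  for (src in seq_len(K)) {
    for (dst in seq_len(K)) {
      if (src == dst) next
      v <- analysis$transitions[, src, dst]
      if (sum(!is.na(v[!is_id])) && sum(!is.na(v[is_id]))) {
        trans <- rbind(trans, wilcox_row(sprintf("p_T%d_to_T%d", src, dst), v))
      }
    }
  }

  mm_rows <- function(outcome_col, type) {
    rows <- NULL
    for (t in paste0("T", 1:K)) {
      d <- analysis$records[analysis$records$stable_type == t, , drop = FALSE]
      oc <- if (outcome_col == "dominance") "dominance" else paste0("cooc_", type)
      if (outcome_col == "dominance") oc <- "dominance"
      if (is.null(d) || !nrow(d) || length(unique(d$participant_id)) < 2L) next
      if (outcome_col == "dominance") {
        fit <- try(fit_mixed_model(d, "dominance"), silent = TRUE)
        if (!inherits(fit, "try-error")) {
          cf <- fit$coefficients[fit$coefficients$term == "group_id", ]
          rows <- rbind(rows, data.frame(stable_type = t, outcome = "dominance",
                                         estimate = cf$estimate, se = cf$se,
                                         t = cf$t, df = cf$df, p = cf$p))
        }
      } else {
        for (other in setdiff(paste0("T", 1:K), t)) {
          oc <- paste0("cooc_", other)
          if (all(is.na(d[[oc]]))) next
          fit <- try(fit_mixed_model(d, oc), silent = TRUE)
          if (inherits(fit, "try-error")) next
          cf <- fit$coefficients[fit$coefficients$term == "group_id", ]
          rows <- rbind(rows, data.frame(stable_type = t, outcome = oc,
                                         estimate = cf$estimate, se = cf$se,
                                         t = cf$t, df = cf$df, p = cf$p))
        }
      }
    }
    rows
  }
  dominance <- mm_rows("dominance", NULL)
  cooccurrence <- mm_rows("cooc", NULL)

  out <- list(overall = overall, stable_pct = stable_pct, transitions = trans,
              dominance = dominance, cooccurrence = cooccurrence)
  if (p_adjust != "none") {
    out <- lapply(out, function(df) {
      if (!is.null(df)) df$p_adj <- stats::p.adjust(df$p, method = p_adjust)
      df
    })
  }
  out
}
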