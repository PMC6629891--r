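# Six-topic Latent Dirichlet Allocation over per-epoch word counts:
# collapsed Gibbs training, fold-in inference of per-epoch topic mixtures,
# deterministic topic ranking from deep-sleep to wakefulness, and the
# topic-diagram container.

# Expand a word_counts object (or a (doc, word_id, count) triplet data
# frame) into 0-based parallel token vectors. Documents are kept epochs in
# order for word_counts input.
corpus_tokens <- function(corpus) {
  if (inherits(corpus, "word_counts")) corpus <- list(corpus)
  if (is.list(corpus) && all(vapply(corpus, inherits, logical(1), "word_counts"))) {
    doc0 <- integer(0); wrd <- integer(0); offset <- 0L
    for (wc in corpus) {
      cts <- wc$counts
      docs_local <- match(cts$epoch, sort(unique(cts$epoch)))
      doc0 <- c(doc0, rep(docs_local + offset, cts$count))
      wrd <- c(wrd, rep(cts$word_id, cts$count))
      offset <- offset + length(unique(cts$epoch))
    }
    return(list(doc = doc0 - 1L, word = wrd - 1L, n_docs = offset))
  }
  cts <- as.data.frame(corpus)
  names(cts)[1:3] <- c("doc", "word_id", "count")
  docs_local <- match(cts$doc, sort(unique(cts$doc)))
  list(doc = rep(docs_local, cts$count) - 1L,
       word = rep(cts$word_id, cts$count) - 1L,
       n_docs = length(unique(cts$doc)))
}

#' Train a topic model by collapsed Gibbs sampling
#'
#' Learns the `K` topic-over-word distributions from word-count documents
#' (30-s epochs). After `n_burnin` sweeps, `n_samples` further sweeps are
#' averaged for the posterior-mean estimates of `phi` (topic-word) and the
#' training-document mixtures. The run records the joint log-likelihood
#' log p(w, z) per sweep.
#'
#' @param corpus A `word_counts` object, a list of them (one per
#'   participant), or a (doc, word_id, count) triplet data frame.
#' @param K Number of topics (default 6).
#' @param alpha Symmetric document-topic Dirichlet concentration. The
#'   default 0.8 admits genuinely mixed epochs without forcing uniformity.
#' @param eta Symmetric topic-word concentration (default 0.1).
#' @param n_burnin,n_samples Gibbs sweeps discarded / averaged.
#' @param seed Integer seed; training is deterministic given the seed.
#' @param vocab Vocabulary table; taken from the corpus when available.
#' @return An object of class `lda_model`: list with `phi` (K x V, rows sum
#'   to 1), `K`, `alpha`, `eta`, `ranking` (permutation mapping T1..TK to
#'   raw topic indices, see [rank_topics()]), `loglik`, `vocab`.
#' @export
train_lda <- function(corpus, K = 6L, alpha = 0.8, eta = 0.1,
                      n_burnin = 500L, n_samples = 100L, seed = 1L,
                      vocab = NULL) {
  if (K < 2L) stop_param("`K` must be at least 2")
  if (is.null(vocab)) {
    vocab <- if (inherits(corpus, "word_counts")) corpus$vocab
    else if (is.list(corpus) && inherits(corpus[[1L]], "word_counts")) corpus[[1L]]$vocab
    else build_vocabulary()
  }
  tk <- corpus_tokens(corpus)
  if (tk$n_docs < 1L || !length(tk$doc)) stop("empty corpus", call. = FALSE)
  doc_sizes <- tabulate(tk$doc + 1L, nbins = tk$n_docs)
  if (any(doc_sizes == 0L)) stop("corpus contains empty documents", call. = FALSE)
  V <- nrow(vocab)
  fit <- with_seed(seed, {
    lda_gibbs_train_cpp(tk$doc, tk$word, tk$n_docs, V, as.integer(K),
                        alpha, eta, as.integer(n_burnin), as.integer(n_samples))
  })
  model <- structure(
    list(phi = fit$phi, K = as.integer(K), alpha = alpha, eta = eta,
         ranking = seq_len(K), loglik = as.numeric(fit$loglik),
         theta_train = fit$theta, vocab = vocab),
    class = "lda_model")
  model$ranking <- rank_topics(model)
  model
}

#' Rank topics from deep sleep to wakefulness
#'
#' Topics are ordered by a depth score: the expected quantile level (V..E
#' mapped to 0..4, averaged over a word's three letters) of the C3-A2 delta
#' stream minus that of the C3-A2 beta stream, each taken under the topic's
#' word distribution restricted to the stream. The deepest topic (highest
#' score) becomes T1 and the most wake-like becomes the last topic. Scores
#' tied within 0.05 are broken by the expected EOG cross-correlation level
#' (eye movements give negative cross-correlation, i.e. low levels, and
#' rank later); remaining ties fall back to the raw topic index.
#'
#' @param model An `lda_model`.
#' @return Integer permutation `r` such that ranked topic `Ti` is raw topic
#'   `r[i]`.
#' @export
rank_topics <- function(model) {
  stream_level_score <- function(stream_id) {
    idx <- which(model$vocab$stream_id == stream_id)
    if (!length(idx)) return(rep(NA_real_, model$K))
    letters <- if (grepl("xcorr|pow", stream_id)) EOG_LETTERS else EEG_LETTERS
    lv <- vapply(strsplit(model$vocab$word[idx], ""), function(ls) {
      mean(match(ls, letters) - 1L)
    }, numeric(1))
    mass <- model$phi[, idx, drop = FALSE]
    as.numeric((mass %*% lv) / pmax(rowSums(mass), 1e-300))
  }
  depth <- stream_level_score("C3A2.delta") - stream_level_score("C3A2.beta")
  xc <- stream_level_score("EOG.xcorr")
  # models over foreign vocabularies (no EEG streams) keep the raw order
  if (all(!is.finite(depth))) return(seq_len(model$K))
  ord <- seq_len(model$K)
  # primary: depth descending; ties within 0.05 by xcorr level descending;
  # final tie-break by raw index. Implemented as a tolerant comparison sort.
  cmp <- function(i, j) {
    if (abs(depth[i] - depth[j]) >= 0.05) return(depth[i] > depth[j])
    if (!is.na(xc[i]) && !is.na(xc[j]) && abs(xc[i] - xc[j]) > 1e-12) {
      return(xc[i] > xc[j])
    }
    i < j
  }
  for (a in seq_len(model$K - 1L)) {
    for (b in seq.int(a + 1L, model$K)) {
      if (!cmp(ord[a], ord[b])) { tmp <- ord[a]; ord[a] <- ord[b]; ord[b] <- tmp }
    }
  }
  ord
}

#' Infer per-document topic mixtures (fold-in)
#'
#' Gibbs-samples the token-topic assignments of new documents with the
#' model's topic-word distributions held fixed, and returns the
#' posterior-mean mixtures in ranked (T1..TK) order. Documents are
#' conditionally independent, so any number can be processed in one call.
#'
#' @param corpus A `word_counts` object or a (doc, word_id, count) triplet
#'   data frame.
#' @param model An `lda_model`.
#' @param n_burnin,n_samples Gibbs sweeps discarded / averaged per run.
#' @param seed Integer seed.
#' @return Matrix of mixtures, one row per document, columns `T1..TK`;
#'   rows are non-negative and sum to 1. Row names carry the epoch index
#'   for `word_counts` input.
#' @export
infer_mixtures <- function(corpus, model, n_burnin = 50L, n_samples = 20L,
                           seed = 1L) {
  tk <- corpus_tokens(corpus)
  if (!length(tk$doc)) stop("empty document set", call. = FALSE)
  if (max(tk$word) + 1L > nrow(model$vocab)) {
    stop("vocabulary mismatch between corpus and model", call. = FALSE)
  }
  theta <- with_seed(seed, {
    lda_gibbs_infer_cpp(tk$doc, tk$word, tk$n_docs, model$phi, model$alpha,
                        as.integer(n_burnin), as.integer(n_samples))
  })
  theta <- theta[, model$ranking, drop = FALSE]
  colnames(theta) <- paste0("T", seq_len(model$K))
  if (inherits(corpus, "word_counts")) {
    rownames(theta) <- sort(unique(corpus$counts$epoch))
  }
  theta
}

#' @rdname infer_mixtures
#' @param doc A single document: a named or plain count vector over the
#'   vocabulary, or a one-document triplet data frame.
#' @export
infer_mixture <- function(doc, model, n_burnin = 50L, n_samples = 20L,
                          seed = 1L) {
  if (is.numeric(doc) && is.null(dim(doc))) {
    if (sum(doc) < 1) stop("empty document", call. = FALSE)
    doc <- data.frame(doc = 1L, word_id = which(doc > 0),
                      count = as.integer(doc[doc > 0]))
  }
  drop(infer_mixtures(doc, model, n_burnin, n_samples, seed))
}

#' Topic diagram
#'
#' Ordered per-epoch topic mixtures for one night, with rejected epochs as
#' explicit gaps (not zero columns).
#'
#' @param theta Mixture matrix from [infer_mixtures()], one row per kept
#'   epoch, columns `T1..TK`.
#' @param epoch_index Integer epoch indices of the rows (strictly
#'   increasing). Defaults to the matrix row names.
#' @param n_epochs Total number of epochs in the night (kept + rejected).
#' @return An object of class `topic_diagram`: data frame with `epoch` and
#'   topic-probability columns, plus attributes `n_epochs` and `gaps`.
#' @export
build_topic_diagram <- function(theta, epoch_index = NULL,
                                n_epochs = NULL) {
  if (is.null(epoch_index)) epoch_index <- as.integer(rownames(theta))
  if (anyNA(epoch_index)) stop_param("`epoch_index` is required")
  if (anyDuplicated(epoch_index)) stop("duplicate epoch indices", call. = FALSE)
  if (is.unsorted(epoch_index, strictly = TRUE)) {
    stop("epoch indices must be strictly increasing", call. = FALSE)
  }
  if (is.null(n_epochs)) n_epochs <- max(epoch_index)
  df <- data.frame(epoch = as.integer(epoch_index), theta, check.names = FALSE)
  rownames(df) <- NULL
  structure(df, n_epochs = as.integer(n_epochs),
            gaps = setdiff(seq_len(n_epochs), epoch_index),
            class = c("topic_diagram", "data.frame"))
}

theta_matrix <- function(diagram) {
  as.matrix(diagram[, grep("^T\\d+$", names(diagram)), drop = FALSE])
}

#' Plot a topic diagram
#'
#' Stacked per-epoch topic probabilities colored from dark blue (T1, deep
#' sleep) to red (wake-like); rejected epochs appear as blank gaps.
#'
#' @param x A `topic_diagram`.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.topic_diagram <- function(x, ...) {
  th <- theta_matrix(x)
  K <- ncol(th)
  full <- matrix(NA_real_, nrow = K, ncol = attr(x, "n_epochs"))
  full[, x$epoch] <- t(th)
  cols <- grDevices::hcl.colors(K, "Spectral", rev = TRUE)
  graphics::barplot(full, col = cols, border = NA, space = 0,
                    xlab = "epoch (30 s)", ylab = "topic probability", ...)
  graphics::legend("topright", legend = colnames(th), fill = cols,
                   bty = "n", cex = 0.7, horiz = TRUE)
  invisible(x)
}

#' Serialize / load a topic model
#'
#' The scalar parameters and ranking go to JSON; `phi` goes to a delimited
#' (topic_id, word_id, probability) table next to it.
#'
#' @param model An `lda_model`.
#' @param json_path Path for the JSON metadata.
#' @param phi_path Path for the phi table (default: `json_path` with a
#'   `.phi.tsv` suffix).
#' @return `json_path`, invisibly; `read_lda_model()` returns the model
#'   (without the training log).
#' @export
write_lda_model <- function(model, json_path,
                            phi_path = paste0(json_path, ".phi.tsv")) {
  meta <- list(K = model$K, alpha = model$alpha, eta = model$eta,
               ranking = model$ranking, V = nrow(model$vocab),
               phi_file = basename(phi_path))
  jsonlite::write_json(meta, json_path, auto_unbox = TRUE, digits = NA)
  phi_df <- data.frame(topic_id = rep(seq_len(model$K), times = ncol(model$phi)),
                       word_id = rep(seq_len(ncol(model$phi)), each = model$K),
                       probability = as.vector(model$phi))
  write.table(phi_df, phi_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}

#' @rdname write_lda_model
#' @export
read_lda_model <- function(json_path,
                           phi_path = paste0(json_path, ".phi.tsv")) {
  meta <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  phi_df <- read.table(phi_path, header = TRUE, sep = "\t")
  phi <- matrix(0, meta$K, meta$V)
  phi[cbind(phi_df$topic_id, phi_df$word_id)] <- phi_df$probability
  structure(list(phi = phi, K = meta$K, alpha = meta$alpha, eta = meta$eta,
                 ranking = meta$ranking, loglik = NULL,
                 vocab = build_vocabulary()),
            class = "lda_model")
}

#' @export
print.lda_model <- function(x, ...) {
  cat(sprintf("<lda_model> K = %d topics over %d words (alpha = %g, eta = %g)\n",
              x$K, ncol(x$phi), x$alpha, x$eta))
  invisible(x)
}
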