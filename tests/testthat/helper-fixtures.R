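# Shared fixtures. Heavy objects are built once per test run and memoized.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# A reference topic model trained on a cohort of good sleepers (no
# intrusion), mirroring a model trained once on an independent dataset and
# then applied to new recordings.
reference_model_fixture <- function() {
  memo("reference_model", function() {
    train_reference_model(seed = 101,
                          train_args = list(n_burnin = 200, n_samples = 50))
  })
}

# A small fully analyzed mixed cohort for structural/normalization checks.
small_analysis_fixture <- function() {
  memo("small_analysis", function() {
    ref <- reference_model_fixture()
    spec <- cohort_spec(n_control = 3, n_id = 3, n_epochs = 120, fs = 100)
    coh <- make_cohort(spec, seed = 42, signals = FALSE)
    an <- analyze_cohort(coh, model = ref$model, seed = 2,
                         infer_args = list(n_burnin = 20, n_samples = 8))
    list(cohort = coh, analysis = an)
  })
}

# A tiny preprocessed night reused by symbolization tests.
tiny_prep_fixture <- function() {
  memo("tiny_prep", function() {
    hyp <- simulate_hypnogram(40, seed = 11)
    rec <- synthesize_recording(hyp, fs = 100, seed = 12)
    list(hyp = hyp, rec = rec, prep = preprocess_recording(rec, fs_out = 100))
  })
}

# Brute-force oracle: stable epochs by explicit scan over maximal runs.
stable_epochs_oracle <- function(labels, epoch_index, min_run = 3L) {
  n <- length(labels)
  stable <- logical(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && epoch_index[j + 1L] == epoch_index[j] + 1L &&
           labels[j + 1L] == labels[j]) {
      j <- j + 1L
    }
    if (j - i + 1L >= min_run) stable[i:j] <- TRUE
    i <- j + 1L
  }
  stable
}

# Brute-force oracle: word counts by explicit loops over epochs, streams
# and window starts.
word_counts_oracle <- function(streams, keep, vocab) {
  st <- stream_table()
  counts <- matrix(0L, nrow = length(keep), ncol = nrow(vocab))
  key <- paste(vocab$stream_id, vocab$word, sep = ":")
  for (sid in st$stream_id) {
    lt <- streams[[sid]]
    if (!is.character(lt)) lt <- attr(lt, "letters")[as.integer(lt)]
    for (ep in which(keep)) {
      off <- (ep - 1L) * 30L
      for (w in 1:28) {
        word <- paste0(lt[off + w], lt[off + w + 1L], lt[off + w + 2L])
        id <- match(paste(sid, word, sep = ":"), key)
        counts[ep, id] <- counts[ep, id] + 1L
      }
    }
  }
  counts
}

# Random letter streams for oracle tests.
random_streams <- function(n_epochs, seed) {
  set.seed(seed)
  st <- stream_table()
  streams <- lapply(seq_len(nrow(st)), function(i) {
    a <- st$alphabet_size[i]
    labels <- if (a == 5L) c("V", "L", "M", "H", "E") else c("V", "L", "H", "E")
    sample(labels, 30L * n_epochs, replace = TRUE)
  })
  names(streams) <- st$stream_id
  streams
}

# Sparse triplet corpus drawn from a known topic model (multinomial
# composition: topic counts per document, then word counts per topic).
draw_corpus <- function(phi, alpha, n_docs, doc_len, seed, theta = NULL) {
  set.seed(seed)
  K <- nrow(phi); V <- ncol(phi)
  doc_v <- wid_v <- cnt_v <- vector("list", n_docs)
  for (d in seq_len(n_docs)) {
    th <- if (is.null(theta)) {
      g <- rgamma(K, alpha)
      g / sum(g)
    } else theta
    nk <- drop(stats::rmultinom(1L, doc_len, th))
    cnt <- numeric(V)
    for (k in which(nk > 0L)) {
      cnt <- cnt + drop(stats::rmultinom(1L, nk[k], phi[k, ]))
    }
    ids <- which(cnt > 0)
    doc_v[[d]] <- rep.int(d, length(ids))
    wid_v[[d]] <- ids
    cnt_v[[d]] <- as.integer(cnt[ids])
  }
  data.frame(doc = unlist(doc_v), word_id = unlist(wid_v),
             count = unlist(cnt_v))
}

# A well-separated block-structured topic-word matrix over the composite
# vocabulary.
block_phi <- function(K = 6L, V = 1192L) {
  blocks <- split(seq_len(V), cut(seq_len(V), K, labels = FALSE))
  phi <- matrix(1e-8, K, V)
  for (k in seq_len(K)) phi[k, blocks[[k]]] <- 1
  phi / rowSums(phi)
}

total_variation <- function(p, q) 0.5 * sum(abs(p - q))

# Best topic matching (minimal summed TV distance over assignments).
matched_tv <- function(phi_hat, phi_true) {
  K <- nrow(phi_true)
  tv <- outer(seq_len(K), seq_len(K), Vectorize(function(i, j) {
    total_variation(phi_hat[i, ], phi_true[j, ])
  }))
  perms <- sleeptopics:::permutations_of(seq_len(K), K)
  best <- which.min(vapply(perms, function(p) sum(tv[cbind(p, seq_len(K))]),
                           numeric(1)))
  p <- perms[[best]]
  vapply(seq_len(K), function(j) tv[p[j], j], numeric(1))
}
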