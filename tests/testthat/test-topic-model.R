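test_that("training separates a corpus with disjoint vocabulary blocks", {
  V <- 60L
  phi_true <- matrix(0, 2, V)
  phi_true[1, 1:30] <- 1 / 30
  phi_true[2, 31:60] <- 1 / 30
  vocab <- data.frame(word_id = 1:V, stream_id = "synthetic",
                      word = sprintf("w%03d", 1:V))
  corpus <- draw_corpus(phi_true, alpha = 0.2, n_docs = 2000, doc_len = 40,
                        seed = 301)
  model <- train_lda(corpus, K = 2, alpha = 0.2, eta = 0.1,
                     n_burnin = 150, n_samples = 50, seed = 5, vocab = vocab)
  # phi rows are probability distributions
  expect_equal(rowSums(model$phi), c(1, 1), tolerance = 1e-9)
  # each recovered topic concentrates on one block
  block_mass <- cbind(rowSums(model$phi[, 1:30]), rowSums(model$phi[, 31:60]))
  expect_gte(max(block_mass[1, ]), 0.95)
  expect_gte(max(block_mass[2, ]), 0.95)
  expect_equal(sort(apply(block_mass, 1, which.max)), 1:2)
  # the joint log-likelihood improves over the run
  expect_gt(tail(model$loglik, 1), model$loglik[1])
  # determinism
  model2 <- train_lda(corpus, K = 2, alpha = 0.2, eta = 0.1,
                      n_burnin = 150, n_samples = 50, seed = 5, vocab = vocab)
  expect_identical(model$phi, model2$phi)
})

test_that("training rejects degenerate corpora", {
  corpus <- data.frame(doc = c(1, 1), word_id = c(1, 2), count = c(0, 0))
  expect_error(train_lda(corpus, K = 2), "empty")
  good <- data.frame(doc = 1:4, word_id = 1:4, count = 1)
  expect_error(train_lda(good, K = 1), "at least 2")
})

test_that("fold-in inference recovers pure and mixed documents", {
  phi <- block_phi(K = 6, V = 1192)
  model <- structure(list(phi = phi, K = 6L, alpha = 0.8, eta = 0.1,
                          ranking = 1:6, vocab = build_vocabulary()),
                     class = "lda_model")
  # pure documents: dominant topic >= 0.9
  for (k in c(1L, 4L)) {
    doc <- draw_corpus(phi, alpha = 0.8, n_docs = 1, doc_len = 308,
                       seed = 400 + k, theta = as.numeric(seq_len(6) == k))
    th <- infer_mixture(doc, model, seed = 1)
    expect_equal(sum(th), 1, tolerance = 1e-9)
    expect_gte(th[[paste0("T", k)]], 0.9)
  }
  # an even two-topic blend lands near (0.5, 0.5)
  doc <- draw_corpus(phi, alpha = 0.8, n_docs = 1, doc_len = 308, seed = 410,
                     theta = c(0.5, 0.5, 0, 0, 0, 0))
  th <- infer_mixture(doc, model, seed = 2)
  expect_true(all(th[c("T1", "T2")] > 0.3 & th[c("T1", "T2")] < 0.7))
  expect_error(infer_mixture(numeric(1192), model), "empty")
})

test_that("average inferred mixtures are calibrated", {
  # generating mixture (0.7, 0.3, 0, 0, 0, 0): the average posterior mean
  # over documents comes back within 0.05
  phi <- block_phi(K = 6, V = 1192)
  model <- structure(list(phi = phi, K = 6L, alpha = 0.8, eta = 0.1,
                          ranking = 1:6, vocab = build_vocabulary()),
                     class = "lda_model")
  corpus <- draw_corpus(phi, alpha = 0.8, n_docs = 1000, doc_len = 308,
                        seed = 500, theta = c(0.7, 0.3, 0, 0, 0, 0))
  th <- infer_mixtures(corpus, model, seed = 3)
  avg <- colMeans(th)
  expect_lt(abs(avg[["T1"]] - 0.7), 0.05)
  expect_lt(abs(avg[["T2"]] - 0.3), 0.05)
  expect_lt(max(avg[3:6]), 0.05)
})

test_that("inference depends on counts only (bag-of-words exchangeability)", {
  phi <- block_phi(K = 6, V = 1192)
  model <- structure(list(phi = phi, K = 6L, alpha = 0.8, eta = 0.1,
                          ranking = 1:6, vocab = build_vocabulary()),
                     class = "lda_model")
  corpus <- draw_corpus(phi, alpha = 0.8, n_docs = 5, doc_len = 100, seed = 77)
  shuffled <- corpus[sample(nrow(corpus)), ]
  shuffled <- shuffled[order(shuffled$doc), ]  # same counts, new word order
  t1 <- infer_mixtures(corpus, model, seed = 4)
  t2 <- infer_mixtures(shuffled, model, seed = 4)
  expect_equal(t1, t2, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("topic ranking orders deep sleep before wakefulness", {
  vocab <- build_vocabulary()
  # construct six topics with strictly decreasing delta level and
  # increasing beta level on C3-A2
  K <- 6L
  phi <- matrix(1e-10, K, nrow(vocab))
  delta_ids <- vocab$word_id[vocab$stream_id == "C3A2.delta"]
  beta_ids <- vocab$word_id[vocab$stream_id == "C3A2.beta"]
  level <- function(word) mean(match(strsplit(word, "")[[1]],
                                     c("V", "L", "M", "H", "E"))) - 1
  dl <- vapply(vocab$word[delta_ids], level, numeric(1))
  bl <- vapply(vocab$word[beta_ids], level, numeric(1))
  for (k in seq_len(K)) {
    want_d <- 4 - (k - 1) * 0.8   # 4, 3.2, ..., 0
    want_b <- (k - 1) * 0.8
    phi[k, delta_ids[which.min(abs(dl - want_d))]] <- 1
    phi[k, beta_ids[which.min(abs(bl - want_b))]] <- 1
  }
  phi <- phi / rowSums(phi)
  scramble <- c(4, 1, 6, 2, 5, 3)
  model <- structure(list(phi = phi[scramble, ], K = K, alpha = 0.8, eta = 0.1,
                          ranking = 1:6, vocab = vocab), class = "lda_model")
  r <- rank_topics(model)
  expect_identical(sort(r), 1:6)                  # a bijection
  expect_identical(r, order(scramble))            # construction order back
  # relabeling by the ranking is idempotent
  model2 <- model
  model2$phi <- model$phi[r, ]
  expect_identical(rank_topics(model2), 1:6)
})

test_that("topic diagrams preserve gaps and normalization", {
  theta <- matrix(c(0.6, 0.1, 0.1, 0.1, 0.05, 0.05,
                    0.2, 0.2, 0.2, 0.2, 0.1, 0.1), 2, byrow = TRUE)
  colnames(theta) <- paste0("T", 1:6)
  d <- build_topic_diagram(theta, epoch_index = c(2L, 5L), n_epochs = 6L)
  expect_identical(attr(d, "gaps"), c(1L, 3L, 4L, 6L))
  expect_equal(unname(rowSums(sleeptopics:::theta_matrix(d))), c(1, 1))
  expect_error(build_topic_diagram(theta, epoch_index = c(2L, 2L)), "duplicate")
  expect_error(build_topic_diagram(theta, epoch_index = c(5L, 2L)), "increasing")
  # plotting works headlessly
  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_no_error(plot(d))
  grDevices::dev.off()
  unlink(tmp)
})

test_that("models serialize to JSON + phi table and back", {
  phi <- block_phi(K = 3, V = 1192)
  model <- structure(list(phi = phi, K = 3L, alpha = 0.5, eta = 0.2,
                          ranking = c(2L, 3L, 1L), vocab = build_vocabulary()),
                     class = "lda_model")
  tmp <- tempfile(fileext = ".json")
  write_lda_model(model, tmp)
  back <- read_lda_model(tmp)
  expect_equal(back$phi, model$phi, tolerance = 1e-12)
  expect_identical(back$ranking, model$ranking)
  expect_equal(back$alpha, model$alpha)
  unlink(c(tmp, paste0(tmp, ".phi.tsv")))
})
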