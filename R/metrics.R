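# Outcome measures derived from a topic diagram: dominant-topic labeling,
# stable-epoch detection, dominance and normalized co-occurrence,
# stable-epoch transition probabilities, overall topic means and
# stable-time percentages.

#' Dominant topic of a mixture
#'
#' Argmax of the topic probabilities; exact ties resolve to the lower topic
#' index for determinism.
#'
#' @param theta A mixture vector, or a matrix with one mixture per row.
#' @return Integer topic index (vector for matrix input).
#' @export
dominant_topic <- function(theta) {
  if (is.null(dim(theta))) theta <- matrix(theta, nrow = 1L)
  max.col(theta, ties.method = "first")
}

#' Stable-epoch labeling
#'
#' An epoch is *stable* when it belongs to a maximal run of at least three
#' consecutive epochs sharing the same dominant topic. Runs are computed
#' within contiguous kept segments only: a rejected (gap) epoch breaks
#' temporal adjacency.
#'
#' @param labels Integer dominant-topic labels of the kept epochs, in
#'   temporal order.
#' @param epoch_index Epoch indices of the kept epochs (gaps are where
#'   consecutive indices differ by more than 1).
#' @param min_run Minimal run length for stability (default 3).
#' @return Data frame with columns `epoch`, `topic`, `run_id`, `run_len`,
#'   `stable`.
#' @export
find_stable_epochs <- function(labels, epoch_index = seq_along(labels),
                               min_run = 3L) {
  n <- length(labels)
  stopifnot(length(epoch_index) == n)
  if (!n) {
    return(data.frame(epoch = integer(0), topic = integer(0),
                      run_id = integer(0), run_len = integer(0),
                      stable = logical(0)))
  }
  new_run <- c(TRUE, diff(epoch_index) != 1L | diff(labels) != 0L)
  run_id <- cumsum(new_run)
  run_len <- ave(run_id, run_id, FUN = length)
  data.frame(epoch = epoch_index, topic = labels, run_id = run_id,
             run_len = as.integer(run_len), stable = run_len >= min_run)
}

#' Dominance and normalized co-occurrence of stable epochs
#'
#' For every stable epoch: the dominant topic's probability (*dominance*)
#' and the probabilities of the remaining topics renormalized to sum to 1
#' (*co-occurrence*). In the measure-zero case of dominance exactly 1 the
#' co-occurrence is defined as uniform over the other topics.
#'
#' @param diagram A [build_topic_diagram()] result.
#' @param labeling A [find_stable_epochs()] result for the same night.
#' @return Data frame with one row per stable epoch: `epoch`,
#'   `stable_type` (dominant topic, `"T1".."TK"`), `dominance`, and
#'   `cooc_T1..cooc_TK` (the dominant topic's own column is `NA`).
#' @export
dominance_and_cooccurrence <- function(diagram, labeling) {
  th <- theta_matrix(diagram)
  if (!identical(as.integer(diagram$epoch), as.integer(labeling$epoch))) {
    stop("labeling does not match the diagram", call. = FALSE)
  }
  K <- ncol(th)
  sel <- which(labeling$stable)
  dom <- labeling$topic[sel]
  thsel <- th[sel, , drop = FALSE]
  dval <- thsel[cbind(seq_along(sel), dom)]
  cooc <- thsel / (1 - dval)
  unif <- which(dval >= 1)
  if (length(unif)) cooc[unif, ] <- 1 / (K - 1)
  cooc[cbind(seq_along(sel), dom)] <- NA_real_
  colnames(cooc) <- paste0("cooc_T", seq_len(K))
  out <- data.frame(epoch = labeling$epoch[sel],
                    stable_type = paste0("T", dom),
                    dominance = dval, cooc, check.names = FALSE)
  rownames(out) <- NULL
  out
}

#' Stable-epoch transition probabilities
#'
#' Counts one transition for each stable epoch that has an immediate
#' successor in the same kept segment, from its dominant topic (source) to
#' the successor's dominant topic (destination); transitions never cross
#' artifact gaps. Row `i` is normalized by the number of stable-`i` epochs
#' with a successor, so rows with nonzero denominator sum to 1 (the
#' diagonal holds the continuation probability). Rows with denominator 0
#' are `NA` (undefined, to be excluded from group statistics).
#'
#' @param labeling A [find_stable_epochs()] result.
#' @param K Number of topics.
#' @return An object of class `transition_table`: list with `counts`
#'   (K x K integer), `probabilities` (K x K), `denominators` (per source).
#' @export
transition_probabilities <- function(labeling, K = 6L) {
  n <- nrow(labeling)
  counts <- matrix(0L, K, K,
                   dimnames = list(paste0("T", 1:K), paste0("T", 1:K)))
  if (n > 1L) {
    has_succ <- c(diff(labeling$epoch) == 1L, FALSE)
    src_rows <- which(labeling$stable & has_succ)
    if (length(src_rows)) {
      src <- labeling$topic[src_rows]
      dst <- labeling$topic[src_rows + 1L]
      for (i in seq_along(src)) counts[src[i], dst[i]] <- counts[src[i], dst[i]] + 1L
    }
  }
  denom <- rowSums(counts)
  probs <- counts / ifelse(denom > 0, denom, NA_real_)
  structure(list(counts = counts, probabilities = probs, denominators = denom),
            class = "transition_table")
}

#' Overall mean topic probabilities of a night
#'
#' @param diagram A [build_topic_diagram()] result.
#' @return Named numeric vector (mean mixture over kept epochs; sums to 1).
#' @export
overall_topic_means <- function(diagram) {
  th <- theta_matrix(diagram)
  if (!nrow(th)) stop("no kept epochs", call. = FALSE)
  colMeans(th)
}

#' Percentage of time in stable epochs
#'
#' Percentages of kept epochs that are stable, per dominant topic and in
#' total. Topics with no stable epochs in the night are reported as
#' missing (`NA`), matching the convention of summarizing stable-epoch
#' types only over participants expressing them.
#'
#' @param labeling A [find_stable_epochs()] result.
#' @param K Number of topics.
#' @return List with `by_topic` (named percentages, `NA` where the type is
#'   absent), `total`, and `n_kept`.
#' @export
stable_time_percentages <- function(labeling, K = 6L) {
  n <- nrow(labeling)
  by_topic <- vapply(seq_len(K), function(t) {
    cnt <- sum(labeling$stable & labeling$topic == t)
    if (cnt == 0L) NA_real_ else 100 * cnt / n
  }, numeric(1))
  names(by_topic) <- paste0("T", seq_len(K))
  list(by_topic = by_topic,
       total = 100 * sum(labeling$stable) / max(n, 1L),
       n_kept = n)
}
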