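#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive is
#' scored above a random negative, counting ties as 1/2. Equivalent to
#' exhaustive enumeration of all positive-negative pairs.
#'
#' @param scores numeric scores (any monotone scale; logits or
#'   probabilities).
#' @param labels 0/1 vector; both classes must be present.
#' @return scalar in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  check_metric_input(scores, labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("auroc needs at least one positive and one negative", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Area under the precision-recall curve
#'
#' Step-wise average-precision summation over descending unique score
#' thresholds: `sum_k (R_k - R_{k-1}) * P_k` where `P_k`, `R_k` are the
#' precision and recall when everything scored at or above the k-th unique
#' score is called positive.
#'
#' @inheritParams auroc
#' @return scalar in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  check_metric_input(scores, labels)
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stop("auprc needs at least one positive", call. = FALSE)
  thr <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  tp <- 0; called <- 0
  for (t in thr) {
    at <- scores == t
    tp <- tp + sum(labels[at] == 1)
    called <- called + sum(at)
    recall <- tp / n_pos
    precision <- tp / called
    area <- area + (recall - prev_recall) * precision
    prev_recall <- recall
  }
  area
}

check_metric_input <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels differ in length", call. = FALSE)
  if (!all(labels %in% c(0, 1)))
    stop("labels must be 0 or 1", call. = FALSE)
  invisible(TRUE)
}
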