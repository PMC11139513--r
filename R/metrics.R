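#' Classification metrics report
#'
#' Computes macro-averaged F1 (unweighted mean of per-class F1, the primary
#' metric under class imbalance), support-weighted F1, AUC (binary: the
#' Mann-Whitney rank statistic; multi-class: unweighted one-vs-rest mean)
#' and, for binary tasks, sensitivity at 99% specificity.
#'
#' @param labels true labels (integer codes or factor)
#' @param predictions predicted labels, same coding
#' @param scores matrix of class probabilities (samples x classes); may be
#'   NULL to skip score-based metrics
#' @return tibble with one row: `macro_f1`, `weighted_f1`, `auc`,
#'   `sensitivity_at_spec99`
#' @export
compute_metrics <- function(labels, predictions, scores = NULL) {
  if (is.factor(labels)) {
    lev <- levels(labels)
    labels <- as.character(labels); predictions <- as.character(predictions)
  } else {
    lev <- sort(unique(labels))
  }
  if (length(lev) < 2L && !is.null(scores))
    stop("AUC undefined for single-class labels")
  f1 <- vapply(lev, function(k) {
    tp <- sum(labels == k & predictions == k)
    fp <- sum(labels != k & predictions == k)
    fn <- sum(labels == k & predictions != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 0)
  support <- vapply(lev, function(k) sum(labels == k), 0)
  auc <- NA_real_; sens99 <- NA_real_
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    auc <- mean(vapply(seq_along(lev), function(j)
      binary_auc(scores[, j], labels == lev[j]), 0))
    if (length(lev) == 2L)
      sens99 <- sensitivity_at_specificity(scores[, 2L], labels == lev[2L])
  }
  tibble::tibble(macro_f1 = mean(f1),
                 weighted_f1 = sum(f1 * support) / sum(support),
                 auc = auc, sensitivity_at_spec99 = sens99)
}

# Mann-Whitney rank-statistic AUC
binary_auc <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Sensitivity at a fixed specificity
#'
#' Finds the smallest score threshold at which specificity on the negatives
#' reaches at least `spec` (samples scoring at or above the threshold are
#' called positive) and returns the sensitivity there. This is the
#' screening operating point: the recall achievable while mis-calling at
#' most `1 - spec` of the negatives.
#'
#' @param scores numeric scores, larger meaning more positive
#' @param labels logical or 0/1 vector of true positives
#' @param spec target specificity (default 0.99)
#' @return sensitivity in \[0, 1\]
#' @export
sensitivity_at_specificity <- function(scores, labels, spec = 0.99) {
  labels <- as.logical(labels)
  stopifnot(any(labels), any(!labels))
  neg <- scores[!labels]; pos <- scores[labels]
  if (length(neg) < 1 / (1 - spec))
    warning(sprintf(
      "only %d negatives; the %.0f%% specificity threshold is degenerate",
      length(neg), 100 * spec), call. = FALSE)
  for (t in c(sort(unique(scores)), Inf)) {
    if (mean(neg < t) >= spec) return(mean(pos >= t))
  }
  0
}
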