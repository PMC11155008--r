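#' Map RECIST categories to the binary response label
#'
#' Complete response (CR) and partial response (PR) are "responsive";
#' stable disease (SD) and progressive disease (PD) are "nonresponsive".
#'
#' @param category Character vector of RECIST categories.
#' @return Character vector of `"responsive"` / `"nonresponsive"`.
#' @examples
#' map_recist(c("CR", "PR", "SD", "PD"))
#' @export
map_recist <- function(category) {
  out <- character(length(category))
  ok <- category %in% c("CR", "PR", "SD", "PD")
  if (!all(ok)) {
    stop(sprintf("unknown RECIST category: '%s'", category[!ok][1L]),
         call. = FALSE)
  }
  ifelse(category %in% c("CR", "PR"), "responsive", "nonresponsive")
}

check_scored <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  y <- as.integer(labels)
  if (!all(y %in% c(0L, 1L))) {
    stop("labels must be 0/1", call. = FALSE)
  }
  y
}

#' Area under the ROC curve
#'
#' Trapezoidal AUC over all score thresholds, computed via the rank
#' (Mann-Whitney) identity, so tied scores contribute 1/2. Equal to the
#' probability that a random positive is scored above a random negative,
#' plus half the tie probability.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels (1 = positive); both classes must be present.
#' @return AUC in [0, 1].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels) {
  y <- check_scored(scores, labels)
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("both classes must be present to compute AUC", call. = FALSE)
  }
  r <- rank(scores)  # average ranks handle ties as 1/2
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' ROC curve points
#'
#' False/true positive rates at every distinct score threshold
#' (predict positive iff score >= threshold), for export or plotting.
#'
#' @inheritParams roc_auc
#' @return Data frame with `threshold`, `fpr`, `tpr`.
#' @export
roc_curve <- function(scores, labels) {
  y <- check_scored(scores, labels)
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  out <- lapply(th, function(t) {
    pred <- scores >= t
    data.frame(threshold = t,
               fpr = sum(pred & y == 0L) / max(sum(y == 0L), 1L),
               tpr = sum(pred & y == 1L) / max(sum(y == 1L), 1L))
  })
  do.call(rbind, out)
}

#' Stratified percentile bootstrap CI for the AUC
#'
#' Resamples patients with replacement within each class (so every
#' replicate retains both classes) and returns the percentile interval of
#' the bootstrap AUC distribution. Deterministic given `seed`.
#'
#' @inheritParams roc_auc
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named numeric `c(lower, upper)`.
#' @export
bootstrap_auc_ci <- function(scores, labels, n_boot = 2000, level = 0.95,
                             seed = 1) {
  y <- check_scored(scores, labels)
  pos <- which(y == 1L); neg <- which(y == 0L)
  if (!length(pos) || !length(neg)) {
    stop("both classes must be present", call. = FALSE)
  }
  aucs <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ix <- c(sample(pos, length(pos), replace = TRUE),
              sample(neg, length(neg), replace = TRUE))
      roc_auc(scores[ix], y[ix])
    }, 1)
  })
  alpha <- (1 - level) / 2
  q <- stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7)
  c(lower = q[1L], upper = q[2L])
}

#' Confusion matrix and threshold metrics
#'
#' Predicts positive iff `score >= threshold` and reports accuracy,
#' recall (sensitivity, on the positive class) and specificity (on the
#' negative class), plus the 2x2 confusion matrix. These satisfy
#' `accuracy = (recall * n_pos + specificity * n_neg) / n` exactly.
#'
#' @inheritParams roc_auc
#' @param threshold Decision threshold on the positive-class score.
#' @return List with `confusion` (2x2 integer matrix, rows = truth,
#'   columns = prediction), `accuracy`, `recall`, `specificity`,
#'   `threshold`.
#' @export
confusion_and_rates <- function(scores, labels, threshold = 0.5) {
  y <- check_scored(scores, labels)
  if (!length(y)) stop("no samples", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L); tn <- sum(pred == 0L & y == 0L)
  fp <- sum(pred == 1L & y == 0L); fn <- sum(pred == 0L & y == 1L)
  conf <- matrix(c(tn, fp, fn, tp), 2L, 2L, byrow = TRUE,
                 dimnames = list(truth = c("negative", "positive"),
                                 predicted = c("negative", "positive")))
  list(
    confusion = conf,
    accuracy = (tp + tn) / length(y),
    recall = if (tp + fn > 0L) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0L) tn / (tn + fp) else NA_real_,
    threshold = threshold
  )
}

#' Full metrics report for a scored cohort
#'
#' Bundles the threshold metrics, AUC, and its bootstrap interval into
#' one report, the per-model evaluation surface used throughout the
#' experiments. The positive class is configurable (default
#' `"responsive"`); labels may be 0/1 or the label strings.
#'
#' @param scores Positive-class probabilities.
#' @param labels 0/1 or `"responsive"`/`"nonresponsive"`.
#' @param positive Which label value counts as positive when `labels` is
#'   character.
#' @param threshold Decision threshold.
#' @param n_boot,level,seed Passed to [bootstrap_auc_ci()]; `n_boot = 0`
#'   skips the interval.
#' @return A `metrics_report` list: `accuracy`, `recall`, `specificity`,
#'   `auc`, `auc_ci`, `confusion`, `threshold`, `n`.
#' @export
metrics_report <- function(scores, labels, positive = "responsive",
                           threshold = 0.5, n_boot = 2000, level = 0.95,
                           seed = 1) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.integer(as.character(labels) == positive)
  }
  rates <- confusion_and_rates(scores, labels, threshold)
  auc <- roc_auc(scores, labels)
  ci <- if (n_boot > 0L) {
    bootstrap_auc_ci(scores, labels, n_boot = n_boot, level = level,
                     seed = seed)
  } else {
    c(lower = NA_real_, upper = NA_real_)
  }
  structure(
    c(rates[c("accuracy", "recall", "specificity")],
      list(auc = auc, auc_ci = ci, confusion = rates$confusion,
           threshold = threshold, n = length(labels))),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d  Acc %.3f  AUC %.3f (95%% CI %.2f-%.2f)  Spe %.3f  Recall %.3f\n",
    x$n, x$accuracy, x$auc, x$auc_ci[1L], x$auc_ci[2L],
    x$specificity, x$recall
  ))
  invisible(x)
}
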