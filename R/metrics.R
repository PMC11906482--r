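# Ranking metrics used throughout: ROC-AUC, PR-AUC, TOPk%-PPV, Pearson r.

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney probability
#' `P(score_pos > score_neg) + 0.5 * P(tie)` over all positive/negative
#' pairs, via mid-ranks (exact, including ties).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Numeric vector, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("ROC-AUC undefined: both classes must be present", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Step-curve area traversed in descending-score order with tied scores
#' grouped: `sum over thresholds of (recall_i - recall_{i-1}) * precision_i`.
#'
#' @inheritParams roc_auc
#' @return PR-AUC in `[0, 1]`.
#' @export
pr_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  P <- sum(labels == 1)
  if (P == 0) stop("PR-AUC undefined without positive labels", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  tp <- cumsum(lab)
  n <- seq_along(lab)
  keep <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie group
  tp <- tp[keep]; n <- n[keep]
  precision <- tp / n
  recall <- tp / P
  sum(diff(c(0, recall)) * precision)
}

#' Positive predictive value among the top k fraction
#'
#' Ranks by score descending (ties resolved by stable input order), takes the
#' top `ceiling(k * N)` entries and returns the fraction labelled 1.
#'
#' @inheritParams roc_auc
#' @param k Fraction in (0, 1]; default 0.20 (the TOP20%-PPV).
#' @return PPV in `[0, 1]`.
#' @export
top_k_ppv <- function(labels, scores, k = 0.20) {
  stopifnot(length(labels) == length(scores))
  if (length(labels) == 0) stop("empty input", call. = FALSE)
  if (!(k > 0 && k <= 1)) stop("k must be in (0, 1]", call. = FALSE)
  m <- ceiling(k * length(labels))
  top <- order(scores, decreasing = TRUE, method = "radix")[seq_len(m)]
  mean(as.integer(labels)[top] == 1)
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length `>= 2` with nonzero variance.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 2) {
    stop("x and y must have equal length >= 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Pearson correlation undefined for zero variance", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Evaluate predictions
#'
#' Bundles the four metrics for a labelled prediction set.
#'
#' @inheritParams roc_auc
#' @param k Top-fraction for [top_k_ppv()].
#' @return List of class `eval_result`: `pr_auc`, `roc_auc`, `top_k_ppv`,
#'   `pearson_r`, `n_pos`, `n_neg`, `k`.
#' @export
evaluate_predictions <- function(labels, scores, k = 0.20) {
  labels <- as.integer(labels)
  structure(list(
    pr_auc = pr_auc(labels, scores),
    roc_auc = roc_auc(labels, scores),
    top_k_ppv = top_k_ppv(labels, scores, k),
    pearson_r = if (stats::sd(labels) > 0 && stats::sd(scores) > 0)
      pearson_r(labels, scores) else NA_real_,
    n_pos = sum(labels == 1), n_neg = sum(labels == 0), k = k
  ), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf(paste0("PR-AUC %.4f | ROC-AUC %.4f | TOP%d%%-PPV %.4f | ",
                     "r %.4f (n+ %d, n- %d)\n"),
              x$pr_auc, x$roc_auc, round(100 * x$k), x$top_k_ppv,
              x$pearson_r, x$n_pos, x$n_neg))
  invisible(x)
}
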