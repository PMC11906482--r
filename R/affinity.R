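# IC50 <-> score transform and threshold labelling.
#
# Regression targets are score = 1 - ln(IC50)/ln(50000), so IC50 = 1 nM maps
# to 1, IC50 = 50000 nM maps to 0, and the classification threshold of
# 500 nM maps to about 0.426. Scores outside [0,1] (IC50 outside
# [1, 50000] nM) are retained, not clipped: the transform is unbounded and
# clipping would bias the mean-squared-error target.

#' Transform IC50 (nM) to a binding score
#'
#' `score = 1 - ln(IC50) / ln(50000)`. Strictly decreasing in IC50;
#' 1 nM maps to 1 and 50000 nM to 0.
#'
#' @param ic50 Numeric vector of IC50 values in nM, all `> 0`.
#' @return Numeric vector of scores (unclipped).
#' @export
#' @examples
#' ic50_to_score(c(1, 500, 50000))
ic50_to_score <- function(ic50) {
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be finite and > 0 nM", call. = FALSE)
  }
  1 - log(ic50) / log(50000)
}

#' Inverse of [ic50_to_score()]
#'
#' @param score Numeric vector of binding scores (any real value).
#' @return IC50 in nM: `50000^(1 - score)`.
#' @export
score_to_ic50 <- function(score) {
  if (!is.numeric(score) || any(!is.finite(score))) {
    stop("scores must be finite", call. = FALSE)
  }
  50000^(1 - score)
}

#' Binarise IC50 values at a threshold
#'
#' Label 1 (binder) iff `IC50 < threshold`; IC50 at or above the threshold is
#' labelled 0. The default 500 nM is the conventional class-I binder cutoff.
#'
#' @inheritParams ic50_to_score
#' @param threshold Positive IC50 cutoff in nM (default 500).
#' @return Integer vector of 0/1 labels.
#' @export
label_by_threshold <- function(ic50, threshold = 500) {
  if (!is.numeric(ic50) || any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 values must be finite and > 0 nM", call. = FALSE)
  }
  as.integer(ic50 < threshold)
}

#' Read a binding-affinity table
#'
#' TSV with columns `peptide`, `allele`, `ic50_nM`; `#` comment lines and
#' blank lines are ignored. Adds the transformed `score` column.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns peptide, allele, ic50_nM, score.
#' @export
read_ba_table <- function(path) {
  df <- read_table(path, schema = "ba")
  df$score <- ic50_to_score(df$ic50_nM)
  df
}
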