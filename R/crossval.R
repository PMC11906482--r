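# K-fold cross-validated training and fold-averaged ensemble prediction.

#' Assign records to k folds
#'
#' Random balanced assignment (fold sizes differ by at most one),
#' deterministic for a fixed seed. If `records` is a data.frame with a
#' `fold` column containing no missing values, that assignment is returned
#' verbatim (pass-through mode, so published splits are respected).
#'
#' @param records Data.frame of records, or an integer count.
#' @param k Number of folds (default 5).
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`.
#' @export
kfold_split <- function(records, k = 5, seed = 1L) {
  n <- if (is.data.frame(records)) nrow(records) else as.integer(records)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  if (n < k) stop("need at least k records", call. = FALSE)
  if (is.data.frame(records) && "fold" %in% names(records) &&
      !anyNA(records$fold)) {
    return(as.integer(records$fold))
  }
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

#' Train a fold-averaged network ensemble
#'
#' Splits the records into `k` folds, trains one network per fold on the
#' remaining data (the held-out fold serves as validation; parameters with
#' the minimum held-out loss are kept), and returns the ensemble whose
#' prediction is the arithmetic mean of the member predictions.
#'
#' @param records Data.frame with columns `peptide`, `allele`, and the target
#'   (`score` for regression, `label` for classification); an optional `fold`
#'   column is respected.
#' @param pseudo_table Named character vector from [read_pseudo_table()].
#' @param config A [model_config()].
#' @param k Number of folds (default 5).
#' @param verbose Print training progress.
#' @return Object of class `fold_ensemble`.
#' @export
fit_fold_ensemble <- function(records, pseudo_table, config, k = 5,
                              verbose = FALSE) {
  target_col <- if (config$task == "regression") "score" else "label"
  if (!target_col %in% names(records)) {
    stop(sprintf("records must have a '%s' column for task '%s'",
                 target_col, config$task), call. = FALSE)
  }
  fold <- kfold_split(records, k = k, seed = config$seed)
  enc <- encode_dataset(records$peptide, records$allele, pseudo_table,
                        config$max_pep_len)
  y <- as.numeric(records[[target_col]])
  members <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- which(fold != f)
    va <- which(fold == f)
    sub <- function(rows) list(idx = enc$idx[rows, , drop = FALSE],
                               blosum = enc$blosum[rows, , drop = FALSE],
                               y = y[rows], pseudo_len = enc$pseudo_len)
    cfg_f <- config
    cfg_f$seed <- config$seed + f
    members[[f]] <- train_network(sub(tr), cfg_f, val = sub(va),
                                  verbose = verbose)
    if (verbose) message(sprintf("fold %d/%d done (best val loss %.5f)",
                                 f, k, min(members[[f]]$history$val_loss,
                                           na.rm = TRUE)))
  }
  structure(list(members = members, k = k, config = config,
                 fold_assignment = fold, seed = config$seed,
                 fusion_dim = members[[1]]$fusion_dim),
            class = "fold_ensemble")
}

#' Ensemble prediction for peptide/allele pairs
#'
#' The ensemble score is the exact arithmetic mean of the member networks'
#' outputs (probabilities for classification, scores for regression).
#'
#' @param ensemble A `fold_ensemble` from [fit_fold_ensemble()].
#' @param peptide,allele Character vectors of equal length.
#' @param pseudo_table Named character vector of pseudo-sequences.
#' @param per_member Return the member-level score matrix as an attribute.
#' @return Numeric vector of ensemble scores.
#' @export
ensemble_predict <- function(ensemble, peptide, allele, pseudo_table,
                             per_member = FALSE) {
  stopifnot(inherits(ensemble, "fold_ensemble"),
            length(peptide) == length(allele))
  tasks <- vapply(ensemble$members, function(m) m$config$task, character(1))
  if (length(unique(tasks)) != 1) {
    stop("ensemble members disagree on task", call. = FALSE)
  }
  enc <- encode_dataset(peptide, allele, pseudo_table,
                        ensemble$config$max_pep_len)
  mat <- vapply(ensemble$members, function(m) predict_network(m, enc),
                numeric(length(peptide)))
  if (length(peptide) == 1L) mat <- matrix(mat, nrow = 1)
  out <- rowMeans(mat)
  if (per_member) attr(out, "members") <- mat
  out
}

#' Save / load a trained ensemble checkpoint
#'
#' Single-file archive holding every member's parameters plus the
#' configuration used; the format is versioned.
#'
#' @param ensemble A `fold_ensemble`.
#' @param path File path.
#' @export
save_checkpoint <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "fold_ensemble"))
  saveRDS(list(format = "mhcbind-checkpoint", version = 1L,
               ensemble = ensemble), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the `fold_ensemble`.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "mhcbind-checkpoint")) {
    stop("not a mhcbind checkpoint: ", path, call. = FALSE)
  }
  obj$ensemble
}
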