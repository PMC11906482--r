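# Semi-supervised curation of eluted-ligand data: pre-train a regressor on
# binding-affinity data, use it to (a) assign each multi-allele eluted
# peptide to the allele with the highest predicted score and (b) remove
# sampled decoy negatives that the model scores as binders, then merge
# everything into one classification training table.

#' Assign multi-allele eluted peptides to single alleles
#'
#' For each positive sample, predicts the ensemble score for the peptide
#' against every candidate allele and assigns the argmax; ties break
#' lexicographically by allele name. Single-candidate samples keep their
#' allele without consulting the model.
#'
#' @param el Data.frame with `peptide`, `alleles` (list column of candidate
#'   allele names), `label` (only label-1 rows are deconvolved).
#' @param model A `fold_ensemble` (regression pre-trained), or any function
#'   `f(peptide, allele)` returning scores (used by tests).
#' @param pseudo_table Named character vector of pseudo-sequences; every
#'   candidate allele must be present.
#' @return The data.frame with an `assigned_allele` column; for label-1 rows
#'   the candidate set is collapsed to the winner.
#' @export
deconvolve_multi_allele <- function(el, model, pseudo_table) {
  cands <- unique(unlist(el$alleles))
  missing <- setdiff(cands, names(pseudo_table))
  if (length(missing)) {
    stop("candidate allele(s) missing from pseudo-sequence table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (any(lengths(el$alleles) < 1)) {
    stop("every sample needs a non-empty candidate-allele set", call. = FALSE)
  }
  scorer <- if (is.function(model)) model else
    function(pep, al) ensemble_predict(model, pep, al, pseudo_table)
  el$assigned_allele <- vapply(el$alleles, `[[`, character(1), 1)
  todo <- which(el$label == 1 & lengths(el$alleles) > 1)
  if (length(todo)) {
    # score every needed (peptide, candidate) pair in one batch
    pep <- rep(el$peptide[todo], lengths(el$alleles[todo]))
    al <- unlist(el$alleles[todo])
    sc <- scorer(pep, al)
    grp <- rep(seq_along(todo), lengths(el$alleles[todo]))
    for (g in seq_along(todo)) {
      rows <- which(grp == g)
      cand <- al[rows]
      s <- sc[rows]
      best <- cand[s == max(s)]
      el$assigned_allele[todo[g]] <- min(best)  # lexicographic tie-break
    }
    el$alleles[todo] <- as.list(el$assigned_allele[todo])
  }
  el
}

#' Remove implausible sampled negatives
#'
#' Scores every label-0 sample against its (assigned or single) allele and
#' moves those with ensemble score `>= score_threshold` to `removed`.
#' Positives are never removed. The default threshold is the IC50-score of
#' 500 nM — decoys the model already considers binders at the conventional
#' positivity cutoff.
#'
#' @inheritParams deconvolve_multi_allele
#' @param score_threshold Finite score cutoff (default
#'   `ic50_to_score(500)`, about 0.426).
#' @return List `kept`, `removed`, `report` (counts and threshold used).
#' @export
filter_negatives <- function(el, model, pseudo_table,
                             score_threshold = ic50_to_score(500)) {
  if (!is.finite(score_threshold)) stop("threshold must be finite", call. = FALSE)
  scorer <- if (is.function(model)) model else
    function(pep, al) ensemble_predict(model, pep, al, pseudo_table)
  allele1 <- if ("assigned_allele" %in% names(el)) el$assigned_allele else
    vapply(el$alleles, `[[`, character(1), 1)
  neg <- which(el$label == 0)
  drop <- integer(0)
  if (length(neg)) {
    sc <- scorer(el$peptide[neg], allele1[neg])
    drop <- neg[sc >= score_threshold]
  }
  report <- list(n_input = nrow(el),
                 n_negatives = length(neg),
                 n_negatives_removed = length(drop),
                 score_threshold = score_threshold)
  list(kept = el[setdiff(seq_len(nrow(el)), drop), , drop = FALSE],
       removed = el[drop, , drop = FALSE],
       report = report)
}

#' Merge BA and eluted-ligand datasets into one classification table
#'
#' BA samples are labelled by the 500 nM rule; all EL samples must already
#' be single-allele. One record per (peptide, allele): exact duplicates
#' (same label) collapse with provenance union; label conflicts keep the
#' eluted-ligand positive and are logged in the report. Pre-existing `fold`
#' columns are preserved.
#'
#' @param ba Data.frame `peptide`, `allele`, `ic50_nM` (optional `fold`).
#' @param els_sa,els_ma_deconv Data.frames with `peptide`, `label` and a
#'   single allele per row (`alleles` list column or `assigned_allele`).
#' @param ic50_threshold Labelling cutoff for BA rows (nM, default 500).
#' @return List `table` (columns peptide, allele, label, provenance, fold)
#'   and `report` (n_conflicts, per-source counts).
#' @export
merge_datasets <- function(ba, els_sa = NULL, els_ma_deconv = NULL,
                           ic50_threshold = 500) {
  as_records <- function(el, prov) {
    if (is.null(el) || nrow(el) == 0) return(NULL)
    allele <- if ("assigned_allele" %in% names(el)) el$assigned_allele else
      vapply(el$alleles, function(a) {
        if (length(a) != 1) {
          stop("EL samples must be single-allele before merging",
               call. = FALSE)
        }
        a[[1]]
      }, character(1))
    data.frame(peptide = el$peptide, allele = allele,
               label = as.integer(el$label), provenance = prov,
               fold = if ("fold" %in% names(el)) el$fold else NA_integer_,
               stringsAsFactors = FALSE)
  }
  recs <- list()
  if (!is.null(ba) && nrow(ba) > 0) {
    recs$ba <- data.frame(peptide = ba$peptide, allele = ba$allele,
                          label = label_by_threshold(ba$ic50_nM,
                                                     ic50_threshold),
                          provenance = "BA",
                          fold = if ("fold" %in% names(ba)) ba$fold else
                            NA_integer_,
                          stringsAsFactors = FALSE)
  }
  recs$sa <- as_records(els_sa, "ELS_SA")
  recs$ma <- as_records(els_ma_deconv, "ELS_MA")
  all <- do.call(rbind, unname(recs))
  if (is.null(all) || nrow(all) == 0) {
    stop("nothing to merge", call. = FALSE)
  }
  key <- paste(all$peptide, all$allele, sep = "\r")
  n_conflicts <- 0L
  out <- lapply(split(seq_len(nrow(all)), key), function(rows) {
    r <- all[rows, , drop = FALSE]
    lab <- unique(r$label)
    if (length(lab) > 1) {
      # eluted-ligand positive wins over a BA negative
      lab <- 1L
      n_conflicts <<- n_conflicts + 1L
    }
    data.frame(peptide = r$peptide[1], allele = r$allele[1], label = lab,
               provenance = paste(sort(unique(r$provenance)), collapse = ","),
               fold = if (all(is.na(r$fold))) NA_integer_ else
                 min(r$fold, na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # keep first-appearance order
  out <- out[order(match(paste(out$peptide, out$allele, sep = "\r"), key)), ]
  rownames(out) <- NULL
  list(table = out,
       report = list(n_input = nrow(all), n_output = nrow(out),
                     n_conflicts = n_conflicts))
}

#' Run the full curation pipeline
#'
#' Pre-trains a regression ensemble on the BA data, deconvolves multi-allele
#' eluted ligands, filters implausible decoy negatives, and merges all
#' sources into a classification training table. With `rounds > 1` the
#' regressor is re-fitted by self-training (BA true scores plus EL samples
#' with pseudo-targets from the previous round's ensemble) and the
#' deconvolution/filtering steps are repeated.
#'
#' @param ba Data.frame `peptide`, `allele`, `ic50_nM`.
#' @param els_sa,els_ma Eluted-ligand data.frames (`peptide`, `alleles` list
#'   column, `label`); may be `NULL` or empty.
#' @param pseudo_table Named character vector of pseudo-sequences.
#' @param config A [model_config()] (task is forced to regression for the
#'   pre-training stage).
#' @param score_threshold Negative-filter cutoff (default
#'   `ic50_to_score(500)`).
#' @param rounds Number of curation rounds (default 1).
#' @param k Folds for the pre-training ensemble (default 5).
#' @param verbose Print progress.
#' @return List `table` (merged training table), `report` (curation report),
#'   `model` (the final regression ensemble).
#' @export
run_curation <- function(ba, els_sa = NULL, els_ma = NULL, pseudo_table,
                         config, score_threshold = ic50_to_score(500),
                         rounds = 1L, k = 5L, verbose = FALSE) {
  if (is.null(ba) || nrow(ba) == 0) {
    stop("curation requires a non-empty BA dataset for pre-training",
         call. = FALSE)
  }
  cfg <- config
  cfg$task <- "regression"
  ba$score <- ic50_to_score(ba$ic50_nM)
  empty_el <- function(x) is.null(x) || nrow(x) == 0
  reg_train <- ba
  report <- list(rounds = rounds, seed = config$seed,
                 score_threshold = score_threshold)
  model <- NULL
  for (round in seq_len(rounds)) {
    if (verbose) message(sprintf("curation round %d/%d: fitting regressor",
                                 round, rounds))
    cfg$seed <- config$seed + 1000L * (round - 1L)
    model <- fit_fold_ensemble(reg_train, pseudo_table, cfg, k = k,
                               verbose = verbose)
    sa <- if (!empty_el(els_sa)) {
      x <- els_sa
      x$assigned_allele <- vapply(x$alleles, `[[`, character(1), 1)
      x
    }
    ma <- if (!empty_el(els_ma)) {
      deconvolve_multi_allele(els_ma, model, pseudo_table)
    }
    filt <- function(x) {
      if (is.null(x)) return(list(kept = NULL, removed = NULL,
                                  report = list(n_negatives_removed = 0L)))
      filter_negatives(x, model, pseudo_table, score_threshold)
    }
    fsa <- filt(sa)
    fma <- filt(ma)
    if (round < rounds) {
      # self-training targets for the next regression round
      pseudo_rows <- rbind(fsa$kept, fma$kept)
      if (!is.null(pseudo_rows) && nrow(pseudo_rows)) {
        al <- if ("assigned_allele" %in% names(pseudo_rows)) {
          pseudo_rows$assigned_allele
        } else {
          vapply(pseudo_rows$alleles, `[[`, character(1), 1)
        }
        pred <- ensemble_predict(model, pseudo_rows$peptide, al, pseudo_table)
        reg_train <- rbind(
          ba[, c("peptide", "allele", "score")],
          data.frame(peptide = pseudo_rows$peptide, allele = al,
                     score = pred, stringsAsFactors = FALSE))
      }
    }
  }
  merged <- merge_datasets(ba, fsa$kept, fma$kept)
  report$n_ma_deconvolved <- if (is.null(ma)) 0L else
    sum(ma$label == 1 & lengths(els_ma$alleles) > 1)
  report$n_negatives_removed <- fsa$report$n_negatives_removed +
    fma$report$n_negatives_removed
  report$n_conflicts <- merged$report$n_conflicts
  report$n_output <- nrow(merged$table)
  if (!is.null(ma)) {
    tab <- table(ma$assigned_allele[ma$label == 1])
    report$per_allele_assignments <- as.list(stats::setNames(as.integer(tab),
                                                             names(tab)))
  }
  list(table = merged$table, report = report, model = model)
}
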