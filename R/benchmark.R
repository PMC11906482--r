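# End-to-end synthetic benchmark: generates a world with planted anchor
# motifs, runs the full curation + 5-fold training pipeline, and evaluates
# recovery on held-out data. This is the package's offline stand-in for the
# published large-scale benchmarks, which require external datasets and
# GPU-scale training.

#' Run the end-to-end synthetic benchmark
#'
#' Builds a 2-allele world (20,000 binding-affinity rows plus 5,000
#' eluted-ligand rows by default), runs curation (regression pre-training,
#' multi-allele deconvolution, decoy filtering, merging) and 5-fold
#' classification training, then evaluates on fresh held-out data. Also
#' trains a reduced permuted-label control (the no-signal baseline) and
#' measures multi-allele deconvolution recovery in a separate 3-allele
#' world against the generator's hidden truth.
#'
#' @param seed Integer seed driving every stage.
#' @param n_ba Binding-affinity training rows.
#' @param n_el_pos,n_el_neg Eluted-ligand positives/decoys per table (one
#'   single-allele and one multi-allele table are generated).
#' @param n_test Held-out evaluation rows.
#' @param n_ba_deconv,n_el_deconv Sizes for the 3-allele deconvolution
#'   world.
#' @param config Classification [model_config()]; default [tiny_config()].
#' @param pretrain_k,k Folds for the pre-training and classification
#'   ensembles.
#' @param control Also train the permuted-label control (logical).
#' @param deconv Also run the 3-allele deconvolution recovery (logical).
#' @param verbose Print stage progress.
#' @return List with `eval` (an `eval_result` on held-out data),
#'   `pearson_r_ba` (regression recovery of held-out IC50 scores),
#'   `control_roc_auc`, `deconv_recovery`, `curation_report`, `ensemble`,
#'   and the training `table`.
#' @export
synthetic_benchmark <- function(seed = 1L, n_ba = 20000L, n_el_pos = 1250L,
                                n_el_neg = 1250L, n_test = 4000L,
                                n_ba_deconv = 12000L, n_el_deconv = 1500L,
                                config = NULL, pretrain_k = 2L, k = 5L,
                                control = TRUE, deconv = TRUE,
                                verbose = FALSE) {
  seed <- as.integer(seed)
  say <- function(...) if (verbose) message(sprintf(...))
  world <- make_world(2L, seed = seed + 100L)
  ba <- sample_ba(world, n_ba, seed = seed + 110L)
  sa <- sample_el(world, n_el_pos, n_el_neg, multi_allele = FALSE,
                  seed = seed + 120L)
  ma <- sample_el(world, n_el_pos, n_el_neg, multi_allele = TRUE,
                  seed = seed + 130L)
  pseudo <- world$pseudo

  say("curation (pre-train %d-fold regressor on %d BA rows)", pretrain_k, n_ba)
  cfg_reg <- if (is.null(config)) tiny_config(task = "regression",
                                              seed = seed) else {
    cr <- config; cr$task <- "regression"; cr$seed <- seed; cr
  }
  cur <- run_curation(ba, sa$data, ma$data, pseudo, cfg_reg,
                      k = pretrain_k, verbose = verbose)

  say("5-fold classification on %d curated rows", nrow(cur$table))
  cfg_cls <- if (is.null(config)) tiny_config(task = "classification",
                                              seed = seed + 1L,
                                              batch_size = 384) else {
    cc <- config; cc$task <- "classification"; cc$seed <- seed + 1L; cc
  }
  ens <- fit_fold_ensemble(cur$table, pseudo, cfg_cls, k = k,
                           verbose = verbose)

  test_ba <- sample_ba(world, n_test, seed = seed + 210L)
  labels <- label_by_threshold(test_ba$ic50_nM)
  pred <- ensemble_predict(ens, test_ba$peptide, test_ba$allele, pseudo)
  ev <- evaluate_predictions(labels, pred)
  reg_pred <- ensemble_predict(cur$model, test_ba$peptide, test_ba$allele,
                               pseudo)
  r_ba <- pearson_r(reg_pred, ic50_to_score(test_ba$ic50_nM))
  say("held-out ROC-AUC %.3f PR-AUC %.3f", ev$roc_auc, ev$pr_auc)

  control_roc <- NA_real_
  if (control) {
    say("permuted-label control")
    set.seed(seed + 300L)
    ctrl <- cur$table[sample(nrow(cur$table), min(5000L, nrow(cur$table))), ]
    ctrl$label <- sample(ctrl$label)
    cfg_ctrl <- tiny_config(task = "classification", seed = seed + 301L,
                            epochs = 4, t_max = 4)
    ens_ctrl <- fit_fold_ensemble(ctrl, pseudo, cfg_ctrl, k = 2L)
    control_roc <- roc_auc(labels,
                           ensemble_predict(ens_ctrl, test_ba$peptide,
                                            test_ba$allele, pseudo))
    say("control ROC-AUC %.3f", control_roc)
  }

  recovery <- NA_real_
  if (deconv) {
    say("3-allele deconvolution recovery")
    world3 <- make_world(3L, seed = seed + 400L)
    ba3 <- sample_ba(world3, n_ba_deconv, seed = seed + 410L)
    ba3$score <- ic50_to_score(ba3$ic50_nM)
    ma3 <- sample_el(world3, n_el_deconv, 0L, multi_allele = TRUE,
                     seed = seed + 420L)
    reg3 <- fit_fold_ensemble(ba3, world3$pseudo,
                              tiny_config(task = "regression",
                                          seed = seed + 401L),
                              k = pretrain_k)
    dec <- deconvolve_multi_allele(ma3$data, reg3, world3$pseudo)
    recovery <- mean(dec$assigned_allele == ma3$truth$true_allele)
    say("recovery %.3f", recovery)
  }

  list(eval = ev, pearson_r_ba = r_ba, control_roc_auc = control_roc,
       deconv_recovery = recovery, curation_report = cur$report,
       ensemble = ens, table = cur$table, world = world,
       test = list(labels = labels, scores = pred))
}

#' Ablation study over the attention and branch toggles
#'
#' Re-trains the model with each of the three ablations (no CBAM, no
#' 1D-CNN-BiLSTM branch, no BLOSUM62 skip) on the given training table and
#' evaluates each variant on the held-out pairs, reporting the fusion-vector
#' dimensionality of every variant alongside its metrics.
#'
#' @param table Classification training table (`peptide`, `allele`,
#'   `label`).
#' @param pseudo_table Named pseudo-sequence vector.
#' @param test List with `peptide`, `allele`, `labels` for evaluation.
#' @param config Base [model_config()] (classification task).
#' @param k Folds per variant (default 2; the study compares variants, not
#'   absolute performance).
#' @return Data.frame: variant, fusion_dim, roc_auc, pr_auc.
#' @export
ablation_study <- function(table, pseudo_table, test, config, k = 2L) {
  variants <- list(
    full = list(),
    no_cbam = list(use_cbam = FALSE),
    no_1dcnn_bilstm = list(use_1dcnn_bilstm = FALSE),
    no_blosum = list(use_blosum = FALSE)
  )
  rows <- lapply(names(variants), function(nm) {
    cfg <- config
    for (f in names(variants[[nm]])) cfg[[f]] <- variants[[nm]][[f]]
    ens <- fit_fold_ensemble(table, pseudo_table, cfg, k = k)
    pred <- ensemble_predict(ens, test$peptide, test$allele, pseudo_table)
    data.frame(variant = nm, fusion_dim = ens$fusion_dim,
               roc_auc = roc_auc(test$labels, pred),
               pr_auc = pr_auc(test$labels, pred),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
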