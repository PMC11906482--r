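# Synthetic-data generator with planted, recoverable structure: each allele
# gets anchor positions (by default position 2 and the C-terminus) with
# preferred residues; matching an anchor lowers log-IC50 by a planted bonus.
# The generator emulates binding-affinity assays (IC50 tables), eluted-ligand
# mass-spectrometry experiments (positives only, sampled decoy negatives,
# optionally multi-allele candidate sets), and somatic-mutation tables.
# Hidden ground truth is returned separately (and written to sidecar files),
# never into the tables the pipeline consumes.

#' Create a synthetic peptide-MHC world
#'
#' @param n_alleles Number of alleles (`>= 1`).
#' @param peptide_length Peptide length for generated binders (default 9).
#' @param seed Integer seed; the same seed reproduces the world exactly.
#' @param n_anchors Anchor positions per allele (2 or 3; defaults to
#'   position 2 and the C-terminus, plus one random middle position if 3).
#' @param anchor_bonus Reduction of `ln(IC50)` per matched anchor; the
#'   default 4.5 makes a full match a strong binder (IC50 a few nM) and is
#'   deliberately much larger than the noise so that desk-scale models can
#'   recover the structure ("easy mode"). Set closer to `log_ic50_sd` for a
#'   hard mode.
#' @param n_pref Preferred residues per anchor.
#' @param log_ic50_sd Gaussian noise s.d. on `ln(IC50)` (default 0.4).
#' @param pseudo_len Pseudo-sequence length (default 34, class-I style).
#' @return Object of class `synthetic_world`.
#' @export
make_world <- function(n_alleles, peptide_length = 9L, seed = 1L,
                       n_anchors = 2L, anchor_bonus = 4.5, n_pref = 3L,
                       log_ic50_sd = 0.4, pseudo_len = 34L) {
  stopifnot(n_alleles >= 1, peptide_length >= 3, n_anchors %in% c(2L, 3L))
  set.seed(seed)
  alleles <- sprintf("SIM-%02d", seq_len(n_alleles))
  pseudo <- vapply(alleles, function(a)
    paste(sample(aa_alphabet, pseudo_len, replace = TRUE), collapse = ""),
    character(1))
  motifs <- lapply(alleles, function(a) {
    pos <- c(2L, peptide_length)
    if (n_anchors == 3L) pos <- sort(c(pos, sample(3:(peptide_length - 1L), 1)))
    lapply(stats::setNames(pos, pos), function(p)
      sample(aa_alphabet, n_pref))
  })
  names(motifs) <- alleles
  structure(list(alleles = alleles, pseudo = pseudo, motifs = motifs,
                 peptide_length = as.integer(peptide_length),
                 anchor_bonus = anchor_bonus, log_ic50_sd = log_ic50_sd,
                 baseline_log_ic50 = log(30000), seed = as.integer(seed)),
            class = "synthetic_world")
}

# Deterministic (noise-free) ln(IC50) for peptide/allele under the world.
.true_log_ic50 <- function(world, peptide, allele) {
  motif <- world$motifs[[allele]]
  chars <- strsplit(peptide, "")[[1]]
  bonus <- sum(vapply(names(motif), function(p)
    chars[as.integer(p)] %in% motif[[p]], logical(1))) * world$anchor_bonus
  world$baseline_log_ic50 - bonus
}

.random_peptides <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(aa_alphabet, len, replace = TRUE), collapse = ""),
    character(1))
}

# Peptide matching every anchor of an allele (non-anchor positions random).
.motif_peptide <- function(world, allele, p_match = 1) {
  chars <- sample(aa_alphabet, world$peptide_length, replace = TRUE)
  motif <- world$motifs[[allele]]
  for (p in names(motif)) {
    if (stats::runif(1) < p_match) chars[as.integer(p)] <- sample(motif[[p]], 1)
  }
  paste(chars, collapse = "")
}

#' Sample a synthetic binding-affinity table
#'
#' `ln(IC50) = baseline - sum(anchor bonuses) + N(0, sd)`, clipped to
#' `[1, 50000]` nM. A fraction of peptides is drawn to match the sampled
#' allele's anchors so that binders are represented.
#'
#' @param world A [make_world()] object.
#' @param n Number of rows.
#' @param seed Integer seed.
#' @param frac_motif Fraction of peptides forced to match their allele's
#'   anchor motif (default 0.3).
#' @return Data.frame `peptide`, `allele`, `ic50_nM`, plus a hidden-truth
#'   attribute `true_log_ic50` (noise-free values).
#' @export
sample_ba <- function(world, n, seed = world$seed + 100L, frac_motif = 0.3) {
  stopifnot(inherits(world, "synthetic_world"), n >= 1)
  set.seed(seed)
  allele <- sample(world$alleles, n, replace = TRUE)
  is_motif <- stats::runif(n) < frac_motif
  peptide <- character(n)
  peptide[!is_motif] <- .random_peptides(sum(!is_motif), world$peptide_length)
  for (i in which(is_motif)) peptide[i] <- .motif_peptide(world, allele[i])
  true_log <- vapply(seq_len(n), function(i)
    .true_log_ic50(world, peptide[i], allele[i]), numeric(1))
  ic50 <- exp(true_log + stats::rnorm(n, 0, world$log_ic50_sd))
  ic50 <- pmin(pmax(ic50, 1), 50000)
  out <- data.frame(peptide = peptide, allele = allele, ic50_nM = ic50,
                    stringsAsFactors = FALSE)
  attr(out, "true_log_ic50") <- true_log
  out
}

#' Sample a synthetic eluted-ligand table
#'
#' Positives are peptides generated from the motif of a true allele
#' (the stronger the binding, the more likely the match); negatives are
#' uniform random peptides, so a small fraction are true binders — the
#' contamination the curation pipeline is expected to remove. In
#' multi-allele mode the visible candidate set holds 2-6 alleles including
#' the true one.
#'
#' @param world A [make_world()] object.
#' @param n_pos,n_neg Numbers of positive and decoy rows (`>= 0`).
#' @param multi_allele Emit multi-allele candidate sets.
#' @param seed Integer seed.
#' @param p_match Per-anchor match probability for positives (default 0.95).
#' @return List with `data` (data.frame `peptide`, `alleles` list column,
#'   `label`) and `truth` (data.frame with the hidden `true_allele` for
#'   positives and `is_true_binder` for all rows).
#' @export
sample_el <- function(world, n_pos, n_neg, multi_allele = FALSE,
                      seed = world$seed + 200L, p_match = 0.95) {
  stopifnot(inherits(world, "synthetic_world"), n_pos >= 0, n_neg >= 0)
  set.seed(seed)
  n_all <- length(world$alleles)
  true_allele <- c(sample(world$alleles, n_pos, replace = TRUE),
                   rep(NA_character_, n_neg))
  peptide <- character(n_pos + n_neg)
  for (i in seq_len(n_pos)) {
    peptide[i] <- .motif_peptide(world, true_allele[i], p_match)
  }
  if (n_neg > 0) {
    peptide[n_pos + seq_len(n_neg)] <-
      .random_peptides(n_neg, world$peptide_length)
  }
  label <- rep(c(1L, 0L), c(n_pos, n_neg))
  n <- n_pos + n_neg
  alleles <- vector("list", n)
  for (i in seq_len(n)) {
    if (multi_allele && n_all > 1) {
      size <- sample(2:min(6L, n_all), 1)
      anchor <- if (label[i] == 1) true_allele[i] else
        sample(world$alleles, 1)
      others <- setdiff(world$alleles, anchor)
      alleles[[i]] <- sort(c(anchor,
        others[sample.int(length(others), size - 1L)]))
    } else {
      alleles[[i]] <- if (label[i] == 1) true_allele[i] else
        sample(world$alleles, 1)
    }
  }
  # a decoy is a true binder if its noise-free IC50 beats 500 nM for any
  # candidate allele
  is_binder <- vapply(seq_len(n), function(i)
    any(vapply(alleles[[i]], function(a)
      exp(.true_log_ic50(world, peptide[i], a)) < 500, logical(1))),
    logical(1))
  list(
    data = data.frame(peptide = peptide,
                      alleles = I(alleles), label = label,
                      stringsAsFactors = FALSE),
    truth = data.frame(peptide = peptide, label = label,
                       true_allele = true_allele,
                       is_true_binder = is_binder,
                       stringsAsFactors = FALSE)
  )
}

#' Sample a synthetic somatic-mutation table
#'
#' Random proteins (length 50-200) with one mutation each, drawn from the
#' mutation types the neoantigen pipeline accepts. Deliberately bad rows are
#' planted at fixed rates (10% missing mutant sequence, 10% silent no-op
#' mutations, 5% duplicated rows) so the preprocessing filters have known
#' expected removals; the plan is returned alongside the table.
#'
#' @param world A [make_world()] object (used only for its RNG conventions).
#' @param n_proteins Number of clean records before planting bad rows.
#' @param seed Integer seed.
#' @return List with `data` (mutation table) and `plan` (counts of planted
#'   missing/unchanged/duplicate rows).
#' @export
sample_mutations <- function(world, n_proteins, seed = world$seed + 300L) {
  stopifnot(n_proteins >= 1)
  set.seed(seed)
  types <- c("Missense", "Nonsense", "Frame_Shift_Del", "Frame_Shift_Ins",
             "Splice_Site", "Intron", "Nonstop")
  rows <- vector("list", n_proteins)
  for (i in seq_len(n_proteins)) {
    len <- sample(50:200, 1)
    wt <- paste(sample(aa_alphabet, len, replace = TRUE), collapse = "")
    type <- sample(types, 1)
    pos <- sample(seq_len(len), 1)
    mut <- strsplit(wt, "")[[1]]
    if (type %in% c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonstop")) {
      # downstream of pos is neo-sequence
      tail_len <- len - pos + 1L
      mut[pos:len] <- sample(aa_alphabet, tail_len, replace = TRUE)
    } else {
      mut[pos] <- sample(setdiff(aa_alphabet, mut[pos]), 1)
    }
    rows[[i]] <- data.frame(protein_id = sprintf("PROT%04d", i),
                            wildtype_seq = wt,
                            mutant_seq = paste(mut, collapse = ""),
                            mutation_type = type, altered_pos = pos,
                            stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  n_missing <- round(0.10 * n_proteins)
  n_unchanged <- round(0.10 * n_proteins)
  n_dup <- round(0.05 * n_proteins)
  bad <- list()
  if (n_missing > 0) {
    b <- df[sample(n_proteins, n_missing, replace = TRUE), ]
    b$mutant_seq <- ""
    b$protein_id <- sprintf("MISS%04d", seq_len(n_missing))
    bad$missing <- b
  }
  if (n_unchanged > 0) {
    b <- df[sample(n_proteins, n_unchanged, replace = TRUE), ]
    b$mutant_seq <- b$wildtype_seq
    b$protein_id <- sprintf("SILT%04d", seq_len(n_unchanged))
    bad$unchanged <- b
  }
  if (n_dup > 0) bad$dup <- df[sample(n_proteins, n_dup), ]
  out <- rbind(df, do.call(rbind, unname(bad)))
  out <- out[sample(nrow(out)), ]
  rownames(out) <- NULL
  list(data = out,
       plan = list(n_clean = n_proteins, n_missing = n_missing,
                   n_unchanged = n_unchanged, n_duplicate = n_dup))
}

#' Write a world's fixture files to a directory
#'
#' Emits `pseudo.tsv`, `ba.tsv`, `el_sa.tsv`, `el_ma.tsv`, `mutations.tsv`
#' and hidden-truth JSON sidecars (`*_truth.json`), which the pipeline files
#' never read.
#'
#' @param world A [make_world()] object.
#' @param dir Output directory (created if needed).
#' @param n_ba,n_el_pos,n_el_neg,n_proteins Sizes.
#' @param seed Integer seed.
#' @return The directory, invisibly.
#' @export
write_world_fixtures <- function(world, dir, n_ba = 2000, n_el_pos = 500,
                                 n_el_neg = 500, n_proteins = 50,
                                 seed = world$seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table(data.frame(allele = world$alleles,
                         pseudo_sequence = unname(world$pseudo)),
              file.path(dir, "pseudo.tsv"))
  ba <- sample_ba(world, n_ba, seed = seed + 100L)
  write_table(ba, file.path(dir, "ba.tsv"))
  sa <- sample_el(world, n_el_pos, n_el_neg, multi_allele = FALSE,
                  seed = seed + 200L)
  ma <- sample_el(world, n_el_pos, n_el_neg, multi_allele = TRUE,
                  seed = seed + 201L)
  for (nm in c("sa", "ma")) {
    el <- get(nm)
    flat <- data.frame(peptide = el$data$peptide,
                       alleles = vapply(el$data$alleles, paste,
                                        character(1), collapse = ","),
                       label = el$data$label)
    write_table(flat, file.path(dir, paste0("el_", nm, ".tsv")))
    jsonlite::write_json(el$truth,
                         file.path(dir, paste0("el_", nm, "_truth.json")))
  }
  mut <- sample_mutations(world, n_proteins, seed = seed + 300L)
  write_table(mut$data, file.path(dir, "mutations.tsv"))
  jsonlite::write_json(mut$plan, file.path(dir, "mutations_truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
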