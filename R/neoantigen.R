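# Neoantigen candidate pipeline: mutation table -> cleaned records ->
# sliding-window candidate peptides (lengths 8-11) containing the altered
# site -> panel scoring over 20 alleles -> threshold selection -> sequence
# logo information-content matrices.

.mutation_types <- c("Missense", "Nonsense", "Frame_Shift_Del",
                     "Frame_Shift_Ins", "Splice_Site", "Intron", "Nonstop")

# mutation types whose whole downstream sequence is neo-sequence
.suffix_types <- c("Frame_Shift_Del", "Frame_Shift_Ins", "Nonstop")

#' Clean a mutation table
#'
#' Applies the three preprocessing filters: drop rows with missing fields,
#' drop rows whose mutant sequence equals the wild type, and collapse exact
#' duplicate rows. Row order of survivors is preserved; this never fails.
#'
#' @param records Data.frame with columns `protein_id`, `wildtype_seq`,
#'   `mutant_seq`, `mutation_type`, `altered_pos`.
#' @return The filtered data.frame.
#' @export
preprocess_mutations <- function(records) {
  if (nrow(records) == 0) return(records)
  chr_cols <- c("protein_id", "wildtype_seq", "mutant_seq", "mutation_type")
  complete <- rowSums(is.na(records)) == 0 &
    Reduce(`&`, lapply(records[chr_cols], nzchar))
  records <- records[complete, , drop = FALSE]
  records <- records[records$mutant_seq != records$wildtype_seq, ,
                     drop = FALSE]
  records <- records[!duplicated(records), , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Enumerate candidate windows containing the mutated site
#'
#' For each window length L, emits every window of the mutant protein that
#' overlaps the altered region. For missense/nonsense/splice-site/intron
#' records the altered region is the single position `altered_pos`; for
#' frameshift and nonstop records every position from `altered_pos` to the
#' C-terminus counts as altered.
#'
#' @param record One-row data.frame (or list) with `protein_id`,
#'   `mutant_seq`, `mutation_type`, `altered_pos`.
#' @param lengths Window lengths (default 8-11).
#' @return Data.frame `sequence`, `protein_id`, `window_start`, `length`,
#'   `contains_altered` (always `TRUE`).
#' @export
generate_mutant_windows <- function(record, lengths = 8:11) {
  seq <- record$mutant_seq
  N <- nchar(seq)
  p <- as.integer(record$altered_pos)
  if (is.na(p) || p < 1 || p > N) {
    stop(sprintf("altered position %s outside mutant sequence (length %d)",
                 record$altered_pos, N), call. = FALSE)
  }
  if (!record$mutation_type %in% .mutation_types) {
    stop("unsupported mutation type: ", record$mutation_type, call. = FALSE)
  }
  alt_end <- if (record$mutation_type %in% .suffix_types) N else p
  out <- list()
  for (L in lengths) {
    if (L > N) next
    # window [s, s+L-1] must intersect [p, alt_end]
    s_min <- max(1L, p - L + 1L)
    s_max <- min(alt_end, N - L + 1L)
    if (s_min > s_max) next
    s <- s_min:s_max
    out[[length(out) + 1L]] <- data.frame(
      sequence = substring(seq, s, s + L - 1L),
      protein_id = record$protein_id,
      window_start = s, length = L, contains_altered = TRUE,
      stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(sequence = character(0), protein_id = character(0),
                      window_start = integer(0), length = integer(0),
                      contains_altered = logical(0)))
  }
  res <- do.call(rbind, out)
  res[!duplicated(res[c("sequence", "window_start", "length")]), ,
      drop = FALSE]
}

#' Score candidate peptides against an allele panel
#'
#' Predicts the ensemble score of every peptide against every panel allele
#' and attaches the per-peptide row mean (and optionally the maximum).
#'
#' @param peptides Character vector of candidate peptides.
#' @param panel Character vector of panel allele names (20 common class-I
#'   alleles in the bundled default; see [default_panel()]).
#' @param model A `fold_ensemble` (classification task) or a scoring
#'   function `f(peptide, allele)`.
#' @param pseudo_table Named character vector covering every panel allele.
#' @return Object of class `panel_scores`: list with `scores` (peptides x
#'   alleles matrix), `mean_score`, `max_score`, `peptides`, `panel`.
#' @export
score_against_panel <- function(peptides, panel, model, pseudo_table) {
  stopifnot(length(peptides) >= 1, length(panel) >= 1)
  missing <- setdiff(panel, names(pseudo_table))
  if (length(missing)) {
    stop("panel allele(s) missing from pseudo-sequence table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  scorer <- if (is.function(model)) model else
    function(pep, al) ensemble_predict(model, pep, al, pseudo_table)
  pep_rep <- rep(peptides, times = length(panel))
  al_rep <- rep(panel, each = length(peptides))
  sc <- matrix(scorer(pep_rep, al_rep), nrow = length(peptides),
               dimnames = list(peptides, panel))
  structure(list(scores = sc, mean_score = rowMeans(sc),
                 max_score = apply(sc, 1, max),
                 peptides = peptides, panel = panel),
            class = "panel_scores")
}

#' Select high-scoring candidates by mean panel score
#'
#' Keeps peptides whose mean (or maximum, if `statistic = "max"`) panel
#' score strictly exceeds the threshold. Selections nest: the 0.7 set is a
#' subset of the 0.5 set, which is a subset of the 0.2 set.
#'
#' @param panel_scores A [score_against_panel()] result.
#' @param threshold Score cutoff (the conventional choices are 0.2, 0.5,
#'   0.7).
#' @param statistic `"mean"` (default) or `"max"`.
#' @return Character vector of selected peptides.
#' @export
select_high_scoring <- function(panel_scores, threshold,
                                statistic = c("mean", "max")) {
  statistic <- match.arg(statistic)
  s <- if (statistic == "mean") panel_scores$mean_score else
    panel_scores$max_score
  panel_scores$peptides[s > threshold]
}

#' Sequence-logo information-content matrix
#'
#' For equal-length peptides, computes per-position residue frequencies and
#' the Shannon information `log2(20) - H` (bits); the per-residue bar height
#' is `frequency * information` (Shannon-logo convention, no pseudocount).
#'
#' @param peptides Character vector (`>= 1`) of equal-length peptides.
#' @return Object of class `motif_matrix`: list with `freq` and `heights`
#'   (positions x 20 matrices), `information` (bits per position), `n`.
#' @export
motif_matrix <- function(peptides) {
  if (length(peptides) < 1) stop("need at least one peptide", call. = FALSE)
  lens <- nchar(peptides)
  if (length(unique(lens)) != 1) {
    stop("peptides must share one length; group by length first",
         call. = FALSE)
  }
  L <- lens[1]
  mat <- do.call(rbind, strsplit(toupper(peptides), ""))
  freq <- t(vapply(seq_len(L), function(p) {
    counts <- table(factor(mat[, p], levels = aa_alphabet))
    as.numeric(counts) / length(peptides)
  }, numeric(20)))
  colnames(freq) <- aa_alphabet
  H <- apply(freq, 1, function(f) {
    f <- f[f > 0]
    -sum(f * log2(f))
  })
  info <- log2(20) - H
  structure(list(freq = freq, information = info, heights = freq * info,
                 n = length(peptides)),
            class = "motif_matrix")
}

#' Bundled default class-I allele panel
#'
#' Twenty common HLA class-I allele names with synthetic placeholder
#' pseudo-sequences (shipped as
#' `extdata/panel_class1_synthetic.tsv`). The pseudo-sequences are randomly
#' generated stand-ins so the pipeline runs out of the box; replace them
#' with real contact-residue pseudo-sequences for production use.
#'
#' @return Named character vector of 20 pseudo-sequences.
#' @export
default_panel <- function() {
  read_pseudo_table(system.file("extdata", "panel_class1_synthetic.tsv",
                                package = "mhcbind"))
}

#' Run the neoantigen candidate pipeline
#'
#' Cleans the mutation table, enumerates candidate windows, scores them
#' against the allele panel, applies the selection thresholds, and computes
#' per-length motif matrices of the selected peptides.
#'
#' @param mutations Mutation data.frame (schema `mutations`).
#' @param model A classification `fold_ensemble` or scoring function.
#' @param pseudo_table Pseudo-sequences covering the panel.
#' @param panel Character vector of panel alleles (default: names of
#'   `pseudo_table`).
#' @param lengths Window lengths (default 8-11).
#' @param thresholds Selection cutoffs (default `c(0.2, 0.5, 0.7)`).
#' @return List: `candidates` (windows with mean panel scores), `selected`
#'   (list per threshold), `motifs` (list per threshold of per-length
#'   `motif_matrix` objects), `panel_scores`.
#' @export
run_neoantigen <- function(mutations, model, pseudo_table,
                           panel = names(pseudo_table), lengths = 8:11,
                           thresholds = c(0.2, 0.5, 0.7)) {
  clean <- preprocess_mutations(mutations)
  wins <- lapply(seq_len(nrow(clean)), function(i)
    generate_mutant_windows(clean[i, ], lengths))
  cand <- do.call(rbind, wins)
  if (is.null(cand) || nrow(cand) == 0) {
    stop("no candidate windows generated", call. = FALSE)
  }
  cand <- cand[!duplicated(cand$sequence), , drop = FALSE]
  ps <- score_against_panel(cand$sequence, panel, model, pseudo_table)
  cand$mean_score <- ps$mean_score
  selected <- lapply(stats::setNames(thresholds, thresholds), function(th)
    select_high_scoring(ps, th))
  motifs <- lapply(selected, function(peps) {
    if (!length(peps)) return(list())
    by_len <- split(peps, nchar(peps))
    lapply(by_len, motif_matrix)
  })
  list(candidates = cand, selected = selected, motifs = motifs,
       panel_scores = ps)
}
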