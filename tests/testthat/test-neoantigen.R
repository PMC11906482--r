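mut_row <- function(id = "P1", wt = NULL, mut, type = "Missense", pos) {
  if (is.null(wt)) {
    wt <- mut
    substr(wt, pos, pos) <- if (substr(mut, pos, pos) == "A") "C" else "A"
  }
  data.frame(protein_id = id, wildtype_seq = wt, mutant_seq = mut,
             mutation_type = type, altered_pos = pos,
             stringsAsFactors = FALSE)
}

test_that("mutation preprocessing applies the three filters in order", {
  clean <- mut_row("P1", mut = strrep("ACDEF", 6), pos = 3)
  missing <- clean; missing$mutant_seq <- ""
  unchanged <- clean; unchanged$protein_id <- "P2"
  unchanged$mutant_seq <- unchanged$wildtype_seq
  dup <- mut_row("P3", mut = strrep("GHIKL", 6), pos = 7)
  tab <- rbind(clean, missing, unchanged, dup, dup)
  out <- preprocess_mutations(tab)
  expect_equal(nrow(out), 2L)
  expect_equal(out$protein_id, c("P1", "P3"))
  expect_equal(preprocess_mutations(tab[0, ]), tab[0, ])
  all_clean <- rbind(clean, dup)
  expect_equal(preprocess_mutations(all_clean), all_clean)
})

test_that("window enumeration matches the closed form and brute force", {
  r <- mut_row("P1", mut = paste(rep("ACDEFGHIKL", 3), collapse = ""),
               pos = 15)
  w <- generate_mutant_windows(r)
  expect_equal(nrow(w), 8 + 9 + 10 + 11)
  expect_true(all(w$window_start <= 15 &
                    w$window_start + w$length - 1 >= 15))
  expect_true(all(w$contains_altered))

  # boundary: mutation at position 1 allows exactly one window per length
  r1 <- mut_row("P1", mut = strrep("ACDEFGHIKL", 3), pos = 1)
  w1 <- generate_mutant_windows(r1, lengths = 9)
  expect_equal(nrow(w1), 1L)
  expect_equal(w1$window_start, 1L)

  # protein shorter than the window yields nothing for that length
  r2 <- mut_row("P2", mut = "ACDEFGHW", pos = 4)
  expect_equal(nrow(generate_mutant_windows(r2, lengths = 9)), 0L)
  expect_equal(nrow(generate_mutant_windows(r2, lengths = 8)), 1L)

  expect_error(generate_mutant_windows(
    mut_row("P3", mut = "ACDEFGHIK", pos = 25)), "outside")
})

test_that("window counts equal brute-force enumeration on random cases", {
  set.seed(33)
  for (i in 1:100) {
    N <- sample(8:40, 1)
    p <- sample(seq_len(N), 1)
    L <- sample(8:11, 1)
    suffix <- sample(c(TRUE, FALSE), 1)
    type <- if (suffix) "Frame_Shift_Del" else "Missense"
    mut <- paste(sample(aa_alphabet, N, replace = TRUE), collapse = "")
    r <- data.frame(protein_id = "X", wildtype_seq = strrep("A", N),
                    mutant_seq = mut, mutation_type = type, altered_pos = p)
    got <- nrow(generate_mutant_windows(r, lengths = L))
    want <- oracle_window_count(N, p, L, alt_end = if (suffix) N else p)
    expect_identical(got, want)
    # closed form for the point-mutation case
    if (!suffix) {
      expect_identical(got,
                       max(0L, min(p, N - L + 1L) - max(1L, p - L + 1L) + 1L))
    }
  }
})

test_that("panel scoring has the right shape and row statistics", {
  pseudo <- toy_pseudo(sprintf("AL%02d", 1:20))
  peps <- c("ACDEFGHIK", "CDEFGHIKL", "DEFGHIKLM")
  half <- function(pep, al) rep(0.5, length(pep))
  ps <- score_against_panel(peps, names(pseudo), half, pseudo)
  expect_equal(dim(ps$scores), c(3L, 20L))
  expect_equal(unname(ps$mean_score), rep(0.5, 3))

  sc <- stub_scorer(5)
  ps2 <- score_against_panel(peps, names(pseudo), sc, pseudo)
  expect_equal(unname(ps2$mean_score), unname(rowMeans(ps2$scores)))
  expect_equal(unname(ps2$max_score),
               unname(apply(ps2$scores, 1, max)))
  expect_error(score_against_panel(peps, c("AL01", "MISSING"), half,
                                   pseudo), "MISSING")
})

test_that("threshold selection is strict and nested", {
  ps <- structure(list(scores = matrix(c(0.1, 0.55, 0.8), 3, 2),
                       mean_score = c(0.1, 0.55, 0.8),
                       max_score = c(0.1, 0.55, 0.8),
                       peptides = c("p1", "p2", "p3"),
                       panel = c("a", "b")), class = "panel_scores")
  expect_equal(select_high_scoring(ps, 0.5), c("p2", "p3"))
  expect_equal(select_high_scoring(ps, 0.7), "p3")
  expect_equal(select_high_scoring(ps, 0.8), character(0))  # strict >
  set.seed(44)
  for (i in 1:20) {
    ms <- stats::runif(30)
    ps$scores <- matrix(ms, 30, 1); ps$mean_score <- ms; ps$max_score <- ms
    ps$peptides <- sprintf("pep%02d", 1:30)
    s2 <- select_high_scoring(ps, 0.2)
    s5 <- select_high_scoring(ps, 0.5)
    s7 <- select_high_scoring(ps, 0.7)
    expect_true(all(s7 %in% s5))
    expect_true(all(s5 %in% s2))
  }
})

test_that("motif information content hits its closed forms", {
  m <- motif_matrix(rep("ACDEFGHIK", 7))
  expect_equal(m$information, rep(log2(20), 9), tolerance = 1e-9)
  expect_equal(sum(m$heights[1, ]), log2(20), tolerance = 1e-9)
  expect_equal(unname(m$heights[1, "A"]), log2(20), tolerance = 1e-9)

  # uniform usage of all residues at a position carries no information
  peps <- vapply(aa_alphabet, function(a) paste0(a, "CDEFGHIK"), character(1))
  mu <- motif_matrix(peps)
  expect_equal(mu$information[1], 0, tolerance = 1e-9)

  # 50/50 between two residues leaves log2(20) - 1 bits
  half <- c(rep("ACDEFGHIK", 5), rep("CCDEFGHIK", 5))
  mh <- motif_matrix(half)
  expect_equal(mh$information[1], log2(20) - 1, tolerance = 1e-9)
  expect_equal(sum(mh$heights[1, ]), mh$information[1], tolerance = 1e-9)

  expect_error(motif_matrix(c("ACDEFGHIK", "ACDEFGHI")), "length")
  expect_error(motif_matrix(character(0)), "at least one")
})

test_that("motif information is bounded and heights sum per position", {
  set.seed(55)
  peps <- replicate(50, paste(sample(aa_alphabet, 9,
                                     prob = c(rep(4, 4), rep(1, 16)),
                                     replace = TRUE), collapse = ""))
  m <- motif_matrix(peps)
  expect_true(all(m$information >= 0 & m$information <= log2(20) + 1e-12))
  expect_equal(rowSums(m$heights), m$information, tolerance = 1e-12)
})

test_that("the neoantigen pipeline runs end to end with a stub model", {
  pseudo <- toy_pseudo(sprintf("AL%02d", 1:20))
  set.seed(66)
  muts <- do.call(rbind, lapply(1:4, function(i) {
    mut_row(sprintf("P%d", i),
            mut = paste(sample(aa_alphabet, 30, TRUE), collapse = ""),
            pos = sample(5:25, 1))
  }))
  # anchor-proline scorer: peptides with P at position 4 score high
  scorer <- function(pep, al) {
    0.15 + 0.7 * (substr(pep, 4, 4) == "P") + 0.05 * (al == "AL01")
  }
  res <- run_neoantigen(muts, scorer, pseudo)
  expect_true(nrow(res$candidates) > 0)
  expect_true(all(nchar(res$candidates$sequence) %in% 8:11))
  expect_true(all(res$selected[["0.7"]] %in% res$selected[["0.5"]]))
  expect_true(all(res$selected[["0.5"]] %in% res$selected[["0.2"]]))
  sel <- res$selected[["0.5"]]
  if (length(sel) > 0) {
    expect_true(all(substr(sel, 4, 4) == "P"))
    for (len in names(res$motifs[["0.5"]])) {
      mm <- res$motifs[["0.5"]][[len]]
      expect_s3_class(mm, "motif_matrix")
      expect_equal(unname(mm$freq[4, "P"]), 1)  # planted anchor dominates
    }
  }
})

test_that("the bundled panel ships 20 alleles with synthetic sequences", {
  panel <- default_panel()
  expect_length(panel, 20L)
  expect_true(all(grepl("^HLA-", names(panel))))
  expect_equal(unique(nchar(panel)), 34L)
})
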