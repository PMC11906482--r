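el_frame <- function(peptides, alleles, labels) {
  data.frame(peptide = peptides, alleles = I(alleles),
             label = as.integer(labels), stringsAsFactors = FALSE)
}

test_that("multi-allele deconvolution assigns the argmax allele", {
  pseudo <- toy_pseudo()
  el <- el_frame("ACDEFGHIK", list(c("A0201", "B0702")), 1)
  scorer <- function(pep, al) ifelse(al == "A0201", 0.9, 0.4)
  out <- deconvolve_multi_allele(el, scorer, pseudo)
  expect_equal(out$assigned_allele, "A0201")
  expect_equal(out$alleles[[1]], "A0201")
})

test_that("single-candidate samples never consult the model", {
  pseudo <- toy_pseudo()
  el <- el_frame(c("ACDEFGHIK", "CDEFGHIKL"), list("B0702", "A0101"), c(1, 1))
  angry <- function(pep, al) stop("model should not be called")
  out <- deconvolve_multi_allele(el, angry, pseudo)
  expect_equal(out$assigned_allele, c("B0702", "A0101"))
})

test_that("exact ties break lexicographically by allele name", {
  pseudo <- toy_pseudo()
  el <- el_frame("ACDEFGHIK", list(c("B0801", "A0101")), 1)
  pseudo <- c(pseudo, B0801 = unname(pseudo[1]), A0101 = unname(pseudo[2]))
  flat <- function(pep, al) rep(0.5, length(al))
  out <- deconvolve_multi_allele(el, flat, pseudo)
  expect_equal(out$assigned_allele, "A0101")
})

test_that("deconvolution equals brute-force argmax under a random scorer", {
  pseudo <- toy_pseudo(c("A0101", "A0201", "B0702", "B0801", "C0102"))
  sc <- stub_scorer(seed = 77)
  set.seed(78)
  n <- 1000
  peptides <- replicate(n, paste(sample(aa_alphabet, 9, replace = TRUE),
                                 collapse = ""))
  cands <- lapply(seq_len(n), function(i)
    sample(names(pseudo), sample(2:5, 1)))
  el <- el_frame(peptides, cands, rep(1, n))
  out <- deconvolve_multi_allele(el, sc, pseudo)
  for (i in seq_len(n)) {
    s <- sc(rep(peptides[i], length(cands[[i]])), cands[[i]])
    best <- min(cands[[i]][s == max(s)])
    expect_identical(out$assigned_allele[i], best)
  }
})

test_that("deconvolution rejects alleles without pseudo-sequences", {
  pseudo <- toy_pseudo(c("A0101", "A0201"))
  el <- el_frame("ACDEFGHIK", list(c("A0101", "ZZ999")), 1)
  expect_error(deconvolve_multi_allele(el, function(p, a) 1, pseudo),
               "ZZ999")
})

test_that("negative filtering removes high-scoring decoys only", {
  pseudo <- toy_pseudo()
  el <- el_frame(c("AAAAAAAAA", "CCCCCCCCC", "DDDDDDDDD", "EEEEEEEEE"),
                 list("A0101", "A0101", "A0101", "A0101"),
                 c(1, 0, 0, 0))
  scores <- c(AAAAAAAAA = 0.99, CCCCCCCCC = 0.9, DDDDDDDDD = 0.1,
              EEEEEEEEE = 0.5)
  scorer <- function(pep, al) unname(scores[pep])
  res <- filter_negatives(el, scorer, pseudo,
                          score_threshold = ic50_to_score(500))
  expect_equal(nrow(res$removed), 2L)
  expect_setequal(res$removed$peptide, c("CCCCCCCCC", "EEEEEEEEE"))
  # the high-scoring positive is untouched
  expect_true("AAAAAAAAA" %in% res$kept$peptide)
  expect_equal(res$report$n_negatives_removed, 2L)

  none <- filter_negatives(el, scorer, pseudo, score_threshold = 1e9)
  expect_equal(nrow(none$removed), 0L)
})

test_that("negative filtering is monotone in the threshold", {
  pseudo <- toy_pseudo()
  set.seed(90)
  n <- 200
  el <- el_frame(replicate(n, paste(sample(aa_alphabet, 9, TRUE),
                                    collapse = "")),
                 as.list(sample(names(pseudo), n, TRUE)),
                 sample(0:1, n, TRUE))
  sc <- stub_scorer(seed = 91)
  removed <- sapply(c(0.2, 0.4, 0.6, 0.8), function(th)
    nrow(filter_negatives(el, sc, pseudo, th)$removed))
  expect_true(all(diff(removed) <= 0))
})

test_that("merging dedups, unions provenance, and resolves conflicts", {
  ba <- data.frame(peptide = "ACDEFGHIK", allele = "A0101", ic50_nM = 499)
  sa <- el_frame("ACDEFGHIK", list("A0101"), 1)
  m <- merge_datasets(ba, sa)
  expect_equal(nrow(m$table), 1L)
  expect_equal(m$table$label, 1L)
  expect_equal(m$table$provenance, "BA,ELS_SA")
  expect_equal(m$report$n_conflicts, 0L)

  # disjoint inputs concatenate
  ba2 <- data.frame(peptide = c("AAAAAAAAA", "CCCCCCCCC"),
                    allele = "A0101", ic50_nM = c(10, 900))
  sa2 <- el_frame(c("DDDDDDDDD", "EEEEEEEEE", "FFFFFFFFF"),
                  list("A0101", "A0101", "B0702"), c(1, 1, 0))
  ma2 <- el_frame(c("GGGGGGGGG", "HHHHHHHHH", "IIIIIIIII", "KKKKKKKKK"),
                  list("A0101", "B0702", "A0101", "B0702"), c(1, 1, 1, 0))
  m2 <- merge_datasets(ba2, sa2, ma2)
  expect_equal(nrow(m2$table), 9L)

  # BA negative vs EL positive for the same pair -> positive, logged
  ba3 <- data.frame(peptide = "ACDEFGHIK", allele = "A0101", ic50_nM = 600)
  m3 <- merge_datasets(ba3, sa)
  expect_equal(m3$table$label, 1L)
  expect_equal(m3$report$n_conflicts, 1L)

  # multi-allele rows must be deconvolved first
  bad <- el_frame("ACDEFGHIK", list(c("A0101", "B0702")), 1)
  expect_error(merge_datasets(ba, bad), "single-allele")
})

test_that("curation pipeline removes planted binder decoys", {
  world <- make_world(2, seed = 140)
  pseudo <- world$pseudo
  # oracle scorer standing in for the pre-trained regressor
  oracle_model <- function(pep, al) {
    vapply(seq_along(pep), function(i)
      ic50_to_score(min(max(exp(
        mhcbind:::.true_log_ic50(world, pep[i], al[i])), 1), 50000)),
      numeric(1))
  }
  # decoys: mostly random, a few planted true binders
  set.seed(141)
  rand <- replicate(40, paste(sample(aa_alphabet, 9, TRUE), collapse = ""))
  planted <- replicate(10, mhcbind:::.motif_peptide(world, "SIM-01"))
  el <- el_frame(c(rand, planted),
                 as.list(rep("SIM-01", 50)), rep(0, 50))
  res <- filter_negatives(el, oracle_model, pseudo)
  above <- oracle_model(el$peptide, rep("SIM-01", 50)) >= ic50_to_score(500)
  expect_setequal(res$removed$peptide, el$peptide[above])
  expect_true(all(planted %in% res$removed$peptide))
})

test_that("run_curation completes with empty multi-allele input", {
  world <- make_world(2, seed = 150)
  ba <- sample_ba(world, 300, seed = 151)
  sa <- sample_el(world, 40, 40, seed = 152)
  cfg <- tiny_config(task = "regression", seed = 153, epochs = 2, t_max = 2,
                     batch_size = 64)
  res <- run_curation(ba, sa$data, NULL, world$pseudo, cfg, k = 2)
  expect_equal(res$report$n_ma_deconvolved, 0L)
  expect_true(nrow(res$table) > 0)
  expect_true(all(res$table$label %in% 0:1))
  # positives survive curation with their labels intact
  pos <- sa$data$peptide[sa$data$label == 1]
  merged_pos <- res$table$peptide[res$table$label == 1 &
                                    grepl("ELS_SA", res$table$provenance)]
  expect_true(all(pos %in% merged_pos))
})

test_that("curation requires binding-affinity data", {
  cfg <- tiny_config(task = "regression")
  expect_error(run_curation(NULL, NULL, NULL, c(A = "ACD"), cfg),
               "non-empty BA")
})
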