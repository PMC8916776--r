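test_that("wt_normalizer is the median of per-allele log ratios", {
  pair <- toy_count_pair(
    list(sel = vrows(2L, "GTC", 100), unsel = vrows(2L, "GTC", 100)),
    wt_ratios = c(1, 2, 4))
  norm <- wt_normalizer(pair$selected, pair$unselected, pseudocount = 0)
  expect_equal(norm$median_log_ratio, log10(2))
  expect_equal(norm$n_wt_alleles, 3)

  # all ratios one
  pair1 <- toy_count_pair(
    list(sel = vrows(2L, "GTC", 100), unsel = vrows(2L, "GTC", 100)),
    wt_ratios = c(1, 1, 1, 1))
  expect_equal(wt_normalizer(pair1$selected, pair1$unselected,
                             pseudocount = 0)$median_log_ratio, 0)

  # even allele number: median = mean of the central pair (sort-based oracle)
  ratios <- c(0.5, 1.2, 3.1, 8.4)
  paire <- toy_count_pair(
    list(sel = vrows(2L, "GTC", 100), unsel = vrows(2L, "GTC", 100)),
    wt_ratios = ratios)
  got <- wt_normalizer(paire$selected, paire$unselected,
                       pseudocount = 0)$median_log_ratio
  sorted <- sort(log10(ratios))
  expect_equal(got, mean(sorted[2:3]))

  # no shared alleles is an error
  empty <- variant_counts(vrows(2L, "GTC", 1),
                          tibble::tibble(allele = character(0),
                                         count = numeric(0)))
  expect_error(wt_normalizer(empty, empty),
               class = "satmut_missing_normalizer")
})

test_that("a ten-fold-the-WT-median ratio scores exactly +1", {
  pair <- toy_count_pair(
    list(sel = vrows(c(2L, 3L), c("GTC", "CGA"), c(1000, 200)),
         unsel = vrows(c(2L, 3L), c("GTC", "CGA"), c(50, 100))),
    wt_ratios = c(1, 2, 4))
  scores <- enrichment_scores(pair$selected, pair$unselected, pseudocount = 0)
  # variant ratio 20 = 10 x (WT median 2) -> +1
  expect_equal(scores$score[scores$codon == "GTC"], 1)
  # ratio 2 equals the WT median -> 0
  expect_equal(scores$score[scores$codon == "CGA"], 0)
})

test_that("hand-computed score: 200/100 against WT ratios {1,2,4} is zero", {
  pair <- toy_count_pair(
    list(sel = vrows(2L, "GTC", 200), unsel = vrows(2L, "GTC", 100)),
    wt_ratios = c(1, 2, 4))
  scores <- enrichment_scores(pair$selected, pair$unselected, pseudocount = 0)
  expect_equal(scores$score, 0.3010 - 0.3010, tolerance = 1e-3)
})

test_that("variants absent from one sample are flagged missing, not errors", {
  sel <- variant_counts(vrows(c(2L, 3L), c("GTC", "CGA"), c(10, 5)),
                        tibble::tibble(allele = "a", count = 10))
  unsel <- variant_counts(vrows(2L, "GTC", 10),
                          tibble::tibble(allele = "a", count = 10))
  scores <- enrichment_scores(sel, unsel)
  expect_true(is.na(scores$score[scores$codon == "CGA"]))
  expect_false(is.na(scores$score[scores$codon == "GTC"]))
})

test_that("enrichment scores are invariant to sequencing depth", {
  ref <- toy_reference()
  screen <- simulate_screen(screen_model(ref, depth = 200, seed = 5))
  base <- enrichment_scores(screen$selected, screen$unselected,
                            pseudocount = 0)
  for (lambda in c(3, 0.5)) {
    scaled <- variant_counts(
      dplyr::mutate(screen$selected$counts, count = count * lambda),
      dplyr::mutate(screen$selected$wt_alleles, count = count * lambda),
      "scaled")
    rescored <- enrichment_scores(scaled, screen$unselected, pseudocount = 0)
    expect_equal(rescored$score, base$score)
  }
})

test_that("legacy scoring differs from WT-median scoring by a constant", {
  ref <- toy_reference()
  screen <- simulate_screen(screen_model(ref, depth = 500, seed = 9))
  eq1 <- enrichment_scores(screen$selected, screen$unselected,
                           pseudocount = 0)
  ref_counts <- c(sel = 400, unsel = 380)
  eq3a <- legacy_enrichment(screen$selected, screen$unselected, ref_counts,
                            pseudocount = 0)
  diffs <- eq1$score - eq3a$score
  diffs <- diffs[!is.na(diffs)]
  expect_equal(diff(range(diffs)), 0, tolerance = 1e-12)
  # the constant is (median - reference) term
  norm <- wt_normalizer(screen$selected, screen$unselected, pseudocount = 0)
  expect_equal(diffs[1],
               log10(ref_counts[["sel"]] / ref_counts[["unsel"]]) -
                 norm$median_log_ratio)
  expect_error(
    legacy_enrichment(screen$selected, screen$unselected, c(0, 10)),
    class = "satmut_zero_reference")
})

test_that("baseline correction subtracts the median stop-codon signal", {
  variants <- list(
    sel = vrows(c(2L, 2L, 3L, 4L), c("TAA", "TAG", "TGA", "GTC"),
                c(10, 20, 30, 50)),
    unsel = vrows(c(2L, 2L, 3L, 4L), c("TAA", "TAG", "TGA", "GTC"),
                  c(100, 100, 100, 100)))
  pair <- toy_count_pair(variants, wt_ratios = c(1, 1, 1))
  corrected <- baseline_correct_counts(pair$selected, pair$unselected)
  # stop ratios {0.1, 0.2, 0.3}: median 0.2; 50 - 100*0.2 = 30
  expect_equal(corrected$counts$count[corrected$counts$codon == "GTC"], 30)
  # stop codons themselves land at or below zero and are floored
  expect_equal(corrected$counts$count[corrected$counts$codon == "TAA"], 1)
  rec <- attr(corrected, "baseline_record")
  expect_equal(rec$stop_median_ratio, 0.2)
})

test_that("baseline correction floors boundary cases and preserves rank", {
  # variant sitting exactly at the null expectation is floored
  variants <- list(
    sel = vrows(c(2L, 3L, 4L, 5L), c("TAA", "TGA", "GTC", "CGA"),
                c(20, 20, 20, 90)),
    unsel = vrows(c(2L, 3L, 4L, 5L), c("TAA", "TGA", "GTC", "CGA"),
                  c(100, 100, 100, 100)))
  pair <- toy_count_pair(variants, wt_ratios = c(1, 1, 1))
  corrected <- baseline_correct_counts(pair$selected, pair$unselected)
  expect_equal(corrected$counts$count[corrected$counts$codon == "GTC"], 1)
  # rank order among variants sharing unselected counts is preserved
  cnt <- corrected$counts$count
  sel_cnt <- pair$selected$counts$count
  expect_equal(order(cnt), order(sel_cnt))
  # no stop codons -> explicit error
  nostop <- toy_count_pair(
    list(sel = vrows(2L, "GTC", 10), unsel = vrows(2L, "GTC", 10)),
    wt_ratios = 1)
  expect_error(baseline_correct_counts(nostop$selected, nostop$unselected),
               class = "satmut_no_stop_codons")
})

test_that("zero stop-codon signal leaves counts unchanged", {
  variants <- list(
    sel = vrows(c(2L, 4L), c("TAA", "GTC"), c(0, 50)),
    unsel = vrows(c(2L, 4L), c("TAA", "GTC"), c(100, 100)))
  pair <- toy_count_pair(variants, wt_ratios = 1)
  corrected <- baseline_correct_counts(pair$selected, pair$unselected)
  expect_equal(corrected$counts$count[corrected$counts$codon == "GTC"], 50)
})

test_that("combine_synonymous averages codon scores per amino acid", {
  codon_tbl <- tibble::tibble(
    position = c(2L, 2L, 2L, 3L),
    codon = c("GTC", "GTT", "CGA", "AAA"),
    amino_acid = c("V", "V", "R", "K"),
    score = c(0.2, 0.4, NA, NA))
  aa_tbl <- combine_synonymous(codon_tbl)
  expect_equal(aa_tbl$score[aa_tbl$amino_acid == "V"], 0.3)
  expect_true(is.na(aa_tbl$score[aa_tbl$amino_acid == "R"]))
  # single codon is the identity
  expect_equal(nrow(aa_tbl), 3)
})

test_that("center_and_scale centers on the WT mode and hits target_sd", {
  tbl <- random_score_matrix(2:30, seed = 2, sd = 0.4)
  # wt scores symmetric around 0.5 -> mode ~0.5
  wt_scores <- withr::with_seed(8, 0.5 + rnorm(200, 0, 0.02))
  out <- center_and_scale(tbl, wt_scores, target_sd = 1)
  expect_equal(sd(out$score, na.rm = TRUE), 1, tolerance = 1e-6)
  rec <- attr(out, "normalization")
  expect_equal(rec$centered_mode, 0.5, tolerance = 0.02)
  # idempotence: re-running with wt scores at 0 and target sd = current sd
  again <- center_and_scale(out, withr::with_seed(9, rnorm(100, 0, 1e-3)),
                            target_sd = 1)
  expect_equal(again$score, out$score, tolerance = 0.02)
  expect_error(center_and_scale(dplyr::mutate(tbl, score = 1),
                                wt_scores = c(1, 1, 1)),
               class = "satmut_degenerate")
  expect_error(estimate_mode(c(1, 2)), class = "satmut_degenerate")
})

test_that("position_means matches a brute-force column mean, stop excluded", {
  tbl <- random_score_matrix(2:10, seed = 3)
  tbl <- dplyr::bind_rows(tbl, tibble::tibble(position = 2:10,
                                              amino_acid = "*", score = -5))
  tbl$score[c(3, 17)] <- NA
  pm <- position_means(tbl)
  for (p in 2:10) {
    sub <- tbl$score[tbl$position == p & tbl$amino_acid != "*"]
    expect_equal(pm$mean_score[pm$position == p], mean(sub, na.rm = TRUE))
  }
  # column with {1, -1} and the rest missing averages to zero
  toy <- tibble::tibble(position = 2L, amino_acid = c("A", "C", "D"),
                        score = c(1, -1, NA))
  expect_equal(position_means(toy)$mean_score, 0)
})

test_that("replicate score tables average cell-wise", {
  a <- tibble::tibble(position = c(2L, 3L), amino_acid = "A",
                      score = c(0.2, NA))
  b <- tibble::tibble(position = c(2L, 3L), amino_acid = "A",
                      score = c(0.4, 0.6))
  avg <- average_replicates(a, b)
  expect_equal(avg$score, c(0.3, 0.6))
})

test_that("score tables round-trip through delimited text with metadata", {
  ref <- toy_reference()
  screen <- simulate_screen(screen_model(ref, depth = 100, seed = 4))
  scores <- combine_synonymous(
    enrichment_scores(screen$selected, screen$unselected))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_scores(scores, path)
  back <- read_scores(path)
  expect_equal(back$score, scores$score)
  expect_true("normalization" %in% names(attributes(back)))
})
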