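toy_db <- function(position, mut_aa, count, isoform = "H", wt_aa = "G",
                   pathogenic = 0L) {
  tibble::tibble(isoform = isoform, position = position, wt_aa = wt_aa,
                 mut_aa = mut_aa, count = count, pathogenic = pathogenic)
}

test_that("count filter keeps >= 5 inclusively, per isoform or pooled", {
  db <- toy_db(position = c(12L, 12L, 13L, 61L),
               mut_aa = c("V", "D", "C", "L"),
               count = c(5L, 4L, 3L, 100L))
  kept <- filter_by_count(db, min_count = 5)
  expect_true("G12V" %in% kept)   # exactly five counts is in
  expect_false("G12D" %in% kept)  # four is out
  expect_false("G13C" %in% kept)
  expect_true("G61L" %in% kept)
  # brute-force oracle on a mixed toy database
  ids <- variant_id(db$position, db$mut_aa, db$wt_aa)
  brute <- sort(unique(ids[db$count >= 5]))
  expect_equal(kept, brute)
  # isoform pooling: 3 + 3 across isoforms passes pooled, fails per-isoform
  db2 <- toy_db(position = c(12L, 12L), mut_aa = "S", count = c(3L, 3L),
                isoform = c("H", "K"))
  expect_equal(filter_by_count(db2, pool_isoforms = TRUE), "G12S")
  expect_length(filter_by_count(db2, pool_isoforms = FALSE), 0)
})

test_that("truth assembly applies the overlap and pathogenic-flag rules", {
  tp <- toy_db(position = c(12L, 13L, 61L), mut_aa = c("V", "D", "L"),
               count = c(50L, 6L, 2L))
  tn <- toy_db(position = c(12L, 15L, 16L), mut_aa = c("V", "A", "T"),
               count = c(1L, 1L, 1L), pathogenic = c(0L, 1L, 0L))
  truth <- assemble_truth(tp, tn, min_count = 5)
  # overlap rule: G12V in both databases is a positive, not a negative
  expect_true("G12V" %in% truth$positives)
  expect_false("G12V" %in% truth$negatives)
  # below-cutoff cancer variant is unlabeled
  expect_false("G61L" %in% c(truth$positives, truth$negatives))
  # pathogenic-flagged population variant is excluded entirely
  expect_false("G15A" %in% c(truth$positives, truth$negatives))
  expect_setequal(truth$positives, c("G12V", "G13D"))
  expect_setequal(truth$negatives, "G16T")
  expect_error(assemble_truth(toy_db(12L, "V", 1L), tn),
               class = "satmut_degenerate_truth")
  expect_error(variant_truth(c("G12V"), c("G12V", "G13D")),
               class = "satmut_degenerate_truth")
})

test_that("truth from a score matrix labels the k-sigma tail positive", {
  m <- random_score_matrix(2:50, seed = 41)
  truth <- truth_from_scores(m, k = 1.5)
  thr <- 1.5 * sd(m$score)
  expect_equal(length(truth$positives), sum(m$score > thr))
  expect_equal(length(truth$positives) + length(truth$negatives), nrow(m))
  # all-zero matrix has no positives; k = Inf likewise
  zero <- dplyr::mutate(m, score = 0)
  expect_length(truth_from_scores(zero)$positives, 0)
  expect_length(truth_from_scores(m, k = Inf)$positives, 0)
})

test_that("ROC handles the worked four-variant example", {
  scores <- tibble::tibble(variant = c("p1", "p2", "n1", "n2"),
                           score = c(0.9, 0.4, 0.6, 0.1))
  truth <- variant_truth(c("p1", "p2"), c("n1", "n2"))
  roc <- roc_curve(scores, truth)
  expect_equal(roc$auc, 0.75)  # 3 of 4 pairs ordered correctly
  expect_equal(roc$points$fpr[1], 0)
  expect_equal(roc$points$tpr[1], 0)
  expect_equal(utils::tail(roc$points$fpr, 1), 1)
  expect_equal(utils::tail(roc$points$tpr, 1), 1)
  # monotone staircase
  expect_true(all(diff(roc$points$fpr) >= 0))
  expect_true(all(diff(roc$points$tpr) >= 0))
  # perfect separation and label inversion
  sep <- tibble::tibble(variant = c("p1", "p2", "n1", "n2"),
                        score = c(2, 1.5, 0.2, 0.1))
  expect_equal(roc_curve(sep, truth)$auc, 1)
  inv <- variant_truth(c("n1", "n2"), c("p1", "p2"))
  expect_equal(roc_curve(scores, inv)$auc, 1 - 0.75)
})

test_that("AUC equals the pairwise rank statistic (brute-force oracle)", {
  for (seed in 1:4) {
    withr::with_seed(seed, {
      n_p <- sample(5:80, 1)
      n_n <- sample(5:80, 1)
      # draws on a lattice so ties occur
      sp <- sample(seq(0, 2, by = 0.25), n_p, replace = TRUE)
      sn <- sample(seq(0, 2, by = 0.25), n_n, replace = TRUE)
    })
    scores <- tibble::tibble(
      variant = c(paste0("p", seq_len(n_p)), paste0("n", seq_len(n_n))),
      score = c(sp, sn))
    truth <- variant_truth(paste0("p", seq_len(n_p)),
                           paste0("n", seq_len(n_n)))
    roc <- roc_curve(scores, truth)
    wins <- 0
    for (i in seq_len(n_p)) {
      for (j in seq_len(n_n)) {
        wins <- wins + (sp[i] > sn[j]) + 0.5 * (sp[i] == sn[j])
      }
    }
    expect_equal(roc$auc, wins / (n_p * n_n))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::with_seed(77, {
    sp <- rnorm(40, 1)
    sn <- rnorm(60, 0)
  })
  scores <- tibble::tibble(
    variant = c(paste0("p", 1:40), paste0("n", 1:60)),
    score = c(sp, sn))
  truth <- variant_truth(paste0("p", 1:40), paste0("n", 1:60))
  base <- roc_curve(scores, truth)$auc
  for (f in list(function(x) 3 * x + 2, function(x) exp(x),
                 function(x) x^3)) {
    tr <- dplyr::mutate(scores, score = f(score))
    expect_equal(roc_curve(tr, truth)$auc, base)
  }
})

test_that("self-derived truth gives AUC exactly 1", {
  m <- random_score_matrix(2:40, seed = 51)
  truth <- truth_from_scores(m, k = 1.5)
  expect_equal(roc_curve(m, truth)$auc, 1)
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(99, {
    sp <- rnorm(50, 0.8)
    sn <- rnorm(70, 0)
  })
  scores <- tibble::tibble(
    variant = c(paste0("p", 1:50), paste0("n", 1:70)),
    score = c(sp, sn))
  truth <- variant_truth(paste0("p", 1:50), paste0("n", 1:70))
  ours <- roc_curve(scores, truth)$auc
  ref <- pROC::auc(pROC::roc(
    response = c(rep(1, 50), rep(0, 70)), predictor = c(sp, sn),
    direction = "<", quiet = TRUE))
  expect_equal(ours, as.numeric(ref))
})

test_that("unscored truth variants are dropped; empty classes error", {
  scores <- tibble::tibble(variant = c("p1", "n1"), score = c(1, 0))
  truth <- variant_truth(c("p1", "p_unscored"), c("n1"))
  expect_message(roc <- roc_curve(scores, truth), "dropped")
  expect_equal(roc$n_positive, 1)
  bad <- variant_truth("p_unscored", "n1")
  expect_error(suppressMessages(roc_curve(scores, bad)),
               class = "satmut_degenerate_truth")
})

test_that("variant databases read from delimited text", {
  db <- toy_db(position = c(12L, 13L), mut_aa = c("V", "D"),
               count = c(10L, 3L))
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(db, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_variant_db(path)
  expect_equal(back$count, db$count)
  expect_equal(filter_by_count(back), "G12V")
})
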