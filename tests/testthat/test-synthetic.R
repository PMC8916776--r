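test_that("generate_library enumerates 63 substitutions per position", {
  ref <- toy_reference(n_repeats = 2)
  lib <- generate_library(ref, positions = c(2L, 5L))
  expect_equal(nrow(lib), 2 * 63)
  expect_false(anyDuplicated(lib$sequence) > 0)
  per_pos <- table(lib$position)
  expect_true(all(per_pos == 63))
  # every generated sequence calls back to its intended variant
  for (i in sample(nrow(lib), 12)) {
    call <- call_variant(lib$sequence[i], ref)
    if (lib$amino_acid[i] ==
        ref$protein[match(lib$position[i], ref$positions)]) {
      expect_equal(call$category, "wt_synonymous")
    } else {
      expect_equal(call$category, "single_codon")
      expect_equal(call$position, lib$position[i])
      expect_equal(call$codon, lib$codon[i])
    }
  }
})

test_that("wild-type alleles are distinct, non-template and synonymous", {
  ref <- toy_reference()
  alleles <- generate_wt_alleles(ref, n = 50, seed = 2)
  expect_equal(length(alleles), 50)
  expect_false(anyDuplicated(alleles) > 0)
  expect_false(ref$dna %in% alleles)
  for (a in alleles[1:10]) {
    expect_equal(translate_dna(a), ref$protein)
  }
})

test_that("generators are bit-reproducible given the seed", {
  ref <- toy_reference()
  m <- screen_model(ref, leaky_fitness(ref), leak = -1.5, depth = 100,
                    seed = 33)
  s1 <- simulate_screen(m)
  s2 <- simulate_screen(m)
  expect_identical(s1$selected$counts, s2$selected$counts)
  expect_identical(s1$unselected$wt_alleles, s2$unselected$wt_alleles)
  c1 <- simulate_unfolding_curve(29.9, 5, seed = 7)
  c2 <- simulate_unfolding_curve(29.9, 5, seed = 7)
  expect_identical(c1$signal, c2$signal)
  d1 <- simulate_decay_series(10, 0.2, 1:10, seed = 7)
  d2 <- simulate_decay_series(10, 0.2, 1:10, seed = 7)
  expect_identical(d1$value, d2$value)
  # a different seed produces different data
  expect_false(identical(simulate_unfolding_curve(29.9, 5, seed = 8)$signal,
                         c1$signal))
})

test_that("generators do not disturb the caller's RNG stream", {
  set.seed(123)
  before <- rnorm(3)
  set.seed(123)
  invisible(simulate_screen(screen_model(toy_reference(), depth = 10,
                                         seed = 1)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("the null model scores near zero everywhere", {
  ref <- toy_reference()
  screen <- simulate_screen(screen_model(ref, depth = 2000, seed = 19))
  scores <- enrichment_scores(screen$selected, screen$unselected)
  expect_lt(abs(mean(scores$score[scores$amino_acid != "*"], na.rm = TRUE)),
            0.02)
  expect_lt(sd(scores$score[scores$amino_acid != "*"], na.rm = TRUE), 0.1)
})

test_that("a planted ten-fold variant scores close to +1", {
  ref <- toy_reference()
  fit <- tibble::tibble(position = 7L, amino_acid = "V", fitness = 1)
  screen <- simulate_screen(screen_model(ref, fit, depth = 5000, seed = 29))
  scores <- combine_synonymous(
    enrichment_scores(screen$selected, screen$unselected))
  planted <- scores$score[scores$position == 7 & scores$amino_acid == "V"]
  expect_equal(planted, 1, tolerance = 0.05)
})

test_that("noiseless forward models lie exactly on the mean", {
  curve <- simulate_unfolding_curve(
    29.9, 5, noise = c(sigma_constant = 0, sigma_proportional = 0))
  b <- c(signal_unfolded = -4, slope_unfolded = 0.1,
         signal_folded = -16, slope_folded = 0.2)
  u <- curve$urea
  ff <- fraction_folded(u, 29.9, 5)
  expect_equal(curve$signal,
               (b[["signal_unfolded"]] + b[["slope_unfolded"]] * u) +
                 (b[["signal_folded"]] + b[["slope_folded"]] * u) * ff)
  # noiseless midpoint: folded component at half its amplitude at u = dG/m
  mid_signal <- (b[["signal_unfolded"]] + b[["slope_unfolded"]] * 29.9 / 5) +
    (b[["signal_folded"]] + b[["slope_folded"]] * 29.9 / 5) * 0.5
  expect_equal(stats::approx(u, curve$signal, xout = 29.9 / 5)$y, mid_signal,
               tolerance = 0.05)
  d <- simulate_decay_series(10, 0.3, 1:8, noise_fraction = 0)
  expect_equal(d$value, 10 * exp(-0.3 * (1:8)))
  # k = 0 gives a flat series that the fitter refuses to keep
  flat <- simulate_decay_series(10, 0, 1:8, noise_fraction = 0)
  expect_false(fit_exponential(flat)$kept)
})

test_that("simulated databases drive the ROC stage as planted", {
  truth_tbl <- tidyr::expand_grid(position = 2:41, mut_aa = AA20) |>
    dplyr::mutate(wt_aa = "G")
  withr::with_seed(43, truth_tbl$fitness <- rnorm(nrow(truth_tbl), 0, 1))
  dbs <- simulate_variant_databases(truth_tbl, threshold = 1.5, seed = 43)
  expect_true(all(dbs$tp_db$count >= 1))
  expect_true(all(dbs$tn_db$pathogenic == 0))
  # clean labels + min_count 1: AUC on the true fitness is exactly 1
  truth <- assemble_truth(dbs$tp_db, dbs$tn_db, min_count = 1)
  scores <- tibble::tibble(
    variant = variant_id(truth_tbl$position, truth_tbl$mut_aa,
                         truth_tbl$wt_aa),
    score = truth_tbl$fitness)
  expect_equal(roc_curve(scores, truth)$auc, 1)
  # heavy contamination pushes the AUC toward chance
  noisy <- simulate_variant_databases(truth_tbl, threshold = 1.5,
                                      contamination = 0.5, seed = 44)
  truth2 <- assemble_truth(noisy$tp_db, noisy$tn_db, min_count = 1)
  auc2 <- roc_curve(scores, truth2)$auc
  expect_lt(auc2, 0.75)
  # a count law keeping every positive below the cutoff degenerates truth
  low <- simulate_variant_databases(truth_tbl, threshold = 1.5,
                                    count_mu = 0.01, count_size = 100,
                                    seed = 45)
  expect_error(assemble_truth(low$tp_db, low$tn_db, min_count = 5),
               class = "satmut_degenerate_truth")
})
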