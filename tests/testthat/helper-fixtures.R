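# Shared fixtures: all built in code, no files.

AA20 <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")

# 40-residue toy construct (5 distinct codons repeated), residues 2-41
toy_reference <- function(n_repeats = 8, first_residue_number = 2L) {
  coding_sequence(paste(rep(c("GGC", "CAA", "TTG", "AAA", "GAT"), n_repeats),
                        collapse = ""),
                  id = "toy", first_residue_number = first_residue_number)
}

# count-table pair built directly from per-variant ratios; WT allele counts
# chosen so their selected/unselected ratios are exactly `wt_ratios`
toy_count_pair <- function(variants, wt_ratios, unsel_base = 100) {
  wt_unsel <- rep(unsel_base, length(wt_ratios))
  wt <- function(cnt) tibble::tibble(
    allele = paste0("wt", seq_along(wt_ratios)), count = cnt)
  sel <- variant_counts(variants$sel, wt(wt_unsel * wt_ratios), "sel")
  unsel <- variant_counts(variants$unsel, wt(wt_unsel), "unsel")
  list(selected = sel, unselected = unsel)
}

# long-form variant tibble helper
vrows <- function(position, codon, count) {
  tibble::tibble(
    position = position, codon = codon,
    amino_acid = vapply(codon, translate_codon, character(1),
                        USE.NAMES = FALSE),
    count = count)
}

# a realistic continuous fitness mixture for a leaky bacterial screen:
# 40% deleterious (uniform on [-4, -1] log10 units), the rest near-neutral
leaky_fitness <- function(reference, seed = 7) {
  tbl <- tidyr::expand_grid(position = reference$positions, amino_acid = AA20)
  withr::with_seed(seed, {
    del <- runif(nrow(tbl)) < 0.4
    tbl$fitness <- ifelse(del, runif(nrow(tbl), -4, -1),
                          rnorm(nrow(tbl), 0, 0.3))
  })
  tbl
}

# centered score matrix with normal scores at every (position, aa) cell
random_score_matrix <- function(positions, seed = 1, sd = 1) {
  tbl <- tidyr::expand_grid(position = positions, amino_acid = AA20)
  withr::with_seed(seed, tbl$score <- rnorm(nrow(tbl), 0, sd))
  tbl
}

make_exchange_fit <- function(r_squared, k = 1, kept = NULL) {
  structure(list(id = "x", amplitude = 1, rate_k_obs = k, offset = 0,
                 tau = 1 / k, r_squared = r_squared,
                 kept = kept %||% (r_squared > 0.7 && k > 0),
                 diagnostic = NA_character_, n_points = 10),
            class = "exchange_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
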