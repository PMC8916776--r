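#' Relative enrichment scoring
#'
#' The central statistic of a selection screen is the relative enrichment
#' score of each variant x at position i,
#'
#'   dE_xi = log10(c_xi,sel / c_xi,unsel) - median(log10(Cwt,sel / Cwt,unsel))
#'
#' where the median runs over the synonymous wild-type alleles -- library DNA
#' sequences that differ from the template but translate to the wild-type
#' protein.  A variant behaving like the wild-type median scores 0; scores of
#' +1 / -1 correspond to ten-fold faster / slower propagation.  Centering on
#' the median of >100 internal-null alleles is robust to outliers, unlike the
#' legacy single-reference-sequence centering (see [legacy_enrichment()]).
#'
#' @name enrichment-scoring
NULL

apply_pseudocount <- function(sel, unsel, pseudocount) {
  if (identical(pseudocount, "drop")) {
    keep <- sel > 0 & unsel > 0
    list(sel = ifelse(keep, sel, NA_real_),
         unsel = ifelse(keep, unsel, NA_real_))
  } else {
    stopifnot(is.numeric(pseudocount), pseudocount >= 0)
    list(sel = sel + pseudocount, unsel = unsel + pseudocount)
  }
}

#' Wild-type normalizer term
#'
#' Median of the per-allele log10 selected/unselected count ratios over the
#' synonymous wild-type alleles, joined by allele identity.
#'
#' @param selected,unselected [variant_counts()] objects sharing wild-type
#'   allele identities.
#' @param pseudocount Added to every count before forming ratios (default 1),
#'   or `"drop"` to discard alleles with a zero count in either sample.
#' @return A list with `median_log_ratio` and `n_wt_alleles`.
#' @export
wt_normalizer <- function(selected, unselected, pseudocount = 1) {
  stopifnot(inherits(selected, "variant_counts"),
            inherits(unselected, "variant_counts"))
  joined <- inner_join(selected$wt_alleles, unselected$wt_alleles,
                       by = "allele", suffix = c("_sel", "_unsel"))
  if (nrow(joined) == 0L) {
    abort("No shared synonymous wild-type alleles: cannot form normalizer.",
          class = "satmut_missing_normalizer")
  }
  pc <- apply_pseudocount(joined$count_sel, joined$count_unsel, pseudocount)
  ratios <- log10(pc$sel / pc$unsel)
  ratios <- ratios[is.finite(ratios)]
  if (length(ratios) == 0L) {
    abort("All wild-type allele ratios undefined after zero handling.",
          class = "satmut_missing_normalizer")
  }
  list(median_log_ratio = median(ratios), n_wt_alleles = length(ratios))
}

#' Codon-level enrichment scores
#'
#' Applies the synonymous-wild-type-normalised enrichment formula to a
#' selected/unselected pair of count tables.  Variants absent from the
#' unselected sample cannot be scored and are flagged missing (`NA`), not
#' errored.
#'
#' @inheritParams wt_normalizer
#' @param baseline_correct If `TRUE`, apply the stop-codon baseline
#'   correction ([baseline_correct_counts()]) to the selected counts first.
#' @param floor Floor for non-positive baseline-corrected counts (passed on).
#' @return A tibble with columns `position`, `codon`, `amino_acid`, `score`
#'   (`NA` = not represented), carrying a `normalization` attribute that
#'   records the applied steps.
#' @export
enrichment_scores <- function(selected, unselected, baseline_correct = FALSE,
                              pseudocount = 1, floor = 1) {
  record <- list()
  if (isTRUE(baseline_correct)) {
    selected <- baseline_correct_counts(selected, unselected, floor = floor)
    record <- attr(selected, "baseline_record") %||%
      list(baseline_corrected = TRUE)
  }
  norm <- wt_normalizer(selected, unselected, pseudocount = pseudocount)
  joined <- full_join(
    selected$counts, unselected$counts,
    by = c("position", "codon", "amino_acid"), suffix = c("_sel", "_unsel"))
  # absent from one sample = not represented, distinct from an explicit zero
  missing <- is.na(joined$count_sel) | is.na(joined$count_unsel)
  pc <- apply_pseudocount(joined$count_sel, joined$count_unsel, pseudocount)
  score <- log10(pc$sel / pc$unsel) - norm$median_log_ratio
  score[missing | !is.finite(score)] <- NA_real_
  out <- tibble(position = joined$position, codon = joined$codon,
                amino_acid = joined$amino_acid, score = score) |>
    arrange(.data$position, .data$codon)
  attr(out, "normalization") <- c(record, list(
    method = "wt_median", pseudocount = pseudocount,
    median_log_ratio = norm$median_log_ratio,
    n_wt_alleles = norm$n_wt_alleles))
  out
}

#' Legacy enrichment scores (single-reference centering)
#'
#' The traditional calculation centers each variant's log ratio on the count
#' ratio of the wild-type reference DNA sequence alone.  It relies on a
#' single data point, so a sequencing or counting fluctuation in that one
#' allele shifts every score -- the fragility the wild-type-median normalizer
#' is designed to remove.  Within one dataset the two scores differ by a
#' constant (median minus reference term).
#'
#' @inheritParams wt_normalizer
#' @param wt_reference_counts Length-2 numeric, counts of the reference DNA
#'   sequence in the selected and unselected samples; both must be positive.
#' @inherit enrichment_scores return
#' @export
legacy_enrichment <- function(selected, unselected, wt_reference_counts,
                              pseudocount = 1) {
  stopifnot(is.numeric(wt_reference_counts), length(wt_reference_counts) == 2L)
  if (any(wt_reference_counts <= 0)) {
    abort("Reference-sequence count is zero: legacy centering undefined.",
          class = "satmut_zero_reference")
  }
  ref_term <- log10(wt_reference_counts[1] / wt_reference_counts[2])
  joined <- full_join(
    selected$counts, unselected$counts,
    by = c("position", "codon", "amino_acid"), suffix = c("_sel", "_unsel"))
  missing <- is.na(joined$count_sel) | is.na(joined$count_unsel)
  pc <- apply_pseudocount(joined$count_sel, joined$count_unsel, pseudocount)
  score <- log10(pc$sel / pc$unsel) - ref_term
  score[missing | !is.finite(score)] <- NA_real_
  out <- tibble(position = joined$position, codon = joined$codon,
                amino_acid = joined$amino_acid, score = score) |>
    arrange(.data$position, .data$codon)
  attr(out, "normalization") <- list(method = "legacy_reference",
                                     pseudocount = pseudocount,
                                     reference_log_ratio = ref_term)
  out
}

#' Stop-codon baseline correction of selected counts
#'
#' In leaky selections, cells carrying a null variant still grow at some
#' basal rate (leaky expression of the resistance gene), so every selected
#' count contains a null-growth component.  The stop-codon variants estimate
#' it: the median stop-codon selected/unselected ratio, x_f, times each
#' variant's unselected count is subtracted from its selected count,
#'
#'   c_corrected,sel = c_sel - c_unsel * x_f.
#'
#' Non-positive corrected counts (stop codons themselves land here) are
#' floored.  Before the correction a leaky screen's score distribution is
#' bimodal (null peak plus functional peak); after it, unimodal.  The
#' correction cannot be applied when stop variants grow like everything else
#' (no stop-codon signal), in which case it errors so the caller can skip it.
#'
#' @inheritParams wt_normalizer
#' @param floor Replacement for corrected counts `<= 0` (default 1).
#' @return A `variant_counts` object with corrected (possibly fractional)
#'   selected counts.
#' @export
baseline_correct_counts <- function(selected, unselected, floor = 1) {
  stopifnot(inherits(selected, "variant_counts"),
            inherits(unselected, "variant_counts"))
  stops <- inner_join(stop_counts(selected), stop_counts(unselected),
                      by = c("position", "codon", "amino_acid"),
                      suffix = c("_sel", "_unsel")) |>
    filter(.data$count_unsel > 0)
  if (nrow(stops) == 0L) {
    abort("No stop-codon variants with nonzero unselected counts: baseline correction unavailable.",
          class = "satmut_no_stop_codons")
  }
  x_f <- median(stops$count_sel / stops$count_unsel)
  joined <- left_join(selected$counts, unselected$counts,
                      by = c("position", "codon", "amino_acid"),
                      suffix = c("_sel", "_unsel"))
  corrected <- joined$count_sel - joined$count_unsel * x_f
  corrected[is.na(joined$count_unsel)] <- joined$count_sel[is.na(joined$count_unsel)]
  n_floored <- sum(corrected <= 0, na.rm = TRUE)
  corrected[!is.na(corrected) & corrected <= 0] <- floor
  out <- variant_counts(
    tibble(position = joined$position, codon = joined$codon,
           amino_acid = joined$amino_acid, count = corrected),
    selected$wt_alleles, sample_id = selected$sample_id,
    total_reads = selected$total_reads,
    n_multi_codon = selected$n_multi_codon,
    n_unreadable = selected$n_unreadable)
  attr(out, "baseline_record") <- list(baseline_corrected = TRUE,
                                       stop_median_ratio = x_f,
                                       n_stop_variants = nrow(stops),
                                       n_floored = n_floored, floor = floor)
  out
}

#' Combine synonymous codons into amino-acid scores
#'
#' Unweighted mean of the non-missing codon-level scores for each
#' (position, amino acid); a cell whose codons are all missing stays missing.
#'
#' @param codon_scores Codon-level score tibble from [enrichment_scores()].
#' @return Amino-acid-level tibble (`position`, `amino_acid`, `score`).
#' @export
combine_synonymous <- function(codon_scores) {
  record <- attr(codon_scores, "normalization")
  out <- codon_scores |>
    group_by(.data$position, .data$amino_acid) |>
    summarise(score = if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
              .groups = "drop") |>
    arrange(.data$position, .data$amino_acid)
  attr(out, "normalization") <- c(record, list(synonymous_combined = "mean"))
  out
}

#' Kernel-density mode estimate
#'
#' Gaussian kernel density (plug-in bandwidth, 512-point grid) argmax;
#' deterministic and robust for the shouldered distributions of wild-type
#' allele scores.
#'
#' @param x Numeric vector (NAs dropped), length >= 3.
#' @export
estimate_mode <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3L) {
    abort("Need >= 3 values to estimate a mode.", class = "satmut_degenerate")
  }
  if (sd(x) == 0) return(x[1])
  d <- density(x, n = 512)
  d$x[which.max(d$y)]
}

#' Center on the wild-type mode and scale to a common spread
#'
#' Subtracts the mode of the synonymous wild-type allele scores (so that
#' wild-type-like behaviour sits at 0), then rescales all scores so that the
#' standard deviation of the substitution scores equals `target_sd`,
#' making distributions comparable across datasets.
#'
#' @param scores Score tibble (codon- or amino-acid-level).
#' @param wt_scores Numeric vector of synonymous wild-type allele scores
#'   (length >= 3) computed under the same normalization.
#' @param target_sd Common standard deviation after scaling (default 1).
#' @param exclude_stop Exclude the stop row from the sd used for scaling
#'   (default `TRUE`; the spread describes amino-acid substitutions).
#' @return The score tibble, centered and scaled, with the `normalization`
#'   attribute extended.
#' @export
center_and_scale <- function(scores, wt_scores, target_sd = 1,
                             exclude_stop = TRUE) {
  stopifnot(is.numeric(target_sd), target_sd > 0)
  mode_wt <- estimate_mode(wt_scores)
  shifted <- scores$score - mode_wt
  basis <- shifted[!is.na(shifted)]
  if (exclude_stop && "amino_acid" %in% names(scores)) {
    basis <- shifted[!is.na(shifted) & scores$amino_acid != "*"]
  }
  s <- sd(basis)
  if (!is.finite(s) || s == 0) {
    abort("Score distribution has zero spread: cannot scale.",
          class = "satmut_degenerate")
  }
  out <- mutate(scores, score = (shifted) * target_sd / s)
  attr(out, "normalization") <- c(attr(scores, "normalization"),
                                  list(centered_mode = mode_wt,
                                       scale_factor = target_sd / s,
                                       target_sd = target_sd,
                                       sd_excludes_stop = exclude_stop))
  out
}

#' Count the modes of a score distribution
#'
#' Kernel-density mode count with a prominence criterion: a local maximum
#' counts as a mode only if it rises at least `min_prominence` (as a
#' fraction of the maximum density) above the deepest valley separating it
#' from a higher peak.  Used to characterise the bimodal-to-unimodal change
#' a leaky screen's score distribution undergoes under the stop-codon
#' baseline correction.
#'
#' @param x Numeric vector (NAs dropped).
#' @param min_prominence Fraction of the maximum density a secondary peak
#'   must clear (default 0.5).
#' @return Integer number of modes.
#' @export
count_modes <- function(x, min_prominence = 0.5) {
  x <- x[!is.na(x)]
  if (length(x) < 10 || sd(x) == 0) return(1L)
  d <- density(x, n = 512)
  y <- d$y / max(d$y)
  peaks <- which(diff(sign(diff(y))) == -2) + 1
  if (length(peaks) <= 1) return(length(peaks))
  prom <- vapply(peaks, function(p) {
    higher <- peaks[y[peaks] > y[p]]
    if (!length(higher)) return(1)  # the global mode
    y[p] - max(vapply(higher, function(o) min(y[min(p, o):max(p, o)]),
                      numeric(1)))
  }, numeric(1))
  sum(prom >= min_prominence)
}

#' Per-position mean substitution score
#'
#' The column means of the fitness heatmap: average over the non-missing
#' amino-acid substitution scores at each position, stop row excluded.
#'
#' @param scores Amino-acid-level score tibble.
#' @return Tibble with `position`, `mean_score`, `n_substitutions`.
#' @export
position_means <- function(scores) {
  scores |>
    filter(.data$amino_acid != "*") |>
    group_by(.data$position) |>
    summarise(mean_score = if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
              n_substitutions = sum(!is.na(.data$score)),
              .groups = "drop") |>
    arrange(.data$position)
}

#' Average replicate score tables cell-wise
#'
#' Scores are computed per biological replicate, then averaged per
#' (position, amino acid or codon) cell; a cell missing in one replicate is
#' averaged over the replicates where it is defined.
#'
#' @param ... Two or more score tibbles on the same keys.
#' @export
average_replicates <- function(...) {
  reps <- list(...)
  stopifnot(length(reps) >= 2L)
  keys <- intersect(c("position", "codon", "amino_acid"), names(reps[[1]]))
  bind_rows(reps) |>
    group_by(across(dplyr::all_of(keys))) |>
    summarise(score = if (all(is.na(.data$score))) NA_real_
              else mean(.data$score, na.rm = TRUE),
              .groups = "drop")
}

#' Write / read a score table as delimited text
#'
#' Long-form tab-separated table (`position`, `amino_acid` (and `codon` if
#' codon-level), `score`) plus a key-value sidecar `<path>.meta.txt` carrying
#' the normalization record.
#'
#' @param scores Score tibble.
#' @param path Output path.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- attr(scores, "normalization")
  if (!is.null(rec)) {
    lines <- vapply(seq_along(rec), function(i) {
      paste0(names(rec)[i], "=", paste(format(rec[[i]]), collapse = ","))
    }, character(1))
    writeLines(lines, paste0(path, ".meta.txt"))
  }
  invisible(path)
}

#' @rdname write_scores
#' @export
read_scores <- function(path) {
  out <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
  meta_path <- paste0(path, ".meta.txt")
  if (file.exists(meta_path)) {
    lines <- readLines(meta_path)
    kv <- strsplit(lines, "=", fixed = TRUE)
    rec <- lapply(kv, function(p) paste(p[-1], collapse = "="))
    names(rec) <- vapply(kv, `[[`, character(1), 1L)
    attr(out, "normalization") <- rec
  }
  out
}

AA_ORDER <- c("D", "E", "K", "H", "R", "G", "N", "Q", "S", "T", "A", "C",
              "F", "I", "L", "M", "P", "V", "W", "Y", "*")

#' Fitness heatmap of an enrichment score table
#'
#' Amino acids on the vertical axis (grouped by chemistry, stop last),
#' positions on the horizontal; missing cells drawn in green as
#' "not represented".
#'
#' @param scores Amino-acid-level score tibble.
#' @param limits Symmetric colour limits; default from the data.
#' @return A ggplot object.
#' @export
plot_enrichment_heatmap <- function(scores, limits = NULL) {
  if (is.null(limits)) {
    m <- max(abs(scores$score), na.rm = TRUE)
    limits <- c(-m, m)
  }
  scores$amino_acid <- factor(scores$amino_acid,
                              levels = rev(intersect(AA_ORDER,
                                                     unique(scores$amino_acid))))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data$position, y = .data$amino_acid,
                               fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = limits, na.value = "darkgreen") +
    ggplot2::labs(x = "residue", y = "substitution", fill = "ΔE") +
    ggplot2::theme_minimal()
}
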