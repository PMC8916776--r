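#' Construct epistasis: pairwise score differences
#'
#' Comparing the fitness landscape of a destabilised (shorter) construct with
#' a stabilised (longer) one isolates mutations whose phenotype depends on
#' the thermodynamic stability of the protein.  The per-cell difference
#'
#'   ddE_xi = dE_xi(short) - dE_xi(long)
#'
#' and its per-position average over the defined substitutions quantify this
#' construct epistasis.  Cells missing in either matrix stay missing;
#' positions with no defined entries are dropped from the means.
#'
#' @param short_scores,long_scores Amino-acid-level score tibbles on a
#'   shared position range (the intersection is used), comparably centered
#'   and scaled.
#' @param dataset_pair Optional length-2 character labels.
#' @return An `epistasis_result`: list with `delta` (tibble `position`,
#'   `amino_acid`, `delta`), `position_means` (tibble `position`,
#'   `mean_delta`, `n_substitutions`; stop row excluded) and `dataset_pair`.
#' @export
pairwise_epistasis <- function(short_scores, long_scores,
                               dataset_pair = c("short", "long")) {
  joined <- inner_join(short_scores, long_scores,
                       by = c("position", "amino_acid"),
                       suffix = c("_short", "_long"))
  if (nrow(joined) == 0L) {
    abort("Score tables share no (position, amino acid) cells.",
          class = "satmut_empty_overlap")
  }
  delta <- joined |>
    mutate(delta = .data$score_short - .data$score_long) |>
    select("position", "amino_acid", "delta") |>
    arrange(.data$position, .data$amino_acid)
  pos_means <- delta |>
    filter(.data$amino_acid != "*") |>
    group_by(.data$position) |>
    summarise(mean_delta = if (all(is.na(.data$delta))) NA_real_
              else mean(.data$delta, na.rm = TRUE),
              n_substitutions = sum(!is.na(.data$delta)),
              .groups = "drop") |>
    filter(.data$n_substitutions > 0)
  structure(list(delta = delta, position_means = pos_means,
                 dataset_pair = dataset_pair),
            class = "epistasis_result")
}

#' @export
print.epistasis_result <- function(x, ...) {
  cat(sprintf("<epistasis_result> %s - %s: %d cells, %d positions\n",
              x$dataset_pair[1], x$dataset_pair[2], sum(!is.na(x$delta$delta)),
              nrow(x$position_means)))
  invisible(x)
}

#' @export
tidy.epistasis_result <- function(x, ...) x$delta

#' @export
glance.epistasis_result <- function(x, ...) {
  tibble(n_cells = sum(!is.na(x$delta$delta)),
         n_positions = nrow(x$position_means),
         mean_abs_delta = mean(abs(x$delta$delta), na.rm = TRUE))
}

#' @export
autoplot.epistasis_result <- function(object, ...) {
  ggplot2::ggplot(object$position_means,
                  ggplot2::aes(x = .data$position, y = .data$mean_delta)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "residue", y = "mean ΔΔE (short - long)") +
    ggplot2::theme_minimal()
}

matrix_sd <- function(scores, exclude_stop = TRUE) {
  x <- scores$score
  if (exclude_stop) x <- x[scores$amino_acid != "*"]
  sd(x, na.rm = TRUE)
}

#' Activating variants by the k-sigma rule
#'
#' A substitution is called activating when its score exceeds `k` times the
#' standard deviation of the (centered) score distribution -- the
#' conventional 1.5-sigma gain-of-function threshold.  The sd is computed
#' over all non-missing substitution scores of the matrix, stop row excluded.
#'
#' @param scores Centered amino-acid-level score tibble.
#' @param k Multiplier on the standard deviation (default 1.5).
#' @return Tibble of activating rows with an extra `threshold` column.
#' @export
activating_variants <- function(scores, k = 1.5) {
  thr <- k * matrix_sd(scores)
  scores |>
    filter(!is.na(.data$score), .data$amino_acid != "*",
           .data$score > thr) |>
    mutate(threshold = thr)
}

#' Classify activating and stability-dependent gain-of-function sites
#'
#' A site is a stability-dependent gain-of-function site when at least one
#' substitution is activating (k-sigma rule) in the long (stable) construct
#' but that same substitution is not activating in the short (destabilised)
#' construct: the activation only manifests when the protein can absorb the
#' mutation's destabilisation.  Per-variant labels record where each
#' substitution activates; substitutions below `-k * sd` in the long
#' construct are labelled deleterious, the remainder neutral.
#'
#' @inheritParams pairwise_epistasis
#' @param k Threshold multiplier (default 1.5); each matrix uses its own sd.
#' @return A `site_classification`: list with `activating_sites` (positions
#'   with >= 1 long-activating substitution), `stability_dependent_sites`,
#'   and `per_variant_labels` (tibble `position`, `amino_acid`, `label`).
#' @export
classify_sites <- function(short_scores, long_scores, k = 1.5) {
  thr_short <- k * matrix_sd(short_scores)
  thr_long <- k * matrix_sd(long_scores)
  joined <- full_join(short_scores, long_scores,
                      by = c("position", "amino_acid"),
                      suffix = c("_short", "_long")) |>
    filter(.data$amino_acid != "*")
  act_short <- !is.na(joined$score_short) & joined$score_short > thr_short
  act_long <- !is.na(joined$score_long) & joined$score_long > thr_long
  label <- dplyr::case_when(
    act_short & act_long ~ "activating_both",
    act_long ~ "activating_long",
    act_short ~ "activating_short",
    !is.na(joined$score_long) & joined$score_long < -thr_long ~ "deleterious",
    TRUE ~ "neutral")
  labels <- tibble(position = joined$position,
                   amino_acid = joined$amino_acid, label = label)
  activating_sites <- sort(unique(joined$position[act_long]))
  stability_dependent <- sort(unique(joined$position[act_long & !act_short]))
  structure(list(activating_sites = activating_sites,
                 stability_dependent_sites = stability_dependent,
                 per_variant_labels = labels,
                 thresholds = c(short = thr_short, long = thr_long), k = k),
            class = "site_classification")
}

#' @export
print.site_classification <- function(x, ...) {
  cat(sprintf(
    "<site_classification> %d activating sites (long construct), %d stability-dependent\n",
    length(x$activating_sites), length(x$stability_dependent_sites)))
  invisible(x)
}

#' @export
tidy.site_classification <- function(x, ...) x$per_variant_labels
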