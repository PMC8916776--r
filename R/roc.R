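#' Variant databases and truth sets
#'
#' Variant databases emulate COSMIC-like (cancer) and gnomAD-like
#' (population, presumed benign) extracts as plain tables with columns
#' `isoform`, `position`, `wt_aa`, `mut_aa`, `count` and optionally
#' `pathogenic` (0/1).  Variants are identified by `wt_aa`-`position`-`mut_aa`
#' (e.g. "G12V"); counts from multiple isoforms can be pooled or kept
#' separate.
#'
#' @name variant-databases
NULL

#' Canonical variant identifier
#' @param position Residue number.
#' @param mut_aa Substituting amino acid.
#' @param wt_aa Wild-type amino acid (optional).
#' @export
variant_id <- function(position, mut_aa, wt_aa = NULL) {
  if (is.null(wt_aa)) paste0(position, mut_aa)
  else paste0(wt_aa, position, mut_aa)
}

db_variant_ids <- function(db) {
  wt <- if ("wt_aa" %in% names(db)) db$wt_aa else NULL
  variant_id(db$position, db$mut_aa, wt)
}

#' Read a variant database from delimited text
#' @param path Tab- or comma-separated file with columns `isoform`,
#'   `position`, `wt_aa`, `mut_aa`, `count` and optionally `pathogenic`.
#' @export
read_variant_db <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  as_tibble(utils::read.table(path, header = TRUE, sep = sep,
                              stringsAsFactors = FALSE))
}

#' Filter database variants by observation count
#'
#' Keeps variants observed at least `min_count` times in at least one
#' isoform.  The inclusive five-count cutoff removes low-frequency database
#' entries that may not be pathogenic.
#'
#' @param db Variant database tibble.
#' @param min_count Minimum observation count (default 5, inclusive).
#' @param pool_isoforms If `TRUE` (default) sum counts over isoforms before
#'   applying the cutoff; if `FALSE` a variant qualifies if any single
#'   isoform reaches the cutoff.
#' @return Character vector of qualifying variant ids.
#' @export
filter_by_count <- function(db, min_count = 5, pool_isoforms = TRUE) {
  ids <- db_variant_ids(db)
  tb <- tibble(variant = ids, isoform = db$isoform %||% "pooled",
               count = db$count)
  per <- if (pool_isoforms) {
    tb |> group_by(.data$variant) |>
      summarise(best = sum(.data$count), .groups = "drop")
  } else {
    tb |> group_by(.data$variant, .data$isoform) |>
      summarise(count = sum(.data$count), .groups = "drop") |>
      group_by(.data$variant) |>
      summarise(best = max(.data$count), .groups = "drop")
  }
  sort(per$variant[per$best >= min_count])
}

#' Assemble a labelled truth set from two databases
#'
#' Positives are the count-filtered variants of the cancer-like database.
#' Negatives are the population-database variants minus any flagged
#' pathogenic and minus the positives (a variant found in both databases is
#' a true positive: some pathogenic variants occur unlabelled in population
#' cohorts).  Variants in neither set are unlabelled and excluded from ROC
#' analysis rather than treated as negatives.
#'
#' @param tp_db Cancer-like database tibble (true-positive source).
#' @param tn_db Population-like database tibble (true-negative source),
#'   optionally with a `pathogenic` column.
#' @inheritParams filter_by_count
#' @return A `variant_truth` object: list with character vectors `positives`
#'   and `negatives` (disjoint).
#' @export
assemble_truth <- function(tp_db, tn_db, min_count = 5, pool_isoforms = TRUE) {
  positives <- filter_by_count(tp_db, min_count, pool_isoforms)
  tn_ids <- db_variant_ids(tn_db)
  if ("pathogenic" %in% names(tn_db)) {
    flagged <- unique(tn_ids[tn_db$pathogenic > 0])
    tn_ids <- setdiff(tn_ids, flagged)
  }
  negatives <- sort(setdiff(unique(tn_ids), positives))
  if (length(positives) == 0L || length(negatives) == 0L) {
    abort("Degenerate truth set: one class is empty.",
          class = "satmut_degenerate_truth")
  }
  variant_truth(positives, negatives)
}

#' @rdname assemble_truth
#' @param positives,negatives Disjoint character vectors of variant ids.
#' @export
variant_truth <- function(positives, negatives) {
  positives <- unique(positives)
  negatives <- unique(negatives)
  if (length(intersect(positives, negatives))) {
    abort("Truth classes overlap.", class = "satmut_degenerate_truth")
  }
  structure(list(positives = positives, negatives = negatives),
            class = "variant_truth")
}

#' @export
print.variant_truth <- function(x, ...) {
  cat(sprintf("<variant_truth> %d positives, %d negatives\n",
              length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Truth set from a reference score matrix
#'
#' Labels the scored variants of a centered reference matrix: those above
#' `k` standard deviations are activating (true positives), the rest are
#' true negatives.  Used when one screen's scores define the truth another
#' screen is benchmarked against.
#'
#' @param reference_scores Centered amino-acid-level score tibble.
#' @param k Threshold multiplier (default 1.5).
#' @export
truth_from_scores <- function(reference_scores, k = 1.5) {
  act <- activating_variants(reference_scores, k = k)
  scored <- filter(reference_scores, !is.na(.data$score),
                   .data$amino_acid != "*")
  pos <- variant_id(act$position, act$amino_acid)
  all_ids <- variant_id(scored$position, scored$amino_acid)
  variant_truth(pos, setdiff(all_ids, pos))
}

#' ROC curve and AUC for variant scores against a truth set
#'
#' Sweeps a decision threshold over every distinct score value (higher score
#' predicts activating/pathogenic) and records the true- and false-positive
#' fractions, giving the full staircase from (0,0) to (1,1).  The area under
#' the curve is computed by the trapezoidal rule, so tied scores contribute
#' half weight and the AUC equals the pairwise rank statistic
#' (#correctly ordered pairs + half the ties) / (|P|*|N|).  Truth variants
#' without a score are dropped with a message.
#'
#' @param scores Tibble with columns `variant` and `score`, or an
#'   amino-acid-level score tibble (`position`, `amino_acid`, `score`) whose
#'   variant ids are formed as position + amino acid.
#' @param truth A [variant_truth()] object.
#' @return A `roc_curve` object: `points` tibble (`threshold`, `fpr`, `tpr`),
#'   `auc`, and the class sizes used.
#' @export
roc_curve <- function(scores, truth) {
  stopifnot(inherits(truth, "variant_truth"))
  if (!"variant" %in% names(scores)) {
    scores <- tibble(variant = variant_id(scores$position, scores$amino_acid),
                     score = scores$score)
  }
  scores <- filter(scores, !is.na(.data$score))
  lookup <- setNames(scores$score, scores$variant)
  pos <- truth$positives[truth$positives %in% names(lookup)]
  neg <- truth$negatives[truth$negatives %in% names(lookup)]
  n_drop <- length(truth$positives) + length(truth$negatives) -
    length(pos) - length(neg)
  if (n_drop > 0) {
    message(n_drop, " truth variants without a score dropped from ROC.")
  }
  if (length(pos) == 0L || length(neg) == 0L) {
    abort("Degenerate truth set after intersecting with scores.",
          class = "satmut_degenerate_truth")
  }
  sp <- unname(lookup[pos])
  sn <- unname(lookup[neg])
  thresholds <- c(Inf, sort(unique(c(sp, sn)), decreasing = TRUE))
  tpr <- vapply(thresholds, function(t) mean(sp >= t), numeric(1))
  fpr <- vapply(thresholds, function(t) mean(sn >= t), numeric(1))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(list(points = tibble(threshold = thresholds, fpr = fpr, tpr = tpr),
                 auc = auc, n_positive = length(pos), n_negative = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> AUC = %.3f (%d positives, %d negatives)\n",
              x$auc, x$n_positive, x$n_negative))
  invisible(x)
}

#' @export
tidy.roc_curve <- function(x, ...) x$points

#' @export
glance.roc_curve <- function(x, ...) {
  tibble(auc = x$auc, n_positive = x$n_positive, n_negative = x$n_negative)
}

#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false-positive fraction", y = "true-positive fraction",
                  subtitle = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
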