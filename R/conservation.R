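#' Sequence conservation by Shannon entropy
#'
#' Column-wise Shannon entropy of a multiple sequence alignment, in bits:
#' H = -sum_a p_a log2 p_a over amino-acid frequencies.  A fully conserved
#' column scores 0; a uniform 20-residue column scores log2(20) ~ 4.32 bits.
#' Columns are mapped to reference residue numbering through the ungapped
#' positions of a designated reference row.
#'
#' @name conservation
NULL

GAP_CHARS <- c("-", ".")

#' Load an aligned FASTA into an alignment object
#'
#' @param path Aligned FASTA (equal-length gapped sequences).
#' @param reference_id Name (or unique prefix) of the reference row used to
#'   map columns to residue numbers; default the first sequence.
#' @param first_residue_number Residue number of the reference row's first
#'   ungapped position (default 1).
#' @return An `msa_alignment` object.
#' @export
read_alignment <- function(path, reference_id = NULL,
                           first_residue_number = 1L) {
  seqs <- Biostrings::readAAStringSet(path)
  alignment(setNames(as.character(seqs), names(seqs)),
            reference_id = reference_id,
            first_residue_number = first_residue_number)
}

#' @rdname read_alignment
#' @param sequences Named character vector of equal-length gapped sequences.
#' @export
alignment <- function(sequences, reference_id = NULL,
                      first_residue_number = 1L) {
  stopifnot(length(sequences) >= 1)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    abort("Alignment rows differ in length.", class = "satmut_invalid_sequence")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("seq", seq_along(sequences))
  }
  if (is.null(reference_id)) reference_id <- names(sequences)[1]
  hit <- which(names(sequences) == reference_id)
  if (length(hit) == 0L) {
    hit <- grep(reference_id, names(sequences), fixed = TRUE)
  }
  if (length(hit) != 1L) {
    abort(sprintf("Reference id \"%s\" does not match exactly one row.",
                  reference_id),
          class = "satmut_invalid_sequence")
  }
  ref_chars <- strsplit(toupper(sequences[[hit]]), "")[[1]]
  ungapped <- which(!ref_chars %in% GAP_CHARS)
  column_map <- setNames(ungapped,
                         first_residue_number + seq_along(ungapped) - 1L)
  structure(list(sequences = toupper(sequences),
                 reference_id = names(sequences)[hit],
                 column_map = column_map,
                 n_columns = widths[1]),
            class = "msa_alignment")
}

#' @export
print.msa_alignment <- function(x, ...) {
  cat(sprintf("<msa_alignment> %d sequences x %d columns, reference %s (%d mapped residues)\n",
              length(x$sequences), x$n_columns, x$reference_id,
              length(x$column_map)))
  invisible(x)
}

#' Shannon entropy of one alignment column
#'
#' @param column Character vector of residue letters (one per sequence).
#' @param gap_policy `"exclude"` (default) drops gap characters from the
#'   frequency denominator; `"include"` treats the gap as a 21st symbol.
#' @return Entropy in bits, or `NA` for an all-gap column under `"exclude"`.
#' @export
column_entropy <- function(column, gap_policy = c("exclude", "include")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(length(column) >= 1)
  column <- toupper(column)
  if (gap_policy == "exclude") {
    column <- column[!column %in% GAP_CHARS]
    if (length(column) == 0L) return(NA_real_)
  } else {
    column[column %in% GAP_CHARS] <- "-"
  }
  p <- table(column) / length(column)
  -sum(p * log2(p))
}

#' Per-site entropies on reference numbering
#'
#' @param aln An [alignment()] object.
#' @param positions Reference residue numbers to report; default all mapped.
#' @inheritParams column_entropy
#' @return Tibble with `position`, `entropy_bits` (`NA` where the position is
#'   not covered by the reference row) and `n_ungapped`.
#' @export
site_entropies <- function(aln, positions = NULL,
                           gap_policy = c("exclude", "include")) {
  gap_policy <- match.arg(gap_policy)
  stopifnot(inherits(aln, "msa_alignment"))
  mapped <- as.integer(names(aln$column_map))
  if (is.null(positions)) positions <- mapped
  chars <- t(vapply(aln$sequences, function(s) strsplit(s, "")[[1]],
                    character(aln$n_columns)))
  rows <- map(positions, function(p) {
    if (!p %in% mapped) {
      return(tibble(position = p, entropy_bits = NA_real_,
                    n_ungapped = NA_integer_))
    }
    col <- chars[, aln$column_map[[as.character(p)]]]
    tibble(position = p,
           entropy_bits = column_entropy(col, gap_policy),
           n_ungapped = sum(!col %in% GAP_CHARS))
  })
  bind_rows(rows)
}
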