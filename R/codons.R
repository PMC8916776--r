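#' Codon utilities
#'
#' Helpers for working with codons under the standard genetic code:
#' translation, enumeration of single-nucleotide variant (SNV) neighbours,
#' and the minimal number of nucleotide changes needed to reach each amino
#' acid from a given codon.  Cancer mutations are overwhelmingly
#' single-nucleotide variants, so the set of amino acids reachable from the
#' wild-type codon by one base change constrains which substitutions are
#' observed in tumour databases.
#'
#' @name codon-utils
NULL

DNA_BASES <- c("A", "C", "G", "T")

check_codon <- function(codon) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon)) {
    abort(
      sprintf("`codon` must be a 3-letter string over A/C/G/T, got \"%s\".",
              paste(codon, collapse = ",")),
      class = "satmut_invalid_sequence"
    )
  }
  invisible(codon)
}

#' Translate a codon under the standard genetic code
#'
#' @param codon A 3-letter string over A/C/G/T.
#' @return A single amino-acid letter, with `"*"` for the three stop codons
#'   (TAA, TAG, TGA).
#' @examples
#' translate_codon("GGC")  # "G"
#' translate_codon("TAA")  # "*"
#' @export
translate_codon <- function(codon) {
  check_codon(codon)
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Translate an in-frame coding DNA string
#'
#' @param dna DNA string, length divisible by 3, alphabet A/C/G/T.
#' @return Character vector of amino-acid letters, one per codon.
#' @export
translate_dna <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  if (nchar(dna) %% 3L != 0L) {
    abort("DNA length must be divisible by 3.", class = "satmut_invalid_sequence")
  }
  codons <- split_codons(dna)
  vapply(codons, translate_codon, character(1), USE.NAMES = FALSE)
}

split_codons <- function(dna) {
  n <- nchar(dna) %/% 3L
  substring(dna, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

#' Enumerate the nine single-nucleotide variant codons
#'
#' Returns the codons at Hamming distance 1 from the input, in a
#' deterministic order: codon position major, alternative base alphabetical.
#'
#' @inheritParams translate_codon
#' @return Character vector of exactly 9 codons; never contains the input.
#' @examples
#' enumerate_snv_codons("GGC")
#' @export
enumerate_snv_codons <- function(codon) {
  check_codon(codon)
  bases <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (i in 1:3) {
    for (b in setdiff(DNA_BASES, bases[i])) {
      neighbour <- bases
      neighbour[i] <- b
      out <- c(out, paste(neighbour, collapse = ""))
    }
  }
  out
}

#' Minimal nucleotide changes from a codon to each amino acid
#'
#' For each of the 20 amino acids and stop (`"*"`), computes the minimum
#' Hamming distance from `wt_codon` to any codon encoding it.  Amino acids at
#' distance 1 are SNV-accessible; those needing 2 or 3 changes are
#' multiple-nucleotide variants, rarely seen in cancer databases.
#'
#' @param wt_codon The wild-type codon (3-letter A/C/G/T string).
#' @return A tibble with columns `amino_acid` and `min_changes` (0-3),
#'   one row per amino acid plus stop (21 rows).
#' @examples
#' snv_accessible_substitutions("GGC")
#' @export
snv_accessible_substitutions <- function(wt_codon) {
  check_codon(wt_codon)
  code <- Biostrings::GENETIC_CODE
  wt_bases <- strsplit(wt_codon, "")[[1]]
  dist <- vapply(names(code), function(cod) {
    sum(strsplit(cod, "")[[1]] != wt_bases)
  }, integer(1))
  tibble(amino_acid = unname(code), dist = unname(dist)) |>
    group_by(.data$amino_acid) |>
    summarise(min_changes = min(.data$dist), .groups = "drop") |>
    arrange(.data$min_changes, .data$amino_acid)
}
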