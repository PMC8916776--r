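#' Wild-type coding sequence
#'
#' Constructs the reference against which library reads are called.  Ras
#' constructs typically start at residue 2 (the initiator methionine is
#' removed), so `first_residue_number` records the residue number of the
#' first encoded codon and all variant positions are reported in that
#' numbering.
#'
#' @param dna Upper-case A/C/G/T string, length divisible by 3, no internal
#'   stop codon.
#' @param id Text label for the construct.
#' @param first_residue_number Residue number of the first codon (default 2,
#'   matching a 2-166 style construct).
#' @return A `coding_sequence` object.
#' @examples
#' ref <- coding_sequence("ATGGGCCAA", id = "toy", first_residue_number = 1)
#' ref$protein
#' @export
coding_sequence <- function(dna, id = "reference", first_residue_number = 2L) {
  stopifnot(is.character(dna), length(dna) == 1L)
  dna <- toupper(dna)
  if (grepl("[^ACGT]", dna)) {
    abort("Reference DNA may only contain A/C/G/T.",
          class = "satmut_invalid_sequence")
  }
  if (nchar(dna) %% 3L != 0L) {
    abort("Reference DNA length must be divisible by 3.",
          class = "satmut_invalid_sequence")
  }
  protein <- translate_dna(dna)
  if (any(protein == "*")) {
    abort("Reference contains an internal stop codon.",
          class = "satmut_invalid_sequence")
  }
  structure(
    list(
      id = id,
      dna = dna,
      codons = split_codons(dna),
      protein = protein,
      first_residue_number = as.integer(first_residue_number),
      positions = as.integer(first_residue_number) +
        seq_len(nchar(dna) %/% 3L) - 1L
    ),
    class = "coding_sequence"
  )
}

#' @export
print.coding_sequence <- function(x, ...) {
  cat(sprintf("<coding_sequence> %s: %d codons, residues %d-%d\n",
              x$id, length(x$codons), min(x$positions), max(x$positions)))
  invisible(x)
}

#' Read a reference coding sequence from FASTA
#'
#' @param path Path to a FASTA file; the first record is used.
#' @inheritParams coding_sequence
#' @export
read_coding_sequence <- function(path, first_residue_number = 2L) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    abort("FASTA file contains no sequences.", class = "satmut_empty_input")
  }
  coding_sequence(as.character(seqs[[1]]), id = names(seqs)[1],
                  first_residue_number = first_residue_number)
}

#' Read merged amplicon reads
#'
#' Accepts FASTQ (quality scores ignored; upstream tools are assumed to have
#' merged, trimmed and quality-filtered) or plain one-sequence-per-line text.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension), `"fastq"` or `"lines"`.
#' @return Character vector of read sequences.
#' @export
read_reads <- function(path, format = c("auto", "fastq", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q$", path, ignore.case = TRUE)) "fastq" else "lines"
  }
  if (format == "fastq") {
    as.character(Biostrings::readDNAStringSet(path, format = "fastq"))
  } else {
    toupper(trimws(readLines(path)))
  }
}
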