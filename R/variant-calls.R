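#' Call a single read against the reference
#'
#' Classifies one merged, trimmed read.  Saturation-mutagenesis libraries are
#' single-codon by design, so reads are sorted into four mutually exclusive
#' categories:
#'
#' * `wt_synonymous` -- translates exactly to the wild-type protein (this
#'   includes the template itself and every synonymous wild-type allele);
#' * `single_codon`  -- exactly one codon differs at the DNA level and the
#'   translation differs at that residue;
#' * `multi_codon`   -- two or more codons differ and the protein is not
#'   wild type (these cannot be attributed to one library variant and are
#'   excluded from counting);
#' * `unreadable`    -- length mismatch with the reference or ambiguous
#'   bases (N).
#'
#' @param read DNA string.
#' @param reference A [coding_sequence()].
#' @return A one-row tibble with columns `category`, `position`, `codon`,
#'   `amino_acid`; the last three are `NA` unless `category == "single_codon"`.
#' @export
call_variant <- function(read, reference) {
  stopifnot(inherits(reference, "coding_sequence"))
  out <- function(category, position = NA_integer_, codon = NA_character_,
                  amino_acid = NA_character_) {
    tibble(category = category, position = position, codon = codon,
           amino_acid = amino_acid)
  }
  read <- toupper(read)
  if (nchar(read) != nchar(reference$dna) || grepl("[^ACGT]", read)) {
    return(out("unreadable"))
  }
  read_codons <- split_codons(read)
  diff_idx <- which(read_codons != reference$codons)
  if (length(diff_idx) == 0L) return(out("wt_synonymous"))
  read_protein <- vapply(read_codons[diff_idx], translate_codon, character(1),
                         USE.NAMES = FALSE)
  aa_diff <- read_protein != reference$protein[diff_idx]
  if (!any(aa_diff)) return(out("wt_synonymous"))
  if (length(diff_idx) == 1L) {
    i <- diff_idx[1]
    return(out("single_codon",
               position = reference$positions[i],
               codon = read_codons[i],
               amino_acid = read_protein[1]))
  }
  out("multi_codon")
}

#' Build a variant count table from merged reads
#'
#' Tallies single-codon variants (stop codons included, amino acid `"*"`)
#' and synonymous wild-type alleles.  Reads with multiple non-attributable
#' changes or ambiguous bases are excluded and logged in the table's tallies.
#'
#' @param reads Character vector of merged, trimmed read sequences.
#' @inheritParams call_variant
#' @param sample_id Label stored with the table.
#' @return A [variant_counts()] object.
#' @export
count_variants <- function(reads, reference, sample_id = "sample") {
  if (length(reads) == 0L) {
    abort("No reads supplied.", class = "satmut_empty_input")
  }
  reads <- toupper(reads)
  ok_len <- nchar(reads) == nchar(reference$dna)
  ok_alpha <- !grepl("[^ACGT]", reads)
  readable <- ok_len & ok_alpha
  n_unreadable <- sum(!readable)

  ref_codons <- reference$codons
  n_cod <- length(ref_codons)
  counts <- list()
  wt_tally <- list()
  n_multi <- 0L

  if (any(readable)) {
    # split all readable reads into a codon matrix (reads x codons)
    mat <- matrix("", nrow = sum(readable), ncol = n_cod)
    rr <- reads[readable]
    for (j in seq_len(n_cod)) {
      mat[, j] <- substring(rr, 3L * j - 2L, 3L * j)
    }
    diff <- mat != matrix(ref_codons, nrow = nrow(mat), ncol = n_cod, byrow = TRUE)
    n_diff <- rowSums(diff)
    for (i in seq_len(nrow(mat))) {
      k <- n_diff[i]
      if (k == 0L) {
        wt_tally[[rr[i]]] <- (wt_tally[[rr[i]]] %||% 0) + 1
      } else {
        idx <- which(diff[i, ])
        aas <- vapply(mat[i, idx], translate_codon, character(1),
                      USE.NAMES = FALSE)
        nonsyn <- aas != reference$protein[idx]
        if (!any(nonsyn)) {
          wt_tally[[rr[i]]] <- (wt_tally[[rr[i]]] %||% 0) + 1
        } else if (k == 1L) {
          key <- paste0(reference$positions[idx], ":", mat[i, idx])
          counts[[key]] <- (counts[[key]] %||% 0) + 1
        } else {
          n_multi <- n_multi + 1L
        }
      }
    }
  }

  count_tbl <- if (length(counts)) {
    keys <- strsplit(names(counts), ":", fixed = TRUE)
    tibble(
      position = as.integer(vapply(keys, `[[`, character(1), 1L)),
      codon = vapply(keys, `[[`, character(1), 2L),
      count = as.numeric(unlist(counts, use.names = FALSE))
    ) |>
      mutate(amino_acid = vapply(.data$codon, translate_codon, character(1),
                                 USE.NAMES = FALSE)) |>
      select("position", "codon", "amino_acid", "count") |>
      arrange(.data$position, .data$codon)
  } else {
    empty_count_tbl()
  }

  wt_tbl <- if (length(wt_tally)) {
    tibble(allele = names(wt_tally),
           count = as.numeric(unlist(wt_tally, use.names = FALSE))) |>
      arrange(.data$allele)
  } else {
    tibble(allele = character(0), count = numeric(0))
  }

  variant_counts(count_tbl, wt_tbl, sample_id = sample_id,
                 total_reads = length(reads),
                 n_multi_codon = n_multi, n_unreadable = n_unreadable)
}

empty_count_tbl <- function() {
  tibble(position = integer(0), codon = character(0),
         amino_acid = character(0), count = numeric(0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Variant count table
#'
#' Container for per-(position, codon) counts in one sample, with the
#' synonymous wild-type alleles kept as a separate internal-null partition
#' and stop-codon counts accessible for the baseline correction.  Counts may
#' be fractional after baseline correction.
#'
#' @param counts Tibble with columns `position`, `codon`, `amino_acid`,
#'   `count` (stop codons carry amino acid `"*"`).
#' @param wt_alleles Tibble with columns `allele` (DNA sequence or label) and
#'   `count`, one row per distinct synonymous wild-type allele.
#' @param sample_id Label.
#' @param total_reads Number of input reads, if counted from reads.
#' @param n_multi_codon,n_unreadable Excluded-read tallies.
#' @return A `variant_counts` object.
#' @export
variant_counts <- function(counts, wt_alleles, sample_id = "sample",
                           total_reads = NA_integer_,
                           n_multi_codon = 0L, n_unreadable = 0L) {
  counts <- as_tibble(counts)
  wt_alleles <- as_tibble(wt_alleles)
  stopifnot(all(c("position", "codon", "amino_acid", "count") %in% names(counts)),
            all(c("allele", "count") %in% names(wt_alleles)))
  if (any(counts$count < 0) || any(wt_alleles$count < 0)) {
    abort("Counts must be non-negative.", class = "satmut_invalid_counts")
  }
  structure(
    list(counts = counts, wt_alleles = wt_alleles, sample_id = sample_id,
         total_reads = total_reads, n_multi_codon = n_multi_codon,
         n_unreadable = n_unreadable),
    class = "variant_counts"
  )
}

#' @export
print.variant_counts <- function(x, ...) {
  cat(sprintf(
    "<variant_counts> %s: %d variant codons (%d stop), %d WT alleles",
    x$sample_id, nrow(x$counts), sum(x$counts$amino_acid == "*"),
    nrow(x$wt_alleles)))
  if (!is.na(x$total_reads)) {
    cat(sprintf("; %d reads (%d multi-codon, %d unreadable excluded)",
                x$total_reads, x$n_multi_codon, x$n_unreadable))
  }
  cat("\n")
  invisible(x)
}

#' Stop-codon subset of a count table
#' @param x A `variant_counts` object.
#' @export
stop_counts <- function(x) {
  stopifnot(inherits(x, "variant_counts"))
  filter(x$counts, .data$amino_acid == "*")
}

#' @export
tidy.variant_counts <- function(x, ...) {
  bind_rows(
    mutate(x$counts, sample_id = x$sample_id, partition = "variant"),
    tibble(position = NA_integer_, codon = NA_character_,
           amino_acid = NA_character_, count = x$wt_alleles$count,
           sample_id = x$sample_id, partition = "wt_synonymous",
           allele = x$wt_alleles$allele)
  ) |>
    select("sample_id", "partition", "position", "codon", "amino_acid",
           "count", dplyr::any_of("allele"))
}

#' Write / read a variant count table as delimited text
#'
#' Two tab-separated files: the variant table (`sample_id`, `position`,
#' `codon`, `amino_acid`, `count`) and a sidecar `<path>.wt.tsv` with the
#' synonymous wild-type allele counts.
#'
#' @param x A `variant_counts` object.
#' @param path Output path for the variant table.
#' @export
write_variant_counts <- function(x, path) {
  stopifnot(inherits(x, "variant_counts"))
  utils::write.table(
    mutate(x$counts, sample_id = x$sample_id)[
      , c("sample_id", "position", "codon", "amino_acid", "count")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(x$wt_alleles, paste0(path, ".wt.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_variant_counts
#' @export
read_variant_counts <- function(path) {
  counts <- as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                        stringsAsFactors = FALSE))
  wt <- as_tibble(utils::read.table(paste0(path, ".wt.tsv"), header = TRUE,
                                    sep = "\t", stringsAsFactors = FALSE))
  wt$allele <- as.character(wt$allele)
  sample_id <- if (nrow(counts)) counts$sample_id[1] else "sample"
  variant_counts(counts[, c("position", "codon", "amino_acid", "count")],
                 wt, sample_id = sample_id)
}
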