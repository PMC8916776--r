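#' Synthetic data generation
#'
#' Seeded generators for every input the pipeline consumes: selection-screen
#' count tables with known per-variant fitness, leaky null growth and
#' Poisson sampling noise; unfolding titrations with the exact noise law of
#' the fitting likelihood; exponential decay series; variant databases with
#' a heavy-tailed count law; and toy alignments.  All generators are
#' bit-reproducible given the seed, so every analysis stage can be tested by
#' closing the generator/estimator loop.
#'
#' @name synthetic-data
NULL

with_local_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Enumerate a single-codon saturation library
#'
#' All 63 non-wild-type codon substitutions at each requested position.
#'
#' @param reference A [coding_sequence()].
#' @param positions Residue numbers to mutate; default all.
#' @return Tibble with `position`, `codon`, `amino_acid`, `sequence` (the
#'   full-length variant DNA).
#' @export
generate_library <- function(reference, positions = reference$positions) {
  stopifnot(all(positions %in% reference$positions))
  all_codons <- names(Biostrings::GENETIC_CODE)
  rows <- map(positions, function(p) {
    i <- match(p, reference$positions)
    codons <- setdiff(all_codons, reference$codons[i])
    seqs <- vapply(codons, function(cod) {
      v <- reference$codons
      v[i] <- cod
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    tibble(position = p, codon = codons,
           amino_acid = vapply(codons, translate_codon, character(1),
                               USE.NAMES = FALSE),
           sequence = seqs)
  })
  bind_rows(rows)
}

#' Generate synonymous wild-type allele sequences
#'
#' Recodes randomly chosen positions to synonymous codons, producing the
#' internal-null alleles a saturation library carries (the study libraries
#' contain over a hundred of them).
#'
#' @inheritParams generate_library
#' @param n Number of distinct alleles (default 120).
#' @param seed Integer seed.
#' @return Character vector of distinct DNA sequences, all translating to
#'   the wild-type protein (the template itself is excluded).
#' @export
generate_wt_alleles <- function(reference, n = 120, seed = 1) {
  code <- Biostrings::GENETIC_CODE
  syn_sets <- split(names(code), unname(code))
  with_local_seed(seed, {
    alleles <- character(0)
    guard <- 0
    while (length(alleles) < n && guard < 50 * n) {
      guard <- guard + 1
      v <- reference$codons
      n_swap <- sample(1:3, 1)
      at <- sample(seq_along(v), n_swap)
      for (i in at) {
        alts <- setdiff(syn_sets[[reference$protein[i]]], v[i])
        if (length(alts)) v[i] <- sample(alts, 1)
      }
      s <- paste(v, collapse = "")
      if (s != reference$dna && !s %in% alleles) alleles <- c(alleles, s)
    }
    alleles
  })
}

#' Specify a selection-screen simulation
#'
#' Ties together the reference, the planted per-variant fitness (log10
#' growth advantage relative to wild type: +1 means ten-fold faster
#' propagation), the leaky null growth rate, the wild-type allele profile
#' and the sequencing depth.
#'
#' @inheritParams generate_library
#' @param true_fitness Tibble with `position`, `amino_acid`, `fitness`
#'   (log10 units); unlisted substitutions default to 0.  Stop codons always
#'   grow at the leak rate.
#' @param leak Log10 growth of null variants relative to wild type
#'   (`-Inf` = a clean, leak-free selection; a leaky bacterial screen sits
#'   around -1 to -2).
#' @param depth Expected unselected reads per library member.
#' @param selected_depth Expected selected reads per library member after
#'   renormalisation (sequencing reports frequencies, not absolute growth);
#'   default equal to `depth`.
#' @param n_wt_alleles Number of synonymous wild-type alleles (default 120,
#'   log-normal abundances).
#' @param wt_abundance_sdlog Log-sd of the wild-type allele abundances.
#' @param seed Integer seed.
#' @export
screen_model <- function(reference, true_fitness = NULL, leak = -Inf,
                         depth = 100, selected_depth = depth,
                         n_wt_alleles = 120, wt_abundance_sdlog = 1,
                         seed = 1) {
  stopifnot(inherits(reference, "coding_sequence"), depth > 0,
            leak <= 0)
  if (is.null(true_fitness)) {
    true_fitness <- tibble(position = integer(0), amino_acid = character(0),
                           fitness = numeric(0))
  }
  structure(list(reference = reference, true_fitness = true_fitness,
                 leak = leak, depth = depth, selected_depth = selected_depth,
                 n_wt_alleles = n_wt_alleles,
                 wt_abundance_sdlog = wt_abundance_sdlog, seed = seed),
            class = "screen_model")
}

#' Simulate an unselected/selected count-table pair
#'
#' Unselected counts are Poisson with mean `depth * abundance`.  Growth
#' multiplies each expectation by `10^g`, where `g` floors every variant's
#' fitness at the leak rate (`g = log10(10^fitness + 10^leak)`) and stop
#' codons carry fitness `-Inf`, so they grow exactly at the leak.  Selected
#' expectations are renormalised to the target selected depth before Poisson
#' sampling, modelling the fact that sequencing a fixed number of molecules
#' reports frequencies.
#'
#' @param model A [screen_model()].
#' @param positions Positions to include; default all in the construct.
#' @return List with `unselected` and `selected` [variant_counts()] objects
#'   and `library` (the truth table with an extra `fitness` column).
#' @export
simulate_screen <- function(model, positions = model$reference$positions) {
  stopifnot(inherits(model, "screen_model"))
  ref <- model$reference
  lib <- generate_library(ref, positions) |>
    left_join(model$true_fitness, by = c("position", "amino_acid")) |>
    mutate(fitness = ifelse(is.na(.data$fitness), 0, .data$fitness),
           fitness = ifelse(.data$amino_acid == "*", -Inf, .data$fitness))
  # synonymous codon substitutions in the library are wild-type-like
  lib$fitness[lib$amino_acid ==
                ref$protein[match(lib$position, ref$positions)]] <- 0
  with_local_seed(model$seed, {
    wt_seqs <- if (model$n_wt_alleles > 0) {
      generate_wt_alleles(ref, model$n_wt_alleles,
                          seed = sample.int(2^31 - 1, 1))
    } else character(0)
    wt_abund <- rlnorm(length(wt_seqs), 0, model$wt_abundance_sdlog)
    if (length(wt_abund)) wt_abund <- wt_abund / mean(wt_abund)
    abund <- c(rep(1, nrow(lib)), wt_abund)
    g <- log10(10^c(lib$fitness, rep(0, length(wt_seqs))) + 10^model$leak)
    mu_unsel <- model$depth * abund
    unsel <- rpois(length(abund), mu_unsel)
    w <- mu_unsel * 10^g
    if (all(w == 0)) {
      abort("All selected expectations are zero (no growth anywhere).",
            class = "satmut_degenerate")
    }
    mu_sel <- w / sum(w) * model$selected_depth * length(abund)
    sel <- rpois(length(abund), mu_sel)
    n_lib <- nrow(lib)
    make_table <- function(counts, id) {
      variant_counts(
        tibble(position = lib$position, codon = lib$codon,
               amino_acid = lib$amino_acid, count = counts[seq_len(n_lib)]),
        tibble(allele = wt_seqs, count = counts[n_lib + seq_along(wt_seqs)]),
        sample_id = id)
    }
    list(unselected = make_table(unsel, "unselected"),
         selected = make_table(sel, "selected"),
         library = lib)
  })
}

#' Simulate an unfolding titration
#'
#' Points on an even urea grid with the exact noise law of the fitting
#' likelihood: normal, scale `sigma_constant + sigma_proportional * urea`
#' (proteolysis curves use a constant scale and flat baselines).
#'
#' @inheritParams fraction_folded
#' @param baselines Named vector `signal_unfolded`, `slope_unfolded`,
#'   `signal_folded`, `slope_folded` (slopes ignored for proteolysis).
#' @param noise Named vector `sigma_constant`, `sigma_proportional`.
#' @param assay `"cd"` or `"proteolysis"`.
#' @param n_points Number of titration points (default 25 for CD, 12 for
#'   proteolysis, matching typical plate layouts).
#' @param urea_max Top of the urea grid, M (default 8).
#' @param seed Integer seed.
#' @return An [unfolding_curve()].
#' @export
simulate_unfolding_curve <- function(dG, m, baselines = c(
                                       signal_unfolded = -4,
                                       slope_unfolded = 0.1,
                                       signal_folded = -16,
                                       slope_folded = 0.2),
                                     noise = c(sigma_constant = 0.32,
                                               sigma_proportional = 0),
                                     assay = c("cd", "proteolysis"),
                                     n_points = if (assay[1] == "cd") 25 else 12,
                                     urea_max = 8, temperature = 298.15,
                                     seed = 1) {
  assay <- match.arg(assay)
  if (assay == "proteolysis") {
    baselines[c("slope_unfolded", "slope_folded")] <- 0
    noise["sigma_proportional"] <- 0
  }
  u <- seq(0, urea_max, length.out = n_points)
  mu <- unfolding_mean(u, dG, m, baselines[["signal_unfolded"]],
                       baselines[["slope_unfolded"]],
                       baselines[["signal_folded"]],
                       baselines[["slope_folded"]], temperature)
  sigma <- noise[["sigma_constant"]] + noise[["sigma_proportional"]] * u
  y <- with_local_seed(seed, mu + rnorm(n_points, 0, sigma))
  unfolding_curve(u, y, assay = assay, temperature = temperature)
}

#' Simulate an exponential decay series
#'
#' `A * exp(-k t) * (1 + eps)` with multiplicative normal noise.
#'
#' @param amplitude,k Decay parameters (`k = 0` gives a flat series).
#' @param times Time points.
#' @param noise_fraction Relative noise sd (default 0.05).
#' @param seed Integer seed.
#' @param id Probe identifier.
#' @return A [decay_series()].
#' @export
simulate_decay_series <- function(amplitude, k, times,
                                  noise_fraction = 0.05, seed = 1,
                                  id = "probe") {
  stopifnot(k >= 0, amplitude > 0)
  mu <- amplitude * exp(-k * times)
  y <- with_local_seed(seed, mu * (1 + rnorm(length(times), 0, noise_fraction)))
  decay_series(times, y, id = id)
}

#' Simulate cancer-like and population-like variant databases
#'
#' Activating variants (fitness above `threshold`) receive observation
#' counts from a heavy-tailed negative-binomial law, so some rare activating
#' variants fall below the five-count cutoff just as rare cancer variants
#' do; the remaining variants populate the negative database.  A
#' contamination fraction swaps labels in both directions, and a small
#' fraction of swapped-in negatives is flagged `pathogenic`.
#'
#' @param truth Tibble with `position`, `wt_aa`, `mut_aa`, `fitness`.
#' @param threshold Fitness above which a variant is truly activating.
#' @param count_mu,count_size Negative-binomial mean and size for positive
#'   counts (size < 1 gives the heavy tail).
#' @param contamination Fraction of variants whose label is swapped.
#' @param seed Integer seed.
#' @return List with `tp_db` and `tn_db` tibbles (columns `isoform`,
#'   `position`, `wt_aa`, `mut_aa`, `count`, `pathogenic`).
#' @export
simulate_variant_databases <- function(truth, threshold,
                                       count_mu = 30, count_size = 0.6,
                                       contamination = 0, seed = 1) {
  stopifnot(all(c("position", "wt_aa", "mut_aa", "fitness") %in% names(truth)))
  with_local_seed(seed, {
    activating <- truth$fitness > threshold
    if (contamination > 0) {
      flip <- runif(nrow(truth)) < contamination
      activating <- xor(activating, flip)
    }
    tp <- truth[activating, ]
    tn <- truth[!activating, ]
    tp_db <- tibble(isoform = "H", position = tp$position, wt_aa = tp$wt_aa,
                    mut_aa = tp$mut_aa,
                    count = rnbinom(nrow(tp), size = count_size,
                                    mu = count_mu) + 1L,
                    pathogenic = 1L)
    tn_db <- tibble(isoform = "H", position = tn$position, wt_aa = tn$wt_aa,
                    mut_aa = tn$mut_aa,
                    count = rnbinom(nrow(tn), size = 2, mu = 10) + 1L,
                    pathogenic = 0L)
    list(tp_db = tp_db, tn_db = tn_db)
  })
}

#' Simulate a toy multiple sequence alignment
#'
#' Each non-reference row substitutes residues independently at
#' `sub_rate`, except at `conserved` positions which are never touched, so
#' conserved columns have entropy 0 and variable columns positive entropy.
#'
#' @param reference_seq Ungapped reference amino-acid string.
#' @param n_sequences Total rows including the reference.
#' @param sub_rate Per-position substitution probability.
#' @param conserved Residue numbers kept invariant.
#' @param first_residue_number Numbering of the first residue.
#' @param seed Integer seed.
#' @return An [alignment()] object with reference row `"reference"`.
#' @export
simulate_alignment <- function(reference_seq, n_sequences = 50,
                               sub_rate = 0.3, conserved = integer(0),
                               first_residue_number = 1L, seed = 1) {
  aa <- setdiff(unique(unname(Biostrings::GENETIC_CODE)), "*")
  ref <- strsplit(toupper(reference_seq), "")[[1]]
  pos <- first_residue_number + seq_along(ref) - 1L
  with_local_seed(seed, {
    rows <- c(list(reference = paste(ref, collapse = "")),
              lapply(seq_len(n_sequences - 1), function(i) {
                s <- ref
                hit <- runif(length(ref)) < sub_rate & !pos %in% conserved
                s[hit] <- sample(aa, sum(hit), replace = TRUE)
                paste(s, collapse = "")
              }))
    names(rows)[-1] <- paste0("seq", seq_len(n_sequences - 1))
    alignment(unlist(rows), reference_id = "reference",
              first_residue_number = first_residue_number)
  })
}

#' Expand a simulated count table back into reads
#'
#' Error-free reads replicated per count, for round-trip tests of the
#' variant caller.
#'
#' @param screen Result of [simulate_screen()].
#' @param which `"unselected"` or `"selected"`.
#' @return Character vector of reads.
#' @export
screen_reads <- function(screen, which = c("unselected", "selected")) {
  which <- match.arg(which)
  tbl <- screen[[which]]
  c(rep(screen$library$sequence, tbl$counts$count),
    rep(tbl$wt_alleles$allele, tbl$wt_alleles$count))
}
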