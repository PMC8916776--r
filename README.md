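# satmut

Analysis of deep mutational scanning (saturation mutagenesis) selection
screens and their biophysical follow-up assays, built for groups mapping
protein fitness landscapes — the motivating system is Ras, where screen
scores, construct comparisons, thermodynamic stability and local dynamics
together explain why particular mutations activate the protein.

## What it computes

**Enrichment scores.** For variant *x* at position *i*, with counts *c* in
the selected and unselected sequencing samples,

    ΔE_xi = log10(c_sel / c_unsel) − median_a { log10(C_a^wt,sel / C_a^wt,unsel) }

where the median runs over the synonymous wild-type alleles *a* (library
sequences that translate to the wild-type protein). A variant behaving like
wild type scores 0; ±1 means ten-fold faster/slower propagation. The
package also provides the fragile single-reference legacy score, a
stop-codon baseline correction for leaky selections
(c_sel − c_unsel·x̃_f, with x̃_f the median stop-codon count ratio),
mode-centering and common-spread scaling, and replicate averaging.

**Construct epistasis.** ΔΔE = ΔE(short) − ΔE(long) per cell with
per-position means, plus classification of activating (score > 1.5 σ) and
stability-dependent gain-of-function sites.

**ROC benchmarking.** Truth sets from COSMIC-like/gnomAD-like variant
tables (inclusive ≥5-count cutoff, pathogenic-flag and overlap rules) or
from a reference screen's scores; threshold-sweep ROC curves whose
trapezoidal AUC equals the pairwise rank statistic.

**Stability fits.** Two-state equilibrium unfolding, ΔG(u) = ΔG_unf − m·u:
maximum-likelihood CD fits (linear baselines, noise scale linear in urea)
and pulse-proteolysis fits (flat baselines, m fixed to the CD estimate,
constant noise), both reporting the midpoint Cm = ΔG_unf/m with
observed-information standard errors; the ligand-contribution correction
RT·ln[(1 + [GDP]new/KD)/(1 + [GDP]old/KD)] for changes in nucleotide
concentration between assays.

**Exchange kinetics.** Single-exponential fits A·e^(−kt) of per-residue
HDX peak-volume decays (and nucleotide-release fluorescence), a strict
R² > 0.7 keep filter, mutant/WT rate fold changes and their five-level
binning.

**Conservation.** Per-column Shannon entropy (bits) of a multiple sequence
alignment mapped to reference residue numbering.

**Synthetic data.** Seeded generators for every input above — selection
screens with planted fitness and leaky null growth, titrations, decays,
variant databases, alignments — so the whole pipeline is testable
end to end with no external data.

## Worked example

Simulate a 40-residue screen with one planted ten-fold activating
substitution, score it, and fit a stability curve:

```r
library(satmut)

ref <- coding_sequence(paste(rep(c("GGC", "CAA", "TTG", "AAA", "GAT"), 8),
                             collapse = ""), first_residue_number = 2)
fitness <- tibble::tibble(position = 7L, amino_acid = "V", fitness = 1)
screen <- simulate_screen(screen_model(ref, fitness, depth = 5000, seed = 1))
screen$unselected
#> <variant_counts> unselected: 2520 variant codons (120 stop), 120 WT alleles

scores <- combine_synonymous(
  enrichment_scores(screen$selected, screen$unselected))
dplyr::filter(scores, position == 7, amino_acid %in% c("V", "A", "*"))
#> # A tibble: 3 × 3
#>   position amino_acid    score
#>      <int> <chr>         <dbl>
#> 1        7 *          -3.71
#> 2        7 A          -0.00680
#> 3        7 V           1.00
```

The planted variant scores +1.00 (ten-fold enrichment), an unplanted
substitution scores ≈ 0, and stop codons fall to the bottom of the range.
`plot_enrichment_heatmap(scores)` draws the fitness heatmap.

```r
curve <- simulate_unfolding_curve(29.9, 5, seed = 1)  # CD titration, 0-8 M urea
fit_cd_curve(curve)
#> <stability_fit> cd: dG_unf = 32.73 +/- 2.51 kJ/mol, m = 5.56, Cm = 5.89 M

ligand_contribution(100, 36, K_D = 0, temperature = 298)
#> [1] 2.531215   # kJ/mol added by raising GDP from 36 to 100 uM
```

Fitted objects support `tidy()`, `glance()` and `autoplot()`.

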