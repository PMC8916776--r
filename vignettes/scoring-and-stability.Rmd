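---
title: "Scoring saturation-mutagenesis screens and fitting stability assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring saturation-mutagenesis screens and fitting stability assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(satmut)
library(dplyr)
```

satmut analyses deep mutational scanning (saturation mutagenesis) selection
screens of the kind used to map the fitness landscape of Ras, together with
the biophysical follow-up assays that interpret the screen: equilibrium
unfolding titrations, hydrogen-deuterium exchange kinetics, and sequence
conservation. This vignette is the package's account of the underlying
models, the tunable parameters, and the design decisions taken where more
than one reasonable choice existed.

## The enrichment model

A selection screen couples variant fitness to sequencing counts: a library
of single-codon variants is sequenced before and after selection, and the
relative enrichment of variant $x$ at position $i$ is

$$\Delta E_{xi} \;=\; \log_{10}\!\frac{c_{xi}^{\mathrm{sel}}}{c_{xi}^{\mathrm{unsel}}}
\;-\; \operatorname{median}\!\left\{\log_{10}\frac{C^{\mathrm{wt,sel}}_a}{C^{\mathrm{wt,unsel}}_a}\right\}_a ,$$

where the median runs over the synonymous wild-type alleles $a$ — library
DNA sequences that differ from the template but translate to the wild-type
protein. A library typically carries more than a hundred of them, so the
centering term is an internal null distribution rather than a single data
point. A variant behaving like the wild-type median scores 0, and scores of
$\pm 1$ correspond to ten-fold faster or slower propagation. The legacy
alternative (`legacy_enrichment()`) centers on the count ratio of the one
wild-type reference sequence; within a dataset the two scores differ by a
constant, but the legacy score inherits the full sampling noise of that
single allele and fails outright when its count is zero.

**Pseudocounts.** Counts of zero make the log ratio undefined. By default a
pseudocount of 1 is added to every variant and wild-type allele count in
both samples before forming ratios; `pseudocount = "drop"` discards
zero-count entries instead, and `pseudocount = 0` applies the formula
exactly (appropriate for tables known to be all-positive, and used in the
package's own exactness tests). Variants present in one sample's table but
absent from the other are flagged missing (`NA`) rather than scored — a
missing cell is knowledge of absence of evidence, distinct from an observed
zero.

**Stop-codon baseline correction.** In a leaky selection, cells carrying a
null variant still grow at a basal rate, so every selected count contains a
null component. The stop-codon variants measure it: with
$\tilde{x}_f$ the median of the stop codons' selected/unselected ratios,
corrected counts are $c^{\mathrm{sel}} - c^{\mathrm{unsel}}\,\tilde{x}_f$.
Corrected counts at or below zero — the stop codons themselves land here —
are floored to 1 (configurable); they then score at the bottom of the range,
which is the correct reading: the data cannot distinguish "null" from
"worse than null". Before the correction the score distribution of a leaky
screen is bimodal (a null peak plus the functional peak); after it, the null
mass spreads into the lower tail and the distribution becomes unimodal.
`count_modes()` quantifies this with a kernel-density mode count in which a
secondary peak only counts if its prominence — its height above the deepest
valley separating it from a higher peak — exceeds half the maximum density;
raw peak height is not used because the floor policy necessarily leaves a
small density ripple at the bottom of the scale. The correction is
unavailable (an error, so the caller can skip it) when stop variants grow
like everything else, as in GAP-regulated datasets where selection does not
distinguish null from wild type.

**Post-processing.** Codon-level scores are combined per amino acid by an
unweighted mean (`combine_synonymous()`), centered at zero on the *mode* of
the wild-type allele scores (kernel density, plug-in bandwidth, 512-point
grid — deterministic and robust to the shouldered distributions these
screens produce), and rescaled so the standard deviation of the substitution
scores equals `target_sd` (default 1.0; the constant is arbitrary but must
be shared across datasets being compared). The stop row is excluded from the
scaling spread and from per-position means, which describe amino-acid
substitutions. Replicates are scored separately and averaged per cell
(`average_replicates()`).

## Construct epistasis and site classification

Comparing a destabilised (shorter) construct with a stabilised (longer) one
isolates mutations whose phenotype depends on protein stability:
$\Delta\Delta E_{xi} = \Delta E_{xi}^{\mathrm{short}} - \Delta E_{xi}^{\mathrm{long}}$,
averaged per position over the defined substitutions. A substitution is
*activating* when its score exceeds $k\,\sigma$ of its own matrix's
substitution-score distribution ($k = 1.5$ by convention), and a site is a
*stability-dependent gain-of-function site* when at least one substitution
is activating in the long construct but not in the short one. "Not
activating" is implemented as the strict complement of the activating rule;
a separate deleterious threshold ($< -k\sigma$) is reported in the
per-variant labels but does not enter the site classification. Thresholds
are computed per matrix *after* centering and scaling, so classification is
only invariant to shifting both matrices if the centering step is re-run.

## ROC benchmarking

Truth sets can come from variant databases
(`assemble_truth()`: positives are cancer-database variants observed at
least 5 times — the inclusive cutoff removes low-frequency entries that may
not be pathogenic; negatives are population-database variants minus any
flagged pathogenic and minus the positives, since a variant found in both
databases is treated as a positive) or from a reference screen's own scores
(`truth_from_scores()`: the $k\sigma$ tail is positive, the rest negative).
Variants in neither database are excluded rather than presumed benign.
Isoform counts are pooled by default; per-isoform qualification is
available. The ROC itself sweeps a threshold over every distinct score
(higher score predicts activating) and integrates by the trapezoidal rule,
so tied scores contribute half weight and the AUC equals the pairwise
rank-comparison statistic exactly — a property the test suite verifies
against a brute-force double loop and against an independent ROC
implementation.

## Two-state unfolding fits

Both stability assays assume a folded $\rightleftharpoons$ unfolded
two-state equilibrium with free energy linear in denaturant,
$\Delta G(u) = \Delta G_{\mathrm{unf}} - m u$, giving a logistic folded
fraction with midpoint $C_m = \Delta G_{\mathrm{unf}}/m$
(`fraction_folded()`, evaluated overflow-safely). Throughout,
$R = 8.314\times10^{-3}\,$kJ·mol⁻¹·K⁻¹ and the default temperature is
298.15 K (assays at 25 °C).

**CD titrations** (`fit_cd_curve()`) are fit by maximum likelihood with the
mean taken as the unfolded linear baseline *plus the folded component times
the folded fraction* — note this parametrisation, which the synthetic
generator shares so that generator and estimator agree — and normal noise
whose scale is linear in urea,
$\sigma(u) = \sigma_{\mathrm{const}} + \sigma_{\mathrm{prop}} u$.
Optimisation is staged: the six mean parameters are first fit by least
squares with a multistart over eight evenly spaced midpoint guesses
(initial $m = 5$ kJ·mol⁻¹·M⁻¹), the noise scale is initialised from the
residuals, and the full eight-parameter likelihood is then polished with
bounded L-BFGS-B. The staging matters: the joint likelihood becomes stiff
when the noise scale is far below the signal scale, and direct multistart
on all eight parameters can stall in local optima. Standard errors come
from the observed information (numerical Hessian with parameter-scaled
steps) over the interior parameters; parameters pinned at a bound are
excluded from the inversion. A fit is rejected as having no identifiable
transition when the $m$-value runs to its bound, the relative standard
error of $\Delta G_{\mathrm{unf}}$ exceeds 25 %, or the fitted transition is
not bracketed by the data (folded fraction above 0.7 at the low end and
below 0.3 at the high end of the urea range). A strictly zero-noise curve
makes the likelihood unbounded; self-consistency checks therefore use a
vanishingly small noise floor.

**Pulse proteolysis** (`fit_proteolysis_curve()`) band intensities report
the folded fraction directly: flat baselines, the $m$-value *fixed to its
CD estimate*, and constant noise — equivalent to nonlinear least squares.
The baselines enter linearly, so the fit profiles them out and optimises
$\Delta G_{\mathrm{unf}}$ alone; standard errors come from the Gauss-Newton
approximation to the information.

**Ligand contribution.** Raising a folded-state ligand's concentration
between assays adds
$RT\,\ln\!\left[(1 + [L]_{\mathrm{new}}/K_D)\,/\,(1 + [L]_{\mathrm{old}}/K_D)\right]$
to the apparent $\Delta G_{\mathrm{unf}}$ (`ligand_contribution()`). The
natural logarithm is used: for GDP raised from 36 to 100 µM at 298 K in the
tight-binding limit it gives ~2.53 kJ·mol⁻¹, the established value for this
correction, which a base-10 logarithm would understate by a factor of
$\ln 10$. At $K_D = 3$ µM the deviation from tight-binding behaviour is
~0.13 kJ·mol⁻¹ (about 5 %), so the correction is robust to the weakened
nucleotide affinities expected of destabilised point mutants.

## Exchange kinetics

Per-residue HDX peak volumes (and nucleotide-release fluorescence) decay as
a single exponential $A e^{-kt}$; `fit_exponential()` initialises by
log-linear regression and refines by Levenberg-Marquardt. No offset term is
included by default — the plateau of fully exchanged peaks is zero volume —
but `offset = TRUE` adds one for MS-style data. $R^2$ is computed against
the mean-only model and the filter is strict: a fit is kept only when
$R^2 > 0.7$, so a fit at exactly 0.7 is excluded. Mutant/wild-type rate
ratios are binned into five categories for structure colouring; the bin
edges at 1/3, 1/2, 2 and 3 assign exact boundary values to the inner bin
(the conventional wording "between two and three times" is read
inclusively), and the bins are monotone in the ratio — the natural reading,
with the extreme bins open-ended.

## Conservation

`site_entropies()` computes per-column Shannon entropy in bits (base 2;
no base is canonical, bits are the common convention), with columns mapped
to reference residue numbering through the ungapped positions of a
designated reference row. Gaps are excluded from the frequency denominator
by default (`gap_policy = "include"` treats the gap as a 21st symbol); no
sequence weighting or pseudocounts are applied — the statistic is plain
observed-frequency entropy.

## What the synthetic generator emulates — and what it does not

`simulate_screen()` draws unselected counts as Poisson with mean
`depth × abundance`, multiplies expectations by $10^{g}$ with
$g = \log_{10}(10^{f} + 10^{\mathrm{leak}})$ — so the leak floors every
variant's growth and stop codons (fitness $-\infty$) grow exactly at the
leak — renormalises selected expectations to a target depth (sequencing
reports frequencies, not absolute growth; this is what makes
depth-invariance testable), and draws selected counts as Poisson. The
default wild-type allele profile is 120 distinct synonymous alleles with
log-normal abundances, matching the over-a-hundred alleles such libraries
carry. Titrations are generated under the exact noise law of the fitting
likelihood, decays with multiplicative normal noise, and variant databases
with a heavy-tailed negative-binomial count law so that some truly
activating variants fall below the five-count cutoff, as rare cancer
variants do. All generators restore the caller's RNG state and are
bit-reproducible given their seed.

Deliberately not modelled: PCR jackpot artifacts, position- or
context-dependent sequencing error, read-level quality, epistatic double
mutants, and replicate-to-replicate condition drift. Passing
generator/estimator round trips therefore demonstrates correctness of the
*computation*, not robustness to every artifact of real screens; on real
data the synonymous-allele normaliser and the replicate averaging are the
defences against those artifacts.

## Problem sizes and numerical tolerances used in the tests

The test suite exercises a 40-residue toy construct (2 520 single-codon
variants plus 120 wild-type alleles): large enough for distributional
checks, small enough to run everywhere. Screen-recovery checks use depths
of 300–10 000 expected reads per variant; the rank-recovery check requires
Spearman $\rho > 0.95$ at depth $10^4$. Stability-fit coverage runs 100
seeded curves per assay at a constant noise of 2 % of the folded amplitude
and asks the true $\Delta G_{\mathrm{unf}}$ to fall within two estimated
standard errors at least 90 % of the time. Decay-rate recovery uses 12
time points at 5 % multiplicative noise over 100 seeds. Exact identities
(depth invariance, the constant offset between the two scoring formulas,
AUC as a rank statistic) are asserted to machine precision on
pseudocount-free, all-positive tables.

## Known limitations

* The two-state model excludes three-state or intermediate-populated
  unfolding; curves that are genuinely multi-state will either fail the
  transition-bracketing check or return biased $\Delta G_{\mathrm{unf}}$.
* The scaling constant `target_sd` is a convention, not an estimate;
  absolute score magnitudes are only comparable across datasets scaled to
  the same constant.
* `call_variant()` requires reads pre-trimmed to the reference frame;
  indels and frame shifts surface as `unreadable`/`multi_codon`, not as
  calls.
* The refractive-index-to-urea conversion used when preparing titrations is
  upstream of the package: urea molarities are inputs.

## A worked end-to-end example

```{r example, eval = FALSE}
ref <- coding_sequence(paste(rep(c("GGC", "CAA", "TTG", "AAA", "GAT"), 8),
                             collapse = ""), first_residue_number = 2)
fitness <- tibble::tibble(position = 7L, amino_acid = "V", fitness = 1)
screen <- simulate_screen(screen_model(ref, fitness, depth = 5000, seed = 1))
scores <- combine_synonymous(
  enrichment_scores(screen$selected, screen$unselected))
dplyr::filter(scores, position == 7, amino_acid == "V")  # score ~ +1
plot_enrichment_heatmap(scores)
```
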