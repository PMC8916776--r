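Package: satmut
Title: Saturation-Mutagenesis Screen Scoring and Protein Stability Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for analysing deep mutational scanning (saturation
    mutagenesis) selection screens and the biophysical follow-up assays
    that accompany them.  Calls single-codon variants from merged amplicon
    reads, computes relative enrichment (fitness) scores normalised by
    synonymous wild-type alleles with an optional stop-codon baseline
    correction, compares fitness landscapes between protein constructs
    (epistasis), benchmarks scores against cancer and population variant
    databases with ROC curves, fits two-state equilibrium unfolding models
    to circular dichroism and pulse proteolysis urea titrations by maximum
    likelihood, fits single-exponential hydrogen-deuterium exchange decays,
    and computes Shannon-entropy sequence conservation from alignments.
    A seeded synthetic-data generator produces every input the pipeline
    consumes, so all stages are testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    Biostrings
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
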