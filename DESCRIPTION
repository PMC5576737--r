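Package: pleiocfdr
Title: Cross-Trait Pleiotropy Analysis with Conditional and Conjunction
    False Discovery Rates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies genetic variants shared between two traits from GWAS
    summary statistics using the empirical conditional false discovery rate
    (cFDR) and its conjunction form (ccFDR). Provides reading, harmonization
    and merging of two summary-statistic tables, windowed greedy LD pruning
    with a minor-allele-frequency removal rule, conditional Q-Q enrichment
    diagnostics, Manhattan-plot data with MHC region classification, a
    tabular pleiotropic-locus report, and a synthetic two-trait GWAS
    generator with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
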