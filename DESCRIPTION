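Package: polysomics
Title: Polysomal Proteomics of Ribosome Association and Polysome Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free quantitative (LFQ) polysome
    profiling proteomics in yeast. Reads MaxQuant-style protein-group and
    peptide tables for sucrose-gradient fractions (monosome F1 through heavy
    polysomes F5) and unfractionated totals, estimates per-protein ribosome
    association (fraction sum over total, percent ribosomal), tests
    stress-induced association changes against an empirical null derived
    from ribosomal proteins, builds and clusters normalized polysome
    enrichment profiles (Euclidean distance, complete linkage with
    deterministic tie-breaking), and tests peptide-level N-terminal
    intensity bias with a Kolmogorov-Smirnov statistic. Includes a
    synthetic-data generator reproducing the statistical structure of the
    experimental design (multiplicative log-normal noise,
    intensity-dependent dropout, stress-induced monosome shift) so that
    every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
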