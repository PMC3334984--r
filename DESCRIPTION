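Package: snparray
Title: Design and Evaluation of Fixed-Size SNP Genotyping Arrays from
    Low-Coverage Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to design and evaluate Infinium-style SNP genotyping
    arrays from low-coverage whole-genome resequencing of a breeding
    panel. Implements the two detection-stage variant filtering regimes
    (quality, coverage band, minor-allele read support, repeat exclusion
    via interval tracks or k-mer copy number), Infinium probe candidacy
    screening (type I/II classification, 50 bp probe context, probe-tail
    uniqueness, design-score thresholds, multi-source merge), design-stage
    filtering and even physical spacing selection into a fixed number of
    bead slots with pre-validated marker pinning, and array evaluation
    (cluster-quality QC, minor allele frequency spectra, polymorphism
    classification, inter-marker gap statistics, panel comparison,
    validation cross-tabulation, progeny informativeness, and sequencing
    coverage accounting). A synthetic-data module simulates genomes,
    annotations, diploid panels, per-accession call tables and array
    genotype reports so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
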