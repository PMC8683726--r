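Package: poliseq
Title: RNA Polymerase I NET-seq Occupancy and In Vitro Transcription
    Kinetics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of RNA polymerase I (Pol I) transcription of the rDNA
    35S unit at single-nucleotide resolution. Converts native elongating
    transcript sequencing (NET-seq) alignments into UMI-deduplicated
    per-position occupancy tracks, quantifies replicate reproducibility by
    Spearman rank correlation, tests for differential occupancy between
    conditions (per-position Welch t-tests, per-spacer two-sample
    Kolmogorov-Smirnov tests), calls pause sites as the most-occupied spacer
    positions and compares their sequence context between conditions with
    Jensen-Shannon-divergence differential logos. A companion set of
    functions quantifies promoter-dependent in vitro transcription assays:
    ladder-calibrated gel densitometry, elongation-rate fits, exponential
    dose-response IC50 fits, promoter-escape time-course reductions, and
    conserved pause-band detection. A seed-reproducible simulator generates
    every input the pipeline consumes, emulating drug-induced loss of Pol I
    occupancy and sequence-specific pausing upstream of G-rich rDNA.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
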