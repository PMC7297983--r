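Package: gcscreen
Title: Pooled In Vivo shRNA Screen Simulation and Analysis for Germinal
    Center B Cell Selection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for pooled short-hairpin RNA (shRNA) screens read out by
    amplicon sequencing of sorted cell compartments, as used to find
    regulators of germinal center (GC) B cell differentiation. Models and
    validates hairpin cassettes (leader-sense-loop-antisense-terminator
    grammar), generates libraries with a minimum pairwise stem distance, and
    simulates a screen end to end: skewed plasmid pool, founder-cell
    bottleneck, per-gene GC-fate selection, clonal expansion, overdispersed
    parallel PCR replicates, and FASTQ emission with substitution errors.
    Counts cassette occurrences in reads by exact matching on both strands,
    reduces parallel replicates to median percentage abundances, applies a
    scarcity filter, and ranks constructs and genes by GC/non-GC fold change
    and reciprocal-standard-deviation consistency. Includes a 2^-ddCt
    utility for quantitative PCR validation data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    stringi,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
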