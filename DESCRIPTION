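Package: evotraj
Title: Allele-Frequency Trajectory Analysis for Evolve-and-Resequence Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing whole-population (metagenomic) sequencing of
    experimentally evolving bacterial populations. Implements statistical
    filtering of candidate mutations from polymorphism-caller read counts
    (Poisson likelihood-ratio test with read-total offsets, Benjamini-Hochberg
    control, ubiquity and persistence filters), per-generation
    mutation-accumulation-rate estimation with hypermutator lineage
    decomposition, Manhattan-distance lineage assignment, six-class
    base-substitution spectra, and rule-based genotype-nesting reconstruction
    with ggmuller-compatible Muller-plot export. A synthetic-experiment
    generator reproduces the statistical structure the analysis assumes,
    including hypermutator lineage dynamics, binomial read sampling and
    sequencing-noise false positives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr
Config/testthat/edition: 3
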