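Package: isoscreen
Title: Analysis and Simulation of Isogenic CRISPR/Cas9 Drop-Out Screens
Version: 0.1.0
Authors@R:
    person("Iso", "Screen", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for genome-wide CRISPR/Cas9 negative-selection
    (drop-out) screens run in isogenic knockout / wild-type cell-line pairs.
    Covers sgRNA quantification from FASTQ reads by exact spacer matching,
    guide-level log2 fold changes against the plasmid library, gene-level
    Bayes-factor lethality scores from kernel-density likelihood ratios
    trained on reference essential and non-essential gene sets, and a
    differential-dependency statistic: the standardized residual (Z score)
    of a linear model of knockout-genotype gene scores on wild-type scores.
    Includes a seeded synthetic-screen generator with exportable ground
    truth so the full pipeline is testable without screen sequencing data,
    plus the small deterministic calculations behind common follow-up
    assays (competitive depletion, delta-delta-Ct, ChIP percent input,
    promoter-luciferase normalization).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
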