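Package: cuedit
Title: Quantification of Site-Specific C-to-U RNA Editing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies site-specific C-to-U RNA editing of coding
    transcripts, modelled on the SDHB c.136C>U (R46X) editing system in
    human monocytes. Provides strand-aware CDS-to-genome coordinate
    mapping and codon consequence prediction, pileup-based per-position
    base-call tallies from aligned reads with a pooled background-error
    null and a Yates-corrected chi-square site test, allele-specific qPCR
    delta-Cp editing estimation with standard-curve efficiency calibration
    and assay-specificity correction, amplicon deep-sequencing variant
    screening with a frequency reporting rule, in-silico restriction
    digests (RFLP) for edit verification, exact nonparametric cohort
    statistics, and seeded simulators for reads, qPCR plates and paired
    donor cohorts so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    BiocGenerics,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), vcfR, withr
Config/testthat/edition: 3
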