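Package: neovax
Title: Individualized Neoantigen Vaccine Design and Immunomonitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the computational core of individualized neoantigen
    mRNA vaccine studies: construction of mutated peptide sequences from
    somatic variants on coding transcripts, enumeration and scoring of
    variant-containing HLA class I and II epitopes via a pluggable
    (mockable) binding predictor, staged prioritization and selection of up
    to 20 vaccine targets assembled into two SEC-concatemer-MITD mRNA
    constructs, distribution-free resampling (DFR) response calling for
    IFN-gamma ELISpot with de novo/amplified classification, and reverse
    immunomonitoring (RevImMo) of bulk and single-cell TCR repertoires
    with clonal-enrichment candidate selection, reporter-assay specificity
    calls and clonotype tracking. Includes seeded synthetic-data
    generators with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
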