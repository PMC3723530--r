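Package: sca1repeats
Title: Repeat Structure, Interruptions and Age at Onset in SCA1 CAG Expansions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the CAG-repeat tract of the ataxin-1 gene
    (ATXN1) from cloned allele sequences: run-length parsing of the repeat
    region into codon runs, detection and classification of CAT (histidine)
    interruptions, the longest uninterrupted CAG stretch statistic, in-silico
    SfaNI digestion of repeat-region amplicons, clone-depth-corrected
    mosaicism summaries, transmission-event classification, capillary
    fragment-sizing calibration, and genotype-phenotype linear modelling of
    age at disease onset with non-simultaneous prediction bounds. Includes a
    synthetic cohort generator emulating allele structure, somatic mosaicism
    and PCR artefacts so the full pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    car,
    minpack.lm
Config/testthat/edition: 3
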