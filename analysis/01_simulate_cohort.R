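#!/usr/bin/env Rscript
# Simulate the study-scale cohort: 35 patients, ~11% with interrupted
# pathogenic alleles, clone libraries with mosaicism and PCR artefacts,
# onset driven by the longest pure CAG run, diagnostic sizes through the
# calibration line. Writes the bundle under results/cohort/.

suppressPackageStartupMessages(library(sca1repeats))

cfg <- synthetic_config(seed = 20130725)
paths <- write_synthetic_bundle(cfg, "results/cohort")

cohort <- read_cohort(paths$cohort)
cat("Simulated cohort:", length(unique(cohort$patient_id)), "patients,",
    sum(cohort$n_clones), "clones,",
    nrow(cohort), "distinct clone sequences\n")

truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
cat("Truly interrupted pathogenic alleles:", sum(truth$interrupted), "\n")
cat("Bundle written to results/cohort (cohort.tsv, clones.fasta,",
    "truth.json, config.yaml)\n")
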