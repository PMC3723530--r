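# Shared generators for property-style tests. All draws use the caller's
# RNG state; tests set a fixed seed before looping.

# A random valid repeat pattern: CAG runs interleaved with CAT (or
# occasionally CAA/other) runs, adjacent runs always distinct. With
# `start_cag` the tract opens with a CAG run, as real ATXN1 tracts do —
# required when a CAT interruption must carry its 5' CAG context.
random_pattern <- function(max_runs = 7L, allow_other = FALSE,
                           start_cag = FALSE) {
  n_runs <- sample(1:max_runs, 1L)
  codons <- character(n_runs)
  counts <- integer(n_runs)
  pool <- c("CAG", "CAT", if (allow_other) c("CAA", "AAG"))
  codons[1L] <- if (start_cag) "CAG" else sample(pool, 1L)
  for (i in seq_len(n_runs)[-1L]) {
    codons[i] <- sample(setdiff(pool, codons[i - 1L]), 1L)
  }
  for (i in seq_len(n_runs)) {
    counts[i] <- if (codons[i] == "CAG") sample(1:60, 1L) else sample(1:2, 1L)
  }
  repeat_pattern(codons, counts, merge = FALSE)
}

# Brute-force string-walk oracle: codon-frame run-length encoding of a
# DNA region, computed with an explicit loop independent of the package
# parsing code.
walk_codons_oracle <- function(region) {
  stopifnot(nchar(region) %% 3 == 0)
  n <- nchar(region) / 3
  codons <- vapply(seq_len(n), function(i)
    substr(region, 3 * i - 2, 3 * i), "")
  runs_codon <- character(0)
  runs_count <- integer(0)
  for (cd in codons) {
    k <- length(runs_codon)
    if (k > 0 && runs_codon[k] == cd) {
      runs_count[k] <- runs_count[k] + 1L
    } else {
      runs_codon <- c(runs_codon, cd)
      runs_count <- c(runs_count, 1L)
    }
  }
  list(codon = runs_codon, count = runs_count)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# A tiny deterministic cohort data frame builder.
cohort_row <- function(patient_id, pattern, n_clones,
                       allele_label = "pathogenic",
                       onset_age = NA_real_, sized_repeat = NA_real_) {
  data.frame(patient_id = patient_id, onset_age = onset_age,
             sized_repeat = sized_repeat, allele_label = allele_label,
             pattern = pattern, n_clones = n_clones,
             stringsAsFactors = FALSE)
}
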