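---
title: "Repeat interruptions, mosaicism and age at onset in SCA1: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat interruptions, mosaicism and age at onset in SCA1: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sca1repeats)
```

## The problem

Spinocerebellar ataxia type 1 (SCA1) is caused by expansion of the CAG
repeat in *ATXN1*. Two features of the repeat tract complicate both
diagnosis and prognosis. First, the tract may carry CAT (histidine)
interruptions: at DNA level these break the pure CAG run, and
phenotypically they delay or abolish disease even when the *total*
tract is long. Second, within one person the tract is mosaic: cloned
molecules from a single allele differ in length, and PCR introduces its
own artefacts (template-switching chimeras that carry a spurious
`(CAT)(CAG)(CAT)` block, and slippage that shifts the run length).

This package implements the resulting analysis chain: run-length
parsing of repeat tracts, interruption classification, the in-silico
SfaNI screen, clone-depth-corrected cohort accounting, the fragment-
sizing calibration, and the genotype–phenotype regression that
distinguishes the two candidate predictors of onset — total tract
length versus the longest uninterrupted CAG stretch. A synthetic
cohort generator reproduces the statistical structure of such data so
every stage can be exercised without patient material.

## The repeat grammar

A tract is represented as a `repeat_pattern`: ordered codon runs such
as `(CAG)12(CAT)(CAG)(CAT)(CAG)14`. Two statistics matter:

* **total repeats** — the sum of all run counts, interruptions
  included; this is the "allele size" convention for interrupted
  alleles, and what fragment sizing approximates;
* **longest pure CAG run** — the maximal contiguous CAG stretch.
  CAA codons encode glutamine too but break a *pure CAG* run, so they
  are accepted and flagged rather than treated as CAG. Pathogenicity
  is judged on this statistic against the full-penetrance threshold of
  39 repeats: an interrupted allele of total length 41 with longest
  run 20 is benign; `(CAG)46(CAT)(CAG)(CAT)(CAG)10` is pathogenic.

When the tract is extracted from sequence rather than notation, the
codon frame is anchored at the first base 3′ of the 5′ flank — the
reading frame of the cloned fragment. One-off non-CAG/CAA/CAT codons
(e.g. a lone AAG from a sequencing artefact) are retained and flagged
as codon class `other`, never silently dropped, because whether such a
clone is an artefact is a cohort-level judgement, not a parsing one.

Interruption configurations are labelled by their CAT-run count, with
the canonical `CAT_CAG_CAT` (two CAT runs separated by a single CAG)
distinguished because it dominates real data (~88% of interrupted
clones) and is also the signature of template-switching chimeras.

## The SfaNI screen

SfaNI recognises `GCATC`, cutting 5 nt downstream on the top strand
(the N5/N9 offsets are standard enzyme properties and are kept as
documented constants). Within a CAG context every CAT interruption
creates the motif (`…CAG CAT CAG… = …G CATC…`), so an amplicon
digests if and only if the tract is interrupted — the diagnostic
screen separating large-normal (interrupted) from pathogenic (pure)
alleles. `digest_fragments()` reports fragment lengths from top-strand
cut positions only, matching the single-number readout of a gel or
capillary trace. A CAT run at the extreme 5′ terminus of the tract has
no upstream CAG; whether it still yields a site then depends entirely
on the flank sequence, so the package makes no promise beyond what the
motif search returns (with the default *ATXN1* flanks it does not).

## Cohort accounting

Clone depth differs between patients, so raw clone counts over-weight
deeply sequenced individuals. `depth_corrected_frequencies()` converts
counts to within-patient percentages and averages those across
patients — each patient contributes equally to the cohort-level
frequency of a sequence. (The combining rule — sum of within-patient
percentages divided by the number of patients — is the package's
choice; it is the simplest rule in which depth correction is exact.)

A patient is called *interrupted* only when the evidence exceeds what
PCR artefacts explain: at least 2 interrupted pathogenic clones, or
interrupted clones exceeding 20% of the pathogenic clone count. A
single interrupted clone in an otherwise pure library is reported as
`artifact_suspect` and the patient analysed as uninterrupted. Both
constants are configurable; the defaults separate the
single-clone case from patients whose libraries are consistently
interrupted.

Mean allele sizes are clone-count-weighted means, with sub-threshold
pathogenic clones (slipped or chimeric small fragments) excluded
before averaging. Allele labels (`normal`/`pathogenic`) come from the
input: the laboratory protocol gel-separates the alleles before
cloning, so inferring labels computationally would only add error.

Transmission events are classified from parent/child mean total sizes
and interruption status: expansion/contraction/stable length by the
sign of the rounded size change, plus interruption loss or gain. The
classification is antisymmetric under swapping parent and child.

## The statistical core

The regression and test machinery is implemented in closed form so its
conventions are explicit:

* `ols_fit()` — simple OLS with `R2 = r²`, adjusted
  `R2 = 1 − (1 − R2)(n − 1)/(n − 2)` (one predictor throughout), and
  the residual standard deviation `s² = RSS/(n − 2)`.
* `prediction_interval()` — non-simultaneous bounds for a *new
  observation*: `ŷ(x0) ± t(α/2, n−2) · s · √(1 + 1/n + (x0 − x̄)²/Sxx)`.
  These are wider than confidence bands for the mean; their empirical
  coverage is checked by simulation (95% ± 2% over 10,000 replicates).
* `exp_fit()` — the two-parameter alternative `y = a·exp(c·x)`, fitted
  by damped Gauss–Newton from the log-linear initialisation. The
  two-parameter form mirrors the two-parameter linear model so the
  adjusted-R² comparison is like for like. Non-convergence raises an
  error carrying the RSS trace; a stalled step at a stationary point
  is convergence.
* `levene_test()` — the classic mean-centred variant (absolute
  deviations from the group mean), the default of mainstream
  statistics packages; two groups of identical values give a
  degenerate statistic and P = 1 with a warning.
* `welch_t_one_tailed()` — unequal-variance t with Satterthwaite
  degrees of freedom, upper-tailed for `mean(g1) > mean(g2)`.
* `fisher_exact_one_sided()` — exact upper tail `P(X ≥ a)` under the
  hypergeometric null, by direct enumeration with log-factorials. The
  one-sided tail is deliberate: comparing an 11% interruption
  prevalence (4/35) against a reference 6% (1/17) gives P = 0.467
  one-sided, which is the reported convention for this comparison (the
  two-sided sum gives a different value). The implementation is
  checked against exhaustive enumeration for every table with N ≤ 60.

`compare_residual_models()` chains the pieces: Levene on the absolute
residuals of the sizing and sequencing fits (motivating unequal
variances), then the one-tailed Welch test of H0 "the sizing fit's
mean absolute residual is not greater".

## Fragment-sizing calibration

Capillary electrophoresis under-sizes GC-rich repeat amplicons, and
the bias grows with length. The calibration is a line fitted with
sized repeats as the response: `sized = α·sequenced + β`, with
defaults α = 0.952, β = −0.822 (r = 0.999 over 100 clones). The
response direction is chosen so that inverting the line converts a
diagnostic size into an estimated true size: a sized 39 inverts to
41.83, i.e. 42 repeats — which is why a fragment-sizing threshold of
39 should really capture alleles sized at 36 or more. Over the cohort
range (≤ 83 repeats) the noiseless bias stays within 5 repeats.

Because simulated sized values are integers (a diagnostic trace
reports the most intense peak), the noiseless round-trip
`invert(simulate(true))` carries the rounding error δ/α with
|δ| ≤ 0.5: its exact bound is 0.5/α ≈ 0.525 repeats, attained near
sizes where α·true + β lands half-way between integers (e.g. true
= 14). The package asserts this exact bound.

## The onset analysis

`onset_analysis()` assembles the genotype–phenotype comparison. The
sizing fit uses the diagnostic sized repeat for every patient —
interrupted alleles cannot be distinguished by that method, so none
are excluded. The sequencing fit uses the clone-mean pathogenic allele
size for patients classified uninterrupted (artifact-suspect patients
included, per the artefact rule above). Interrupted patients are then
placed against the uninterrupted model's 95% prediction band twice:
at their clone-mean *total* size and at their clone-mean *longest pure
run*. When onset is driven by the longest run — as the data and the
cell model indicate — interrupted patients fall outside the band on
the total-size axis (their onset is "too late" for so long a tract)
and inside it on the longest-run axis.

`aggregation_analysis()` restates the same comparison in the cellular
model: the percentage of transfected cells containing aggregates,
regressed on construct length. Construct patterns with histidine
interruptions are stored in the DNA notation with `CAT` standing for a
histidine position — at protein level a CAT codon *is* a histidine —
so one grammar serves both patient alleles and constructs. On the
packaged construct table the uninterrupted series is linear in total
length (R² = 0.94), while the interrupted series is explained by the
longest pure run (R² = 0.97) and not by total length (R² = 0.40):

```{r aggregation}
aggregation_analysis()
```

## The synthetic generator

`synthetic_config()` fixes the study conditions; `gen_cohort()` is a
pure function of the config and its mandatory seed. Defaults, with
the reasoning:

| parameter | default | rationale |
|---|---|---|
| `n_patients` | 35 | the cohort scale the analyses target |
| `p_interrupted_pathogenic` | 4/35 | observed prevalence of interrupted pathogenic alleles |
| `config_frequencies` | 0.88 / 0.10 / 0.015 / 0.005 | observed configuration mix among interrupted clones |
| normal alleles | modal 29–30; interrupted centre `(CAG)12(CAT)(CAG)(CAT)(CAG)14±1` | the dominant large-normal structures |
| pathogenic pure run | round-normal(47, 5) clipped to 39–83 | modal pure allele ~47, range up to 83 |
| interrupted pathogenic | 5′ run round-normal(52, 3); 3′ block uniform 10–15 | long 5′ stretch with a short stable 3′ block |
| `jitter_sd_pathogenic` / `normal` | 1.5 / 0.5 repeats | the expanded allele's 5′ run is the unstable one |
| `p_chimera`, `p_slippage` | 0.02 each | rare per-clone PCR artefacts |
| onset model | A = −1.764, b = 124.817, σ = 7 y | the sequencing-fit line with residual spread at the observed scale |
| clones per allele | uniform 5–25 | "at least five colonies" sequencing depth |

Two structural choices matter for what the tests can show. Onset truth
is driven by the **longest pure run** of the true pathogenic allele,
so the pipeline's ability to discriminate the two predictors is
testable by construction: analysed against total size, interrupted
patients must drift above the band as the 5′/total gap grows.
Mosaicism jitters only the 5′ CAG run, holding the interruption block
and 3′ run fixed — interruptions stabilise the tract 3′ of the
histidine. The slippage step is geometric in magnitude with symmetric
sign, a minimal single-parameter choice; no distribution is claimed
from data. Parent-to-child transmission is *not* given calibrated
probabilities: the evidence base is two families, so the package
classifies observed events but does not simulate them by default.

What the generator does **not** emulate: sequencing base errors,
chromatogram artefacts, allele dropout, relatedness between patients,
ascertainment toward long alleles, or any aggregation-kinetics
biophysics. Tests passing on synthetic cohorts therefore demonstrate
the correctness of the statistical machinery under the stated model,
not robustness to every failure mode of real libraries.

## Numerical and testing notes

Degenerate inputs are contracts, not accidents: constant predictors
raise errors in `ols_fit()`/`pearson_r()`; zero-spread groups
degrade `levene_test()` to P = 1 with a warning; a cut position past
the sequence end is skipped with a warning while length conservation
is preserved; empty cohorts and unparseable rows fail with the row
index named. Ties in the modal-clone choice for fragment sizing
resolve to the first-sorted pattern, deterministically.

Problem sizes in the test suite are chosen to keep the full run in a
couple of minutes on one CPU: 200–1,000 random patterns for grammar
and digest properties, 10,000 replicates for prediction-band coverage,
1,000 for slope recovery, 200 full generator replicates for end-to-end
recovery, and exhaustive Fisher enumeration for all tables with
N ≤ 60. Oracles are independent routes: `lm`, `cor`, `t.test`,
`fisher.test`, `car::leveneTest`, `nls`, Biostrings pattern matching,
brute-force enumeration and hand-walked fixtures.

## Known limitations

* The artefact rule (≥2 clones or >20%) is a heuristic calibrated to
  reproduce the qualitative treatment of single-interrupted-clone
  patients; with very shallow libraries (fewer than five clones) it
  has little power to distinguish artefact from mosaicism.
* The calibration is linear over the observed range; nothing is
  claimed beyond ~100 repeats, and the GC-content mechanism behind the
  bias is not modelled physically.
* `exp_fit()` assumes positive responses; onset ages satisfy this, but
  the fit is not a general-purpose nonlinear least-squares routine.
* Whether cohort-level threshold tallies should be over distinct
  sequences or clone-weighted is a reporting convention; the package
  computes both and asserts neither.
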