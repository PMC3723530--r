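# Synthetic cohorts with the statistical structure the analyses assume:
# bimodal normal/pathogenic allele sizes, CAT-interruption configurations
# at the observed frequencies, clone-level mosaicism concentrated 5' of
# the interruption, PCR chimera/slippage artefacts, onset driven linearly
# by the longest pure CAG run, and fragment sizing through the
# calibration line. Everything is a deterministic function of the config
# and its seed.

clip_int <- function(x, lo, hi) as.integer(pmin(pmax(round(x), lo), hi))

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the study conditions the analyses target: 35
#' patients, about 4 of whom carry a truly interrupted pathogenic allele
#' (11% prevalence); interrupted-clone configurations at frequencies
#' 88% `CAT_CAG_CAT`, 10% `single_CAT`, 1.5% `triple_CAT`, 0.5%
#' `quad_CAT`; normal alleles modal around 29-30 repeats with the
#' canonical `(CAG)12(CAT)(CAG)(CAT)(CAG)14` interrupted structure;
#' pathogenic pure runs centred near 47 repeats within 39-83;
#' interrupted pathogenic alleles with a long 5' run (centre 52) and a
#' stable 3' block of 10-15 repeats; 5-25 clones per patient with 5'-run
#' jitter and small chimera/slippage artefact rates; onset
#' `A * longest_run + b + noise` with `A = -1.764`, `b = 124.817`,
#' noise SD 7 years; and the default sizing calibration.
#'
#' @param seed RNG seed (mandatory).
#' @param n_patients Number of patients.
#' @param p_interrupted_pathogenic Probability a patient's pathogenic
#'   allele is truly interrupted.
#' @param p_interrupted_normal Probability the normal allele is
#'   interrupted.
#' @param config_frequencies Named probabilities over interruption
#'   configurations, conditional on the allele being interrupted; must
#'   sum to at most 1 (names from `CAT_CAG_CAT`, `single_CAT`,
#'   `triple_CAT`, `quad_CAT`).
#' @param normal_mean,normal_sd,normal_range Normal-allele total size
#'   distribution (repeats).
#' @param pathogenic_run_mean,pathogenic_run_sd,pathogenic_run_range
#'   Pure pathogenic CAG-run distribution (repeats).
#' @param interrupted_run_mean,interrupted_run_sd 5' CAG-run
#'   distribution of interrupted pathogenic alleles.
#' @param three_prime_block_range Range of the stable 3' CAG block of
#'   interrupted pathogenic alleles.
#' @param jitter_sd_pathogenic,jitter_sd_normal Per-clone 5'-run jitter
#'   SD (repeats).
#' @param p_chimera,p_slippage Artefact probabilities per clone.
#' @param slippage_geom_p Geometric parameter of the slippage step size.
#' @param clones_range Clones sequenced per allele, sampled uniformly.
#' @param onset_A,onset_b,onset_noise_sd Onset model (years/repeat,
#'   years, years).
#' @param calibration A [calibration()] used for diagnostic sizing.
#' @param sizing_noise_sd Fragment-sizing noise SD (repeats).
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed,
                             n_patients = 35L,
                             p_interrupted_pathogenic = 4 / 35,
                             p_interrupted_normal = 0.8,
                             config_frequencies = c(CAT_CAG_CAT = 0.88,
                                                    single_CAT = 0.10,
                                                    triple_CAT = 0.015,
                                                    quad_CAT = 0.005),
                             normal_mean = 29.5, normal_sd = 1.5,
                             normal_range = c(20L, 36L),
                             pathogenic_run_mean = 47,
                             pathogenic_run_sd = 5,
                             pathogenic_run_range = c(39L, 83L),
                             interrupted_run_mean = 52,
                             interrupted_run_sd = 3,
                             three_prime_block_range = c(10L, 15L),
                             jitter_sd_pathogenic = 1.5,
                             jitter_sd_normal = 0.5,
                             p_chimera = 0.02,
                             p_slippage = 0.02,
                             slippage_geom_p = 0.5,
                             clones_range = c(5L, 25L),
                             onset_A = -1.764,
                             onset_b = 124.817,
                             onset_noise_sd = 7,
                             calibration = default_calibration(),
                             sizing_noise_sd = 0) {
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a seed is mandatory for the synthetic generator")
  }
  known <- c("CAT_CAG_CAT", "single_CAT", "triple_CAT", "quad_CAT")
  if (is.null(names(config_frequencies)) ||
      !all(names(config_frequencies) %in% known)) {
    stop("config_frequencies must be named from: ",
         paste(known, collapse = ", "))
  }
  if (any(config_frequencies < 0) || sum(config_frequencies) > 1 + 1e-9) {
    stop("config_frequencies must be non-negative and sum to at most 1")
  }
  rates <- c(p_interrupted_pathogenic, p_interrupted_normal, p_chimera,
             p_slippage, slippage_geom_p)
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  if (!inherits(calibration, "calibration")) {
    stop("'calibration' must be a calibration object")
  }
  structure(
    list(seed = as.integer(seed), n_patients = as.integer(n_patients),
         p_interrupted_pathogenic = p_interrupted_pathogenic,
         p_interrupted_normal = p_interrupted_normal,
         config_frequencies = config_frequencies,
         normal_mean = normal_mean, normal_sd = normal_sd,
         normal_range = normal_range,
         pathogenic_run_mean = pathogenic_run_mean,
         pathogenic_run_sd = pathogenic_run_sd,
         pathogenic_run_range = pathogenic_run_range,
         interrupted_run_mean = interrupted_run_mean,
         interrupted_run_sd = interrupted_run_sd,
         three_prime_block_range = three_prime_block_range,
         jitter_sd_pathogenic = jitter_sd_pathogenic,
         jitter_sd_normal = jitter_sd_normal,
         p_chimera = p_chimera, p_slippage = p_slippage,
         slippage_geom_p = slippage_geom_p,
         clones_range = clones_range,
         onset_A = onset_A, onset_b = onset_b,
         onset_noise_sd = onset_noise_sd,
         calibration = calibration, sizing_noise_sd = sizing_noise_sd),
    class = "synthetic_config"
  )
}

#' Read a synthetic-generator configuration from YAML or JSON
#'
#' Unknown keys are rejected; omitted keys take the
#' [synthetic_config()] defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file of
#'   [synthetic_config()] arguments.
#' @return A `synthetic_config`.
#' @export
read_synthetic_config <- function(path) {
  vals <- yaml::read_yaml(path)
  allowed <- names(formals(synthetic_config))
  unknown <- setdiff(names(vals), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(vals$config_frequencies)) {
    vals$config_frequencies <- unlist(vals$config_frequencies)
  }
  if (!is.null(vals$calibration)) {
    vals$calibration <- do.call(calibration, as.list(vals$calibration))
  }
  do.call(synthetic_config, vals)
}

# Sample an interruption configuration label from the config.
sample_config_label <- function(cfg) {
  f <- cfg$config_frequencies
  sample(names(f), 1L, prob = f)
}

# Build an interrupted pattern (CAG)five' [interruption block] (CAG)block
# for the sampled configuration.
build_interrupted <- function(run5, block3, label) {
  mid <- switch(label,
    single_CAT = list(codon = "CAT", count = 1L),
    CAT_CAG_CAT = list(codon = c("CAT", "CAG", "CAT"), count = c(1L, 1L, 1L)),
    triple_CAT = list(codon = c("CAT", "CAG", "CAT", "CAG", "CAT"),
                      count = rep(1L, 5L)),
    quad_CAT = list(codon = c("CAT", "CAG", "CAT", "CAG", "CAT", "CAG", "CAT"),
                    count = rep(1L, 7L)),
    stop("unknown configuration label: ", label)
  )
  repeat_pattern(c("CAG", mid$codon, "CAG"), c(run5, mid$count, block3))
}

#' Generate a true (germline) allele
#'
#' Interrupted pathogenic alleles have the structure
#' `(CAG)long [interruption block] (CAG)block` with the interruption
#' stabilising the 3' side; interrupted normal alleles centre on the
#' canonical `(CAG)12(CAT)(CAG)(CAT)(CAG)14` (3' block 14 +/- 1). Draws
#' from the current RNG state.
#'
#' @param class `"normal"` or `"pathogenic"`.
#' @param interrupted Logical.
#' @param cfg A [synthetic_config()].
#' @return A [repeat_pattern()].
#' @export
gen_true_allele <- function(class = c("pathogenic", "normal"), interrupted,
                            cfg) {
  class <- match.arg(class)
  if (class == "pathogenic") {
    if (interrupted) {
      run5 <- clip_int(stats::rnorm(1, cfg$interrupted_run_mean,
                                    cfg$interrupted_run_sd),
                       cfg$pathogenic_run_range[1L],
                       cfg$pathogenic_run_range[2L])
      block3 <- as.integer(sample(seq.int(cfg$three_prime_block_range[1L],
                                          cfg$three_prime_block_range[2L]), 1L))
      build_interrupted(run5, block3, sample_config_label(cfg))
    } else {
      run <- clip_int(stats::rnorm(1, cfg$pathogenic_run_mean,
                                   cfg$pathogenic_run_sd),
                      cfg$pathogenic_run_range[1L],
                      cfg$pathogenic_run_range[2L])
      repeat_pattern("CAG", run)
    }
  } else {
    if (interrupted) {
      block3 <- clip_int(14L + sample(-1L:1L, 1L), 1L, Inf)
      build_interrupted(12L, block3, sample_config_label(cfg))
    } else {
      run <- clip_int(stats::rnorm(1, cfg$normal_mean, cfg$normal_sd),
                      cfg$normal_range[1L], cfg$normal_range[2L])
      repeat_pattern("CAG", run)
    }
  }
}

# Apply a +/- k change to the 5' (first) CAG run, keeping it >= 1.
shift_first_run <- function(pattern, k) {
  count <- pattern$count
  count[1L] <- max(1L, count[1L] + as.integer(k))
  repeat_pattern(pattern$codon, count)
}

# PCR template-switching chimera: introduces a (CAT)(CAG)(CAT) block
# into the 5' run, mimicking switching between alleles mid-extension.
make_chimera <- function(pattern, cfg) {
  n1 <- pattern$count[1L]
  block <- as.integer(sample(seq.int(cfg$three_prime_block_range[1L],
                                     cfg$three_prime_block_range[2L]), 1L))
  a <- n1 - block - 3L
  if (a < 1L) return(pattern)  # run too short to host the insert
  head_runs <- list(codon = c("CAG", "CAT", "CAG", "CAT", "CAG"),
                    count = c(a, 1L, 1L, 1L, block))
  repeat_pattern(c(head_runs$codon, pattern$codon[-1L]),
                 c(head_runs$count, pattern$count[-1L]))
}

#' Generate a clone library for one allele
#'
#' Each clone is the true allele with integer Gaussian jitter applied to
#' the variable 5' CAG run (the 3' block of interrupted alleles is held
#' fixed — the interruption stabilises it); with probability `p_chimera`
#' the clone instead carries a PCR template-switching artefact
#' (`(CAT)(CAG)(CAT)` inserted into the 5' run), and with probability
#' `p_slippage` a symmetric geometric `+/- k` slip of the 5' run.
#'
#' @param true_allele A [repeat_pattern()].
#' @param n_clones Number of clones to draw, `>= 1`.
#' @param cfg A [synthetic_config()].
#' @param jitter_sd Jitter SD; defaults to the config's pathogenic
#'   jitter.
#' @return List of [repeat_pattern()] objects of length `n_clones`.
#' @export
gen_clone_library <- function(true_allele, n_clones, cfg,
                              jitter_sd = cfg$jitter_sd_pathogenic) {
  if (n_clones < 1L) stop("n_clones must be >= 1")
  lapply(seq_len(n_clones), function(i) {
    p <- true_allele
    if (jitter_sd > 0) {
      p <- shift_first_run(p, round(stats::rnorm(1, 0, jitter_sd)))
    }
    if (stats::runif(1) < cfg$p_chimera) {
      p <- make_chimera(p, cfg)
    }
    if (stats::runif(1) < cfg$p_slippage) {
      k <- (1L + stats::rgeom(1, cfg$slippage_geom_p)) * sample(c(-1L, 1L), 1L)
      p <- shift_first_run(p, k)
    }
    p
  })
}

#' Generate a synthetic cohort with its generating truth
#'
#' Per patient: a pathogenic and a normal true allele, clone libraries
#' for both, age at onset
#' `A * longest_pure_run(true pathogenic) + b + N(0, noise)` clipped at
#' 1 year, and a diagnostic sized repeat obtained by passing the modal
#' pathogenic clone's total length through the sizing calibration. The
#' RNG is seeded from `cfg$seed`, so identical configs give
#' byte-identical cohorts.
#'
#' @param cfg A [synthetic_config()].
#' @return A list with `cohort` (data frame in the [read_cohort()]
#'   schema) and `truth` (per-patient generating record: true patterns,
#'   totals, longest runs, interruption status, noiseless onset).
#' @export
gen_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)
  cohort_rows <- list()
  truth_rows <- list()
  for (i in seq_len(cfg$n_patients)) {
    pid <- sprintf("P%02d", i)
    int_path <- stats::runif(1) < cfg$p_interrupted_pathogenic
    int_norm <- stats::runif(1) < cfg$p_interrupted_normal
    true_path <- gen_true_allele("pathogenic", int_path, cfg)
    true_norm <- gen_true_allele("normal", int_norm, cfg)
    n_path <- sample(seq.int(cfg$clones_range[1L], cfg$clones_range[2L]), 1L)
    n_norm <- sample(seq.int(cfg$clones_range[1L], cfg$clones_range[2L]), 1L)
    clones_path <- gen_clone_library(true_path, n_path, cfg,
                                     cfg$jitter_sd_pathogenic)
    clones_norm <- gen_clone_library(true_norm, n_norm, cfg,
                                     cfg$jitter_sd_normal)
    onset_true <- cfg$onset_A * longest_pure_run(true_path) + cfg$onset_b
    onset <- max(1, onset_true +
                   stats::rnorm(1, 0, cfg$onset_noise_sd))
    path_tab <- table(vapply(clones_path, format_notation, ""))
    norm_tab <- table(vapply(clones_norm, format_notation, ""))
    modal_pattern <- names(path_tab)[which.max(path_tab)]
    modal_total <- total_repeats(parse_notation(modal_pattern))
    sized <- simulate_fragment_sizing(modal_total, cfg$calibration,
                                      cfg$sizing_noise_sd)
    row_block <- function(tab, label) data.frame(
      patient_id = pid, onset_age = onset, sized_repeat = sized,
      allele_label = label, pattern = names(tab),
      n_clones = as.integer(tab), stringsAsFactors = FALSE
    )
    cohort_rows[[length(cohort_rows) + 1L]] <- row_block(path_tab, "pathogenic")
    cohort_rows[[length(cohort_rows) + 1L]] <- row_block(norm_tab, "normal")
    truth_rows[[i]] <- data.frame(
      patient_id = pid,
      pathogenic_pattern = format_notation(true_path),
      normal_pattern = format_notation(true_norm),
      true_total = total_repeats(true_path),
      true_longest = longest_pure_run(true_path),
      interrupted = int_path,
      onset_noiseless = onset_true,
      onset = onset,
      sized_repeat = sized,
      stringsAsFactors = FALSE
    )
  }
  cohort <- do.call(rbind, cohort_rows)
  rownames(cohort) <- NULL
  list(cohort = cohort, truth = do.call(rbind, truth_rows))
}

#' Render a repeat pattern as a flanked amplicon
#'
#' `flank5 + tract + flank3`; [extract_repeat_region()] inverts it
#' exactly.
#'
#' @param pattern A [repeat_pattern()].
#' @param flank5,flank3 Flank sequences (defaults: [atxn1_flanks()]).
#' @return DNA string, FASTA-writable via [write_clone_fasta()].
#' @export
gen_flanked_dna <- function(pattern,
                            flank5 = atxn1_flanks()$five,
                            flank3 = atxn1_flanks()$three) {
  stopifnot_pattern(pattern)
  paste0(flank5, pattern_to_dna(pattern), flank3)
}

#' Write a full synthetic bundle to disk
#'
#' Generates a cohort from `cfg` and writes the cohort TSV, a clone
#' FASTA of flanked amplicons (IDs `PATIENT|ALLELE|CLONE`), the truth
#' record as JSON, and the config (with its seed) as YAML, for a fully
#' reproducible bundle.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
write_synthetic_bundle <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gen <- gen_cohort(cfg)
  paths <- list(
    cohort = file.path(dir, "cohort.tsv"),
    fasta = file.path(dir, "clones.fasta"),
    truth = file.path(dir, "truth.json"),
    config = file.path(dir, "config.yaml")
  )
  write_cohort(gen$cohort, paths$cohort)
  ids <- sprintf("%s|%s|%d", gen$cohort$patient_id, gen$cohort$allele_label,
                 seq_len(nrow(gen$cohort)))
  seqs <- vapply(gen$cohort$pattern,
                 function(p) gen_flanked_dna(parse_notation(p)), "")
  write_clone_fasta(ids, seqs, paths$fasta)
  jsonlite::write_json(gen$truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  cfg_out <- unclass(cfg)
  cfg_out$calibration <- unclass(cfg_out$calibration)
  cfg_out$config_frequencies <- as.list(cfg_out$config_frequencies)
  yaml::write_yaml(cfg_out, paths$config)
  invisible(paths)
}
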