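# End-to-end orchestration of the two headline analyses: the
# age-at-onset model (diagnostic sizing vs clone sequencing as the
# predictor) and the cell-aggregation model over polyQ constructs.

#' Age-at-onset analysis of a cohort
#'
#' Builds the two competing onset models and their comparison:
#'
#' * the *sizing fit* — onset age regressed on the diagnostic
#'   fragment-sized repeat, over all patients (interrupted alleles are
#'   indistinguishable by this method, so none are excluded);
#' * the *sequencing fit* — onset age regressed on the clone-sequencing
#'   mean pathogenic allele size, over patients whose pathogenic allele
#'   is uninterrupted (patients whose single interrupted clone is an
#'   artifact suspect count as uninterrupted);
#' * the exponential alternative to the sequencing fit;
#' * a residual-magnitude comparison of the two fits (Levene pre-test,
#'   then one-tailed Welch t);
#' * per-interrupted-patient placement relative to the sequencing fit's
#'   prediction band, using the clone-mean total size and the clone-mean
#'   longest pure CAG run as alternative predictors;
#' * a one-sided Fisher's exact test comparing the prevalence of
#'   interrupted pathogenic alleles against a reference cohort.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param reference_interrupted Reference prevalence as
#'   `c(interrupted, cohort size)` (default `c(1, 17)`).
#' @param level Prediction-band level (default 0.95).
#' @param threshold Pathogenic threshold in repeats (default 39).
#' @return An object of class `onset_report` with fields `sizing_fit`,
#'   `sequencing_fit`, `exp_fit`, `comparison`, `interrupted_points`
#'   (data frame), `fisher_p`, `n_patients`, `n_interrupted`.
#' @export
onset_analysis <- function(cohort, reference_interrupted = c(1L, 17L),
                           level = 0.95, threshold = 39L) {
  cohort <- validate_cohort(cohort)
  ids <- unique(cohort$patient_id)
  per_patient <- data.frame(
    patient_id = ids,
    onset = vapply(ids, function(i)
      cohort$onset_age[cohort$patient_id == i][1L], 0),
    sized = vapply(ids, function(i)
      cohort$sized_repeat[cohort$patient_id == i][1L], 0),
    stringsAsFactors = FALSE
  )
  per_patient$interrupted <- vapply(ids, function(i)
    interrupted_patient_flag(cohort, i), logical(1L))

  with_sizing <- per_patient[!is.na(per_patient$onset) &
                               !is.na(per_patient$sized), , drop = FALSE]
  if (nrow(with_sizing) < 3L) {
    stop("sizing fit failed: fewer than 3 patients with onset age and ",
         "sized repeat")
  }
  sizing_fit <- ols_fit(with_sizing$sized, with_sizing$onset)

  unint <- per_patient[!per_patient$interrupted & !is.na(per_patient$onset), ,
                       drop = FALSE]
  if (nrow(unint) < 3L) {
    stop("sequencing fit failed: fewer than 3 uninterrupted patients ",
         "with onset age")
  }
  unint$mean_size <- vapply(unint$patient_id, function(i)
    mean_allele_size(cohort, i, "pathogenic", "total", threshold), 0)
  sequencing_fit <- ols_fit(unint$mean_size, unint$onset)
  expo <- exp_fit(unint$mean_size, unint$onset)
  comparison <- compare_residual_models(sizing_fit, sequencing_fit)

  inter <- per_patient[per_patient$interrupted & !is.na(per_patient$onset), ,
                       drop = FALSE]
  if (nrow(inter) > 0L) {
    mt <- vapply(inter$patient_id, function(i)
      mean_allele_size(cohort, i, "pathogenic", "total", threshold), 0)
    ml <- vapply(inter$patient_id, function(i)
      mean_allele_size(cohort, i, "pathogenic", "longest", threshold), 0)
    band_t <- prediction_interval(sequencing_fit, mt, level)
    band_l <- prediction_interval(sequencing_fit, ml, level)
    interrupted_points <- data.frame(
      patient_id = inter$patient_id,
      onset = inter$onset,
      mean_total = mt,
      mean_longest = ml,
      in_band_total = inter$onset >= band_t$lower & inter$onset <= band_t$upper,
      in_band_longest = inter$onset >= band_l$lower & inter$onset <= band_l$upper,
      stringsAsFactors = FALSE
    )
  } else {
    interrupted_points <- data.frame(
      patient_id = character(0), onset = numeric(0), mean_total = numeric(0),
      mean_longest = numeric(0), in_band_total = logical(0),
      in_band_longest = logical(0), stringsAsFactors = FALSE
    )
  }

  n_int <- sum(per_patient$interrupted)
  n_all <- nrow(per_patient)
  fisher_p <- fisher_exact_one_sided(
    n_int, n_all - n_int,
    reference_interrupted[1L],
    reference_interrupted[2L] - reference_interrupted[1L]
  )

  structure(
    list(sizing_fit = sizing_fit, sequencing_fit = sequencing_fit,
         exp_fit = expo, comparison = comparison,
         interrupted_points = interrupted_points,
         fisher_p = fisher_p, n_patients = n_all, n_interrupted = n_int,
         level = level),
    class = "onset_report"
  )
}

#' @export
print.onset_report <- function(x, ...) {
  cat("<onset_report>", x$n_patients, "patients,", x$n_interrupted,
      "with interrupted pathogenic alleles\n")
  cat(sprintf("  sizing fit:     r = %.3f, adjR2 = %.3f\n",
              x$sizing_fit$r, x$sizing_fit$adjR2))
  cat(sprintf("  sequencing fit: r = %.3f, adjR2 = %.3f (exp adjR2 = %.3f)\n",
              x$sequencing_fit$r, x$sequencing_fit$adjR2, x$exp_fit$adjR2))
  cat(sprintf("  residual comparison: Levene P = %.3f, Welch one-tailed P = %.3f\n",
              x$comparison$levene_P, x$comparison$welch_one_tailed_P))
  cat(sprintf("  interruption prevalence vs reference: Fisher one-sided P = %.3f\n",
              x$fisher_p))
  invisible(x)
}

#' The packaged polyQ-construct aggregation table
#'
#' Cell-model data: polyglutamine constructs (with and without histidine
#' interruptions) and the percentage of transfected cells containing
#' aggregates. Construct patterns are stored in the DNA notation with
#' `CAT` standing for a histidine position, so the same repeat grammar
#' serves patient alleles and constructs.
#'
#' @return Data frame with columns `group`
#'   (`uninterrupted`/`interrupted`), `pattern`, `percent`, `sd`.
#' @export
aggregation_table <- function() {
  path <- system.file("extdata", "aggregation_constructs.tsv",
                      package = "sca1repeats", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Aggregation-versus-length analysis of polyQ constructs
#'
#' Regresses the percentage of aggregate-containing cells on repeat
#' length, three ways: uninterrupted constructs against total length,
#' and interrupted constructs against either total length or the
#' longest pure polyQ run (histidine interruptions count toward the
#' total but break a pure run, exactly as CAT codons do at DNA level).
#' The interrupted fits share their response vector, so their
#' R-squared values are directly comparable.
#'
#' @param table Data frame with columns `group`, `pattern`, `percent`
#'   (default: the packaged [aggregation_table()]).
#' @return An object of class `aggregation_report` with fields
#'   `fit_uninterrupted_total`, `fit_interrupted_total`,
#'   `fit_interrupted_longest` ([ols_fit()] objects) and `data` (the
#'   per-row derived predictors).
#' @examples
#' rep <- aggregation_analysis()
#' round(rep$fit_interrupted_longest$R2, 2) # 0.97
#' @export
aggregation_analysis <- function(table = aggregation_table()) {
  needed <- c("group", "pattern", "percent")
  missing_cols <- setdiff(needed, names(table))
  if (length(missing_cols) > 0L) {
    stop("aggregation table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  pats <- vector("list", nrow(table))
  for (i in seq_len(nrow(table))) {
    pats[[i]] <- tryCatch(parse_notation(table$pattern[i]),
                          error = function(e) stop("row ", i, ": ",
                                                   conditionMessage(e),
                                                   call. = FALSE))
  }
  dat <- data.frame(
    group = table$group,
    pattern = vapply(pats, format_notation, ""),
    percent = table$percent,
    total = vapply(pats, total_repeats, 0L),
    longest = vapply(pats, longest_pure_run, 0L),
    stringsAsFactors = FALSE
  )
  un <- dat[dat$group == "uninterrupted", , drop = FALSE]
  int <- dat[dat$group == "interrupted", , drop = FALSE]
  if (nrow(un) < 3L || nrow(int) < 3L) {
    stop("need at least 3 uninterrupted and 3 interrupted rows; got ",
         nrow(un), " and ", nrow(int))
  }
  structure(
    list(fit_uninterrupted_total = ols_fit(un$total, un$percent),
         fit_interrupted_total = ols_fit(int$total, int$percent),
         fit_interrupted_longest = ols_fit(int$longest, int$percent),
         data = dat),
    class = "aggregation_report"
  )
}

#' @export
print.aggregation_report <- function(x, ...) {
  cat("<aggregation_report>\n")
  cat(sprintf("  uninterrupted %% vs total length:  R2 = %.2f\n",
              x$fit_uninterrupted_total$R2))
  cat(sprintf("  interrupted %% vs total length:    R2 = %.2f\n",
              x$fit_interrupted_total$R2))
  cat(sprintf("  interrupted %% vs longest Q run:   R2 = %.2f\n",
              x$fit_interrupted_longest$R2))
  invisible(x)
}

#' Serialize an onset or aggregation report to JSON
#'
#' @param report An `onset_report` or `aggregation_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  strip <- function(f) {
    if (inherits(f, "linear_fit")) {
      f[c("A", "b", "r", "R2", "adjR2", "n", "s", "x_bar", "Sxx", "df",
          "residuals")]
    } else if (inherits(f, "exp_fit")) {
      f[c("a", "c", "R2", "adjR2", "RSS", "n", "iterations", "converged")]
    } else {
      unclass(f)
    }
  }
  out <- lapply(unclass(report), function(el) {
    if (inherits(el, c("linear_fit", "exp_fit", "comparison_result"))) {
      strip(el)
    } else el
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
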