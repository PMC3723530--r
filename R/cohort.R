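# Helpers computing per-row pattern statistics for a cohort data frame.
cohort_pattern_stats <- function(df) {
  pats <- lapply(df$pattern, parse_notation)
  data.frame(
    canonical = vapply(pats, format_notation, ""),
    total = vapply(pats, total_repeats, 0L),
    longest = vapply(pats, longest_pure_run, 0L),
    interrupted = vapply(pats, function(p) classify_interruption(p)$n_CAT_runs > 0L,
                         logical(1L)),
    stringsAsFactors = FALSE
  )
}

#' Clone-depth-corrected sequence frequencies
#'
#' Because the number of clones sequenced differs between patients, raw
#' clone counts over-weight deeply sequenced individuals. Each distinct
#' sequence's clone count is first converted to a within-patient
#' percentage (summing to 100 per patient, normal and pathogenic clones
#' pooled); the overall percentage of a sequence is then the sum of its
#' within-patient percentages divided by the number of patients, so
#' every patient contributes equally.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @return Data frame with columns `pattern` (canonical notation) and
#'   `overall_pct`, sorted by decreasing frequency; the `overall_pct`
#'   column sums to 100.
#' @export
depth_corrected_frequencies <- function(cohort) {
  cohort <- validate_cohort(cohort)
  st <- cohort_pattern_stats(cohort)
  per_patient_total <- tapply(cohort$n_clones, cohort$patient_id, sum)
  within_pct <- 100 * cohort$n_clones /
    as.numeric(per_patient_total[cohort$patient_id])
  n_patients <- length(per_patient_total)
  overall <- tapply(within_pct, st$canonical, sum) / n_patients
  out <- data.frame(pattern = names(overall),
                    overall_pct = as.numeric(overall),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$overall_pct, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Clone-weighted mean allele size for one patient
#'
#' The per-patient allele size used in the onset model: the
#' clone-count-weighted mean of either the total tract length or the
#' longest pure CAG run over the patient's clones of the requested
#' allele. For the pathogenic allele, clones whose total length falls
#' below the pathogenic threshold are excluded before averaging (small
#' slipped or chimeric clones would otherwise drag the mean down).
#'
#' @param cohort Cohort data frame.
#' @param patient_id Patient whose clones to average.
#' @param allele_label `"normal"` or `"pathogenic"`.
#' @param measure `"total"` (tract length incl. interruptions) or
#'   `"longest"` (longest pure CAG run).
#' @param pathogenic_threshold Exclusion threshold applied to pathogenic
#'   clones (default 39 repeats).
#' @return Numeric mean size in repeats.
#' @export
mean_allele_size <- function(cohort, patient_id,
                             allele_label = c("pathogenic", "normal"),
                             measure = c("total", "longest"),
                             pathogenic_threshold = 39L) {
  allele_label <- match.arg(allele_label)
  measure <- match.arg(measure)
  rows <- cohort[cohort$patient_id == patient_id &
                   cohort$allele_label == allele_label, , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no ", allele_label, " clones for patient ", patient_id)
  }
  st <- cohort_pattern_stats(rows)
  if (allele_label == "pathogenic") {
    keep <- st$total >= pathogenic_threshold
    rows <- rows[keep, , drop = FALSE]
    st <- st[keep, , drop = FALSE]
    if (nrow(rows) == 0L) {
      stop("no pathogenic clones at or above ", pathogenic_threshold,
           " repeats for patient ", patient_id)
    }
  }
  value <- if (measure == "total") st$total else st$longest
  sum(value * rows$n_clones) / sum(rows$n_clones)
}

#' Interruption status of a patient's pathogenic allele
#'
#' A single interrupted clone within a population of uninterrupted
#' clones is consistent with a PCR template-switching artefact and does
#' not make the patient "interrupted". A patient is flagged interrupted
#' only when at least `min_interrupted_clones` pathogenic clones are
#' interrupted or interrupted clones exceed `max_artifact_fraction` of
#' the pathogenic clone count; a lone interrupted clone is reported as
#' `artifact_suspect` instead.
#'
#' @param cohort Cohort data frame.
#' @param patient_id Patient to assess.
#' @param min_interrupted_clones Clone count at which interruption is
#'   accepted as real (default 2).
#' @param max_artifact_fraction Fraction of pathogenic clones above
#'   which interruption is accepted even if the count is low
#'   (default 0.2).
#' @return A list with elements `interrupted`, `artifact_suspect`,
#'   `n_interrupted_clones`, `n_pathogenic_clones`.
#' @export
patient_interruption_status <- function(cohort, patient_id,
                                        min_interrupted_clones = 2L,
                                        max_artifact_fraction = 0.2) {
  rows <- cohort[cohort$patient_id == patient_id &
                   cohort$allele_label == "pathogenic", , drop = FALSE]
  if (nrow(rows) == 0L) {
    stop("no pathogenic clones for patient ", patient_id)
  }
  st <- cohort_pattern_stats(rows)
  n_total <- sum(rows$n_clones)
  n_int <- sum(rows$n_clones[st$interrupted])
  interrupted <- n_int >= min_interrupted_clones ||
    n_int > max_artifact_fraction * n_total
  list(interrupted = interrupted,
       artifact_suspect = !interrupted && n_int > 0L,
       n_interrupted_clones = n_int,
       n_pathogenic_clones = n_total)
}

#' @rdname patient_interruption_status
#' @return `interrupted_patient_flag()` returns the logical flag alone.
#' @export
interrupted_patient_flag <- function(cohort, patient_id,
                                     min_interrupted_clones = 2L,
                                     max_artifact_fraction = 0.2) {
  patient_interruption_status(cohort, patient_id, min_interrupted_clones,
                              max_artifact_fraction)$interrupted
}

#' Classify a parent-to-child transmission event
#'
#' Labels the intergenerational behaviour of the expanded allele from
#' the mean total sizes and interruption status of parent and child:
#' expansion / contraction / stable length by the sign of the rounded
#' size change, plus loss or gain of the interruption.
#'
#' @param parent_mean_total,child_mean_total Mean total repeat sizes
#'   (clone sequencing) of the transmitted allele; must be positive.
#' @param parent_interrupted,child_interrupted Logical interruption
#'   status of each carrier's pathogenic allele.
#' @return A list of class `transmission_event` with elements `labels`
#'   (character subset of expansion, contraction, stable_length,
#'   interruption_loss, interruption_gain) and `delta_total` (rounded
#'   child minus parent size, repeats).
#' @examples
#' classify_transmission(53, TRUE, 48, FALSE) # contraction + interruption_loss
#' @export
classify_transmission <- function(parent_mean_total, parent_interrupted,
                                  child_mean_total, child_interrupted) {
  if (parent_mean_total <= 0 || child_mean_total <= 0) {
    stop("allele sizes must be positive")
  }
  delta <- as.integer(round(child_mean_total - parent_mean_total))
  labels <- if (delta > 0L) "expansion" else if (delta < 0L) "contraction"
    else "stable_length"
  if (isTRUE(parent_interrupted) && !isTRUE(child_interrupted)) {
    labels <- c(labels, "interruption_loss")
  } else if (!isTRUE(parent_interrupted) && isTRUE(child_interrupted)) {
    labels <- c(labels, "interruption_gain")
  }
  structure(list(labels = labels, delta_total = delta),
            class = "transmission_event")
}

#' @export
print.transmission_event <- function(x, ...) {
  cat("<transmission_event> ", paste(x$labels, collapse = " + "),
      " (delta ", sprintf("%+d", x$delta_total), " repeats)\n", sep = "")
  invisible(x)
}

#' Tally clones against the pathogenic threshold
#'
#' Cross-tabulates clone sequences by interruption status and whether
#' their total length reaches the pathogenic threshold, both over
#' distinct sequences (each unique sequence counted once across the
#' cohort) and clone-count-weighted. Row percentages give, e.g., the
#' share of uninterrupted clones at or above the threshold.
#'
#' @param cohort Cohort data frame.
#' @param threshold Pathogenic threshold in repeats (default 39).
#' @return A list with elements `distinct` and `weighted`, each a list
#'   of `counts` (2x2 integer matrix, rows uninterrupted/interrupted,
#'   columns below/at-or-above) and `row_pct` (row percentages).
#' @export
threshold_tally <- function(cohort, threshold = 39L) {
  cohort <- validate_cohort(cohort)
  st <- cohort_pattern_stats(cohort)
  make_tab <- function(interrupted, above, w) {
    counts <- matrix(0, 2L, 2L,
                     dimnames = list(c("uninterrupted", "interrupted"),
                                     c("below_threshold", "at_or_above")))
    for (i in seq_along(interrupted)) {
      counts[interrupted[i] + 1L, above[i] + 1L] <-
        counts[interrupted[i] + 1L, above[i] + 1L] + w[i]
    }
    rs <- rowSums(counts)
    row_pct <- 100 * counts / ifelse(rs == 0, NA, rs)
    list(counts = counts, row_pct = row_pct)
  }
  dedup <- !duplicated(st$canonical)
  list(
    distinct = make_tab(st$interrupted[dedup], st$total[dedup] >= threshold,
                        rep(1L, sum(dedup))),
    weighted = make_tab(st$interrupted, st$total >= threshold, cohort$n_clones)
  )
}

#' Write a JSON summary report for a cohort
#'
#' Bundles the depth-corrected sequence frequencies and the
#' threshold tally into a single JSON report.
#'
#' @param cohort Cohort data frame.
#' @param path Output JSON path.
#' @param threshold Pathogenic threshold passed to [threshold_tally()].
#' @return `path`, invisibly.
#' @export
write_cohort_summary <- function(cohort, path, threshold = 39L) {
  tally <- threshold_tally(cohort, threshold)
  report <- list(
    n_patients = length(unique(cohort$patient_id)),
    n_clones = sum(cohort$n_clones),
    n_distinct_sequences = length(unique(
      vapply(cohort$pattern, function(p) format_notation(parse_notation(p)), ""))),
    threshold = threshold,
    depth_corrected_frequencies = depth_corrected_frequencies(cohort),
    threshold_tally = tally
  )
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
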