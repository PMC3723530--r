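#' Read clone sequences from FASTA
#'
#' Reads one record per clone. Record IDs are expected in the form
#' `PATIENT|ALLELE|CLONE`; when they match, the components are split out
#' into columns, otherwise those columns are `NA` and only `id` is set.
#'
#' @param path FASTA file of clone amplicon or tract sequences.
#' @return Data frame with columns `id`, `patient_id`, `allele_label`,
#'   `clone_id`, `sequence`.
#' @export
read_clone_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  id <- sub("\\s.*$", "", names(seqs))
  parts <- strsplit(id, "|", fixed = TRUE)
  three <- lengths(parts) == 3L
  data.frame(
    id = id,
    patient_id = ifelse(three, vapply(parts, `[`, "", 1L), NA_character_),
    allele_label = ifelse(three, vapply(parts, `[`, "", 2L), NA_character_),
    clone_id = ifelse(three, vapply(parts, `[`, "", 3L), NA_character_),
    sequence = toupper(as.character(seqs)),
    stringsAsFactors = FALSE
  )
}

#' Write clone sequences to FASTA
#'
#' @param ids Character vector of record IDs (`PATIENT|ALLELE|CLONE`).
#' @param sequences Character vector of DNA strings, parallel to `ids`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_clone_fasta <- function(ids, sequences, path) {
  stopifnot(length(ids) == length(sequences))
  x <- Biostrings::DNAStringSet(sequences)
  names(x) <- ids
  Biostrings::writeXStringSet(x, filepath = path)
  invisible(path)
}

COHORT_COLUMNS <- c("patient_id", "onset_age", "sized_repeat",
                    "allele_label", "pattern", "n_clones")

#' Read a cohort table
#'
#' The cohort TSV has one row per distinct clone sequence with columns
#' `patient_id`, `onset_age` (years; may be `NA`), `sized_repeat`
#' (diagnostic fragment-sized repeats; may be `NA`), `allele_label`
#' (`normal`/`pathogenic`, assigned upstream by gel separation),
#' `pattern` (parenthesized repeat notation) and `n_clones` (count of
#' clones carrying that sequence).
#'
#' @param path Path to a tab-separated cohort file with a header row.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""))
  validate_cohort(df)
}

#' Validate a cohort data frame
#'
#' @param df Data frame in the cohort schema (see [read_cohort()]).
#' @return `df`, with `patient_id` coerced to character, invisibly
#'   usable downstream; stops with an informative message on schema
#'   violations.
#' @export
validate_cohort <- function(df) {
  missing_cols <- setdiff(COHORT_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop("cohort schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) stop("cohort schema error: empty cohort")
  df$patient_id <- as.character(df$patient_id)
  bad_label <- !df$allele_label %in% c("normal", "pathogenic")
  if (any(bad_label)) {
    stop("cohort schema error: invalid allele_label at row(s): ",
         paste(utils::head(which(bad_label), 5L), collapse = ", "))
  }
  if (any(!is.na(df$onset_age) & df$onset_age <= 0)) {
    stop("cohort schema error: onset_age must be positive where present")
  }
  if (any(is.na(df$n_clones) | df$n_clones < 1)) {
    stop("cohort schema error: n_clones must be >= 1 on every row")
  }
  # every pattern must parse; report the offending row
  for (i in seq_len(nrow(df))) {
    tryCatch(parse_notation(df$pattern[i]),
             error = function(e) stop("cohort schema error at row ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  }
  df
}

#' Write a cohort table as TSV
#'
#' @param df Cohort data frame (see [read_cohort()] for the schema).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(df, path) {
  utils::write.table(df[, COHORT_COLUMNS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
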