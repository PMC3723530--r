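# Codon classes of the ATXN1 glutamine tract. CAG/CAA encode glutamine;
# CAT encodes the histidine interruption. Anything else is legal in a
# parsed pattern but flagged, since tracts occasionally carry one-off
# artefact codons (e.g. a single AAG) that must not be silently dropped.
GLUTAMINE_CODONS <- c("CAG", "CAA")
INTERRUPTION_CODON <- "CAT"

#' Construct a repeat pattern from codon runs
#'
#' A `repeat_pattern` is the run-length encoding of a glutamine-tract
#' region: an ordered set of codon runs such as `(CAG)12 (CAT) (CAG)14`.
#' It is the central object from which all repeat statistics (total
#' length, longest pure CAG stretch, interruption configuration) derive.
#'
#' @param codon Character vector of 3-letter uppercase DNA codons.
#' @param count Integer vector of run lengths, same length as `codon`,
#'   all `>= 1`.
#' @param merge If `TRUE` (default), adjacent runs with equal codons are
#'   merged rather than rejected.
#'
#' @return An object of class `repeat_pattern`: a list with elements
#'   `codon` and `count`. Codons outside the glutamine/interruption
#'   alphabet are retained and reported by [classify_interruption()] as
#'   class `"other"`.
#' @examples
#' repeat_pattern(c("CAG", "CAT", "CAG"), c(12L, 1L, 14L))
#' @export
repeat_pattern <- function(codon, count, merge = TRUE) {
  if (length(codon) == 0L) {
    stop("a repeat pattern must contain at least one codon run")
  }
  if (length(codon) != length(count)) {
    stop("'codon' and 'count' must have equal length")
  }
  codon <- toupper(as.character(codon))
  bad <- codon[!grepl("^[ACGT]{3}$", codon)]
  if (length(bad) > 0L) {
    stop("invalid codon token(s): ", paste(unique(bad), collapse = ", "))
  }
  count_num <- suppressWarnings(as.numeric(count))
  if (anyNA(count_num) || any(count_num < 1) || any(count_num != floor(count_num))) {
    stop("run counts must be positive integers; offending count(s): ",
         paste(count[is.na(count_num) | count_num < 1 | count_num != floor(count_num)],
               collapse = ", "))
  }
  count <- as.integer(count_num)
  if (merge) {
    keep <- c(TRUE, codon[-1L] != codon[-length(codon)])
    grp <- cumsum(keep)
    codon <- codon[keep]
    count <- as.integer(tapply(count, grp, sum))
  } else if (any(codon[-1L] == codon[-length(codon)])) {
    stop("adjacent runs must have different codons")
  }
  structure(list(codon = codon, count = count), class = "repeat_pattern")
}

#' @export
print.repeat_pattern <- function(x, ...) {
  cat("<repeat_pattern> ", format_notation(x), "\n", sep = "")
  cat("  total repeats: ", total_repeats(x),
      "; longest pure CAG run: ", longest_pure_run(x), "\n", sep = "")
  invisible(x)
}

#' @export
`==.repeat_pattern` <- function(e1, e2) {
  identical(e1$codon, e2$codon) && identical(e1$count, e2$count)
}

is_repeat_pattern <- function(x) inherits(x, "repeat_pattern")

stopifnot_pattern <- function(pattern) {
  if (!is_repeat_pattern(pattern)) {
    stop("expected a 'repeat_pattern' object; got ", class(pattern)[1L])
  }
  invisible(pattern)
}

#' Parse parenthesized repeat notation
#'
#' Parses strings such as `"(CAG)12(CAT)(CAG)(CAT)(CAG)14"` into a
#' [repeat_pattern()]. A codon in parentheses optionally followed by an
#' integer count (absent count = 1). Whitespace and underscores between
#' tokens are tolerated, so `"(CAG)_12_(CAT)"` parses identically.
#'
#' @param text A single character string in parenthesized notation.
#' @return A [repeat_pattern()]; accidentally adjacent equal codons are
#'   merged into one run.
#' @examples
#' parse_notation("(CAG)12(CAT)(CAG)(CAT)(CAG)14")
#' total_repeats(parse_notation("(CAG)47"))
#' @seealso [format_notation()] for the inverse.
#' @export
parse_notation <- function(text) {
  if (length(text) != 1L || !is.character(text)) {
    stop("parse error: 'text' must be a single character string")
  }
  stripped <- gsub("[[:space:]_]+", "", text)
  if (!nzchar(stripped)) {
    stop("parse error: empty repeat notation")
  }
  m <- gregexpr("\\(([^()]*)\\)([0-9]*)", stripped, perl = TRUE)[[1L]]
  tokens <- regmatches(stripped, list(m))[[1L]]
  if (length(tokens) == 0L || sum(attr(m, "match.length")) != nchar(stripped)) {
    residue <- if (length(tokens) == 0L) stripped else
      paste(strsplit(gsub("\\(([^()]*)\\)([0-9]*)", "\x01", stripped), "\x01")[[1L]],
            collapse = " ")
    stop("parse error: unparseable token(s) near: ", trimws(residue))
  }
  codon <- sub("^\\(([^()]*)\\).*$", "\\1", tokens)
  count_str <- sub("^\\([^()]*\\)", "", tokens)
  bad <- !grepl("^[ACGTacgt]{3}$", codon)
  if (any(bad)) {
    stop("parse error: not a DNA codon: (", codon[which(bad)[1L]], ")")
  }
  count <- ifelse(nzchar(count_str), suppressWarnings(as.integer(count_str)), 1L)
  zero <- !is.na(count) & count < 1L
  if (any(zero)) {
    stop("parse error: zero or negative run count in token ", tokens[which(zero)[1L]])
  }
  repeat_pattern(toupper(codon), count, merge = TRUE)
}

#' Format a repeat pattern as canonical notation
#'
#' Inverse of [parse_notation()]: canonical form uses no subscripts,
#' underscores or whitespace, and omits the count for single-codon runs,
#' e.g. `"(CAG)12(CAT)(CAG)(CAT)(CAG)14"`.
#'
#' @param pattern A [repeat_pattern()].
#' @return A character string; `parse_notation(format_notation(p))`
#'   reproduces `p` exactly.
#' @export
format_notation <- function(pattern) {
  stopifnot_pattern(pattern)
  paste0("(", pattern$codon, ")",
         ifelse(pattern$count > 1L, pattern$count, ""),
         collapse = "")
}

#' Render a repeat pattern as a DNA string
#'
#' @param pattern A [repeat_pattern()].
#' @return Uppercase DNA string of the concatenated codon runs.
#' @export
pattern_to_dna <- function(pattern) {
  stopifnot_pattern(pattern)
  paste(rep.int(pattern$codon, pattern$count), collapse = "")
}

#' Extract and run-length encode the repeat region between two flanks
#'
#' Locates the unique occurrences of `five_prime_flank` and
#' `three_prime_flank` on the given strand and codon-frames the region
#' between them, anchoring the reading frame at the first base after the
#' 5' flank (the cloned-fragment reading frame of the Q tract).
#'
#' @param dna Uppercase DNA string containing the amplified fragment.
#' @param five_prime_flank,three_prime_flank Flanking sequences, each
#'   occurring exactly once and in order. Defaults are the ATXN1
#'   repeat-flanking primer sequences (see [atxn1_flanks()]).
#' @return A [repeat_pattern()] of the between-flank region.
#' @examples
#' fl <- atxn1_flanks()
#' extract_repeat_region(paste0(fl$five, "CAGCAGCAGCATCAGCAG", fl$three))
#' @export
extract_repeat_region <- function(dna,
                                  five_prime_flank = atxn1_flanks()$five,
                                  three_prime_flank = atxn1_flanks()$three) {
  check_dna(dna)
  check_dna(five_prime_flank)
  check_dna(three_prime_flank)
  p5 <- fixed_matches(dna, five_prime_flank)
  p3 <- fixed_matches(dna, three_prime_flank)
  if (length(p5) != 1L) {
    stop("anchoring error: 5' flank ",
         if (length(p5) == 0L) "absent" else "duplicated", " in input")
  }
  if (length(p3) != 1L) {
    stop("anchoring error: 3' flank ",
         if (length(p3) == 0L) "absent" else "duplicated", " in input")
  }
  start <- p5 + nchar(five_prime_flank)   # first base of region (1-based)
  end <- p3 - 1L                          # last base of region
  if (end < start) {
    stop("anchoring error: flanks out of order or overlapping")
  }
  region <- substr(dna, start, end)
  if (nchar(region) %% 3L != 0L) {
    stop("frame error: repeat region length ", nchar(region),
         " nt is not divisible by 3")
  }
  n <- nchar(region) %/% 3L
  codons <- substring(region, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  repeat_pattern(codons, rep.int(1L, n), merge = TRUE)
}

#' Total repeat-tract length including interruptions
#'
#' The allele size convention for interrupted alleles: the total length
#' of the tract in repeat units, CAT interruptions included.
#'
#' @param pattern A [repeat_pattern()].
#' @return Integer sum of all run counts.
#' @examples
#' total_repeats(parse_notation("(CAG)70(CAT)(CAG)(CAT)(CAG)10")) # 83
#' @export
total_repeats <- function(pattern) {
  stopifnot_pattern(pattern)
  sum(pattern$count)
}

#' Longest uninterrupted run of a codon
#'
#' The longest contiguous stretch of pure CAG repeats is the statistic
#' that tracks pathogenicity and age at onset; CAA and CAT codons both
#' break a pure CAG run.
#'
#' @param pattern A [repeat_pattern()].
#' @param codon Codon whose maximal run is sought (default `"CAG"`).
#' @return Integer; 0 if the codon is absent.
#' @examples
#' longest_pure_run(parse_notation("(CAG)51(CAT)(CAG)(CAT)(CAG)10")) # 51
#' @export
longest_pure_run <- function(pattern, codon = "CAG") {
  stopifnot_pattern(pattern)
  hits <- pattern$count[pattern$codon == codon]
  if (length(hits) == 0L) 0L else max(hits)
}

#' Classify the interruption configuration of a pattern
#'
#' Counts CAT runs and assigns the configuration label used for cohort
#' accounting: `pure` (no CAT), `single_CAT`, `CAT_CAG_CAT` (exactly two
#' CAT runs separated by a single CAG run), `triple_CAT`, `quad_CAT`, or
#' `other`. Patterns containing codons outside the CAG/CAA/CAT alphabet
#' are additionally flagged (`has_other_codon`), never dropped.
#'
#' @param pattern A [repeat_pattern()].
#' @return A list of class `interruption_config` with elements `label`,
#'   `n_CAT_runs` and `has_other_codon`.
#' @examples
#' classify_interruption(parse_notation("(CAG)12(CAT)(CAG)(CAT)(CAG)14"))
#' @export
classify_interruption <- function(pattern) {
  stopifnot_pattern(pattern)
  is_cat <- pattern$codon == INTERRUPTION_CODON
  n_cat <- sum(is_cat)
  label <- if (n_cat == 0L) {
    "pure"
  } else if (n_cat == 1L) {
    "single_CAT"
  } else if (n_cat == 2L) {
    idx <- which(is_cat)
    between <- seq.int(idx[1L] + 1L, idx[2L] - 1L)
    if (length(between) == 1L && pattern$codon[between] == "CAG" &&
        pattern$count[between] == 1L && pattern$count[idx[1L]] == 1L &&
        pattern$count[idx[2L]] == 1L) "CAT_CAG_CAT" else "other"
  } else if (n_cat == 3L) {
    "triple_CAT"
  } else if (n_cat == 4L) {
    "quad_CAT"
  } else {
    "other"
  }
  structure(
    list(label = label,
         n_CAT_runs = n_cat,
         has_other_codon = any(!pattern$codon %in%
                                 c(GLUTAMINE_CODONS, INTERRUPTION_CODON))),
    class = "interruption_config"
  )
}

#' @export
print.interruption_config <- function(x, ...) {
  cat("<interruption_config> label: ", x$label,
      "; CAT runs: ", x$n_CAT_runs,
      if (x$has_other_codon) "; contains non-CAG/CAA/CAT codon(s)" else "",
      "\n", sep = "")
  invisible(x)
}

#' Is an allele pathogenic?
#'
#' Pathogenicity is judged on the longest uninterrupted CAG stretch, not
#' on total tract length: an interrupted allele is pathogenic only if
#' its longest pure CAG run reaches the full-penetrance threshold.
#'
#' @param pattern A [repeat_pattern()].
#' @param threshold Full-penetrance threshold in repeats (default 39).
#' @return Logical.
#' @examples
#' is_pathogenic(parse_notation("(CAG)20(CAT)(CAG)(CAT)(CAG)19")) # FALSE
#' is_pathogenic(parse_notation("(CAG)46(CAT)(CAG)(CAT)(CAG)10")) # TRUE
#' @export
is_pathogenic <- function(pattern, threshold = 39L) {
  longest_pure_run(pattern) >= threshold
}

# --- internal helpers ------------------------------------------------------

check_dna <- function(dna) {
  if (length(dna) != 1L || !is.character(dna)) {
    stop("input error: DNA must be a single character string")
  }
  if (nzchar(dna) && grepl("[^ACGT]", dna)) {
    stop("input error: DNA contains non-ACGT characters")
  }
  invisible(dna)
}

# All 1-based start positions of fixed substring 'needle' in 'haystack',
# including overlapping occurrences.
fixed_matches <- function(haystack, needle) {
  if (!nzchar(needle) || !nzchar(haystack)) return(integer(0))
  out <- integer(0)
  from <- 1L
  repeat {
    hit <- regexpr(needle, substr(haystack, from, nchar(haystack)), fixed = TRUE)
    if (hit == -1L) break
    pos <- from + as.integer(hit) - 1L
    out <- c(out, pos)
    from <- pos + 1L
  }
  out
}
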