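# SfaNI is a type IIS enzyme: recognition GCATC, cleaving 5 nt downstream
# on the top strand and 9 nt downstream on the bottom (GCATC(5/9)). These
# offsets are standard enzyme properties (REBASE), kept here as constants.
SFANI_MOTIF <- "GCATC"
SFANI_TOP_CUT_OFFSET <- 5L

#' ATXN1 repeat-flanking sequences
#'
#' The default flanks used when rendering or extracting repeat-region
#' amplicons: the forward cloning primer sequence 5' of the tract and the
#' reverse complement of the reverse cloning primer 3' of it.
#'
#' @return A list with elements `five` and `three` (uppercase DNA).
#' @export
atxn1_flanks <- function() {
  list(
    five  = "GGGTTGGGATCCTTCCAGTTCATTGGGTCCTC",
    three = "CAGACGATGATCCCACACACCTCGAGCAAACC"
  )
}

#' Find restriction-site motif occurrences on both strands
#'
#' Reports every 0-based start offset (in top-strand coordinates) of the
#' recognition motif on the top strand and of its reverse complement on
#' the bottom strand.
#'
#' @param dna Uppercase ACGT string.
#' @param motif Recognition sequence (default SfaNI, `GCATC`).
#' @return A data frame with columns `strand` (`"+"`/`"-"`) and `start`
#'   (0-based offset of the motif window); zero rows when no site exists.
#' @examples
#' find_recognition_sites("CAGCATCAG") # top-strand site at offset 2
#' @export
find_recognition_sites <- function(dna, motif = SFANI_MOTIF) {
  check_dna(dna)
  check_dna(motif)
  rc <- revcomp(motif)
  top <- fixed_matches(dna, motif) - 1L
  bot <- fixed_matches(dna, rc) - 1L
  out <- data.frame(
    strand = c(rep("+", length(top)), rep("-", length(bot))),
    start = c(top, bot),
    stringsAsFactors = FALSE
  )
  out[order(out$start, out$strand), , drop = FALSE]
}

#' Would SfaNI digest the amplicon of a repeat pattern?
#'
#' Renders the amplicon `flank5 + tract + flank3` and reports whether it
#' carries at least one SfaNI recognition site on either strand. A CAT
#' interruption preceded by CAG creates the site (`...CAG CATC AG...`),
#' so interrupted alleles digest while pure CAG tracts are resistant —
#' the diagnostic screen distinguishing large-normal (interrupted) from
#' pathogenic (uninterrupted) alleles.
#'
#' @param pattern A [repeat_pattern()].
#' @param flank5,flank3 Amplicon flank sequences (defaults:
#'   [atxn1_flanks()]).
#' @return Logical.
#' @examples
#' is_digestible(parse_notation("(CAG)19(CAT)(CAG)(CAT)(CAG)17")) # TRUE
#' is_digestible(parse_notation("(CAG)48"))                       # FALSE
#' @export
is_digestible <- function(pattern,
                          flank5 = atxn1_flanks()$five,
                          flank3 = atxn1_flanks()$three) {
  stopifnot_pattern(pattern)
  amplicon <- paste0(flank5, pattern_to_dna(pattern), flank3)
  nrow(find_recognition_sites(amplicon)) > 0L
}

#' In-silico SfaNI digestion with fragment sizes
#'
#' Extends the boolean screen to fragment lengths: the top strand is cut
#' 5 nt 3' of each recognition-motif end, fragments are measured between
#' successive cuts (only top-strand cut positions define boundaries, so
#' fragments carry single lengths as in gel or capillary readouts).
#'
#' @param dna Uppercase ACGT amplicon string.
#' @param motif Recognition sequence (default SfaNI `GCATC`).
#' @param cut_offset Top-strand cut distance 3' of the motif (default 5).
#' @return A list of class `digest_result` with elements `digestible`,
#'   `site_positions` (data frame as in [find_recognition_sites()]) and
#'   `fragment_lengths` (positive integers summing to `nchar(dna)`).
#' @export
digest_fragments <- function(dna, motif = SFANI_MOTIF,
                             cut_offset = SFANI_TOP_CUT_OFFSET) {
  check_dna(dna)
  sites <- find_recognition_sites(dna, motif)
  top <- sites$start[sites$strand == "+"]
  cuts <- top + nchar(motif) + cut_offset  # 0-based position cut occurs before
  n <- nchar(dna)
  beyond <- cuts > n
  if (any(beyond)) {
    warning(sum(beyond), " cut position(s) beyond sequence end; site(s) skipped")
    cuts <- cuts[!beyond]
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  structure(
    list(digestible = nrow(sites) > 0L,
         site_positions = sites,
         fragment_lengths = as.integer(diff(bounds))),
    class = "digest_result"
  )
}

#' @export
print.digest_result <- function(x, ...) {
  cat("<digest_result> digestible: ", x$digestible,
      "; sites: ", nrow(x$site_positions),
      "; fragments (nt): ", paste(x$fragment_lengths, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Digest every record of a clone FASTA
#'
#' Convenience wrapper running [digest_fragments()] over a FASTA file of
#' repeat-region amplicons and returning a per-record table suitable for
#' TSV export.
#'
#' @param fasta_path Path to a FASTA file of amplicon sequences.
#' @return Data frame with columns `id`, `digestible`, `n_sites`,
#'   `fragment_lengths` (comma-separated nt lengths).
#' @export
digest_fasta <- function(fasta_path) {
  seqs <- read_clone_fasta(fasta_path)
  rows <- lapply(seq_along(seqs$id), function(i) {
    d <- digest_fragments(seqs$sequence[i])
    data.frame(id = seqs$id[i],
               digestible = d$digestible,
               n_sites = nrow(d$site_positions),
               fragment_lengths = paste(d$fragment_lengths, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

revcomp <- function(dna) {
  if (!nzchar(dna)) return(dna)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}
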