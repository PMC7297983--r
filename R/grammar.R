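#' Cassette grammar for shRNA hairpin oligos
#'
#' An shRNA cloning oligo is a fixed-structure string:
#' `leader + sense + loop + antisense + terminator + trailer`, where the
#' antisense stem is the reverse complement of the sense stem. The grammar
#' holds the constant elements and the accepted stem-length range. The
#' defaults are the elements shared by the classic pSIREN-style hairpin
#' cassettes with a BamHI-compatible leader, the canonical `TTCAAGAGA`
#' loop, a poly-T pol III terminator, and a short cloning trailer; they can
#' be overridden for other vector systems.
#'
#' @param leader Constant 5' leader (restriction overhang remnant).
#' @param loop Hairpin loop motif separating the two stems.
#' @param terminator Poly-T transcription terminator.
#' @param trailer Constant 3' trailer after the terminator.
#' @param stem_min,stem_max Accepted stem lengths (nt), `stem_min <= stem_max`.
#' @return An object of class `cassette_grammar`.
#' @export
#' @examples
#' g <- cassette_grammar()
#' g$loop
cassette_grammar <- function(leader = "GATCC", loop = "TTCAAGAGA",
                             terminator = "TTTTTT", trailer = "GATATCG",
                             stem_min = 19L, stem_max = 22L) {
  for (el in list(leader = leader, loop = loop, terminator = terminator,
                  trailer = trailer)) {
    if (length(el) != 1L || !is_dna_chr(el) || nchar(el) == 0L) {
      gcs_stop("gcs_config_error",
               "grammar elements must be nonempty A/C/G/T strings")
    }
  }
  stem_min <- as.integer(stem_min); stem_max <- as.integer(stem_max)
  if (is.na(stem_min) || is.na(stem_max) || stem_min < 1L ||
      stem_min > stem_max) {
    gcs_stop("gcs_config_error",
             "stem length range must satisfy 1 <= stem_min <= stem_max")
  }
  structure(
    list(leader = leader, loop = loop, terminator = terminator,
         trailer = trailer, stem_min = stem_min, stem_max = stem_max),
    class = "cassette_grammar"
  )
}

#' Reverse complement of DNA sequences
#'
#' @param seq Character vector of A/C/G/T strings (empty strings allowed).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("GCTGTCAAAGAGAAGGCTTTA")
reverse_complement <- function(seq) {
  if (!is.character(seq)) {
    gcs_stop("gcs_invalid_alphabet", "sequence must be a character vector")
  }
  bad <- !is_dna_chr(seq)
  if (any(bad)) {
    gcs_stop("gcs_invalid_alphabet",
             "sequence contains non-A/C/G/T characters (first offender: %s)",
             seq[bad][1L])
  }
  rc_chr(seq)
}

# Internal: stem design rules shared by assemble_hairpin() and the library
# generator. A stem must avoid the loop motif (parsing anchor), its reverse
# complement (else the antisense stem contains the loop), a >= 6 T run
# (terminator collision) and a >= 6 A run (its complement would be a T run).
stem_violation <- function(sense, grammar) {
  n <- nchar(sense)
  if (!all(is_dna_chr(sense))) return(rep("non-ACGT alphabet", length(sense)))
  v <- character(length(sense))
  v[n < grammar$stem_min | n > grammar$stem_max] <-
    sprintf("stem length outside %d-%d nt", grammar$stem_min, grammar$stem_max)
  hit <- function(pat) stringi::stri_detect_fixed(sense, pat)
  v[v == "" & hit(grammar$loop)] <- "stem contains the loop motif"
  v[v == "" & hit(rc_chr(grammar$loop))] <-
    "stem contains the reverse complement of the loop motif"
  v[v == "" & stringi::stri_detect_regex(sense, "T{6,}")] <-
    "stem contains a run of >= 6 T"
  v[v == "" & stringi::stri_detect_regex(sense, "A{6,}")] <-
    "stem contains a run of >= 6 A"
  v
}

#' Parse a hairpin cloning oligo into its stems
#'
#' Locates the leader prefix, the terminator+trailer suffix, and the unique
#' loop occurrence whose flanking stems are equal-length, inside the
#' grammar's stem range, and reverse complements of one another. Scanning
#' all loop occurrences and keeping only the structurally valid one guards
#' against a stem that happens to contain the loop motif.
#'
#' @param oligo A single A/C/G/T string.
#' @param grammar A [cassette_grammar()].
#' @return A list with elements `sense`, `loop`, `antisense`, `oligo`.
#' @export
#' @examples
#' oligo <- assemble_hairpin("GCTGTCAAAGAGAAGGCTTTA")
#' parse_hairpin(oligo)$sense
parse_hairpin <- function(oligo, grammar = cassette_grammar()) {
  if (length(oligo) != 1L || !is_dna_chr(oligo)) {
    gcs_stop("gcs_invalid_alphabet", "oligo must be a single A/C/G/T string")
  }
  suffix <- paste0(grammar$terminator, grammar$trailer)
  if (!startsWith(oligo, grammar$leader)) {
    gcs_stop("gcs_grammar_mismatch", "leader '%s' not found at oligo start",
             grammar$leader)
  }
  if (!endsWith(oligo, suffix)) {
    gcs_stop("gcs_grammar_mismatch",
             "terminator+trailer '%s' not found at oligo end", suffix)
  }
  core <- substr(oligo, nchar(grammar$leader) + 1L, nchar(oligo) - nchar(suffix))
  locs <- stringi::stri_locate_all_fixed(core, grammar$loop)[[1L]]
  if (anyNA(locs)) {
    gcs_stop("gcs_grammar_mismatch", "loop motif '%s' not found", grammar$loop)
  }
  valid <- list()
  for (i in seq_len(nrow(locs))) {
    sense <- substr(core, 1L, locs[i, 1L] - 1L)
    antisense <- substr(core, locs[i, 2L] + 1L, nchar(core))
    if (nchar(sense) != nchar(antisense)) next
    if (nchar(sense) < grammar$stem_min || nchar(sense) > grammar$stem_max) next
    if (antisense != rc_chr(sense)) next
    valid[[length(valid) + 1L]] <- list(sense = sense, antisense = antisense)
  }
  if (length(valid) == 0L) {
    gcs_stop("gcs_hairpin_invalid",
             paste0("no loop occurrence yields equal-length, in-range stems ",
                    "with antisense = reverse complement of sense"))
  }
  if (length(valid) > 1L) {
    gcs_stop("gcs_hairpin_ambiguous",
             "%d loop occurrences yield structurally valid hairpins",
             length(valid))
  }
  list(sense = valid[[1L]]$sense, loop = grammar$loop,
       antisense = valid[[1L]]$antisense, oligo = oligo)
}

#' Assemble a full cloning oligo from a sense stem
#'
#' The exact inverse of [parse_hairpin()]: for any sense stem passing the
#' design rules, `parse_hairpin(assemble_hairpin(s))$sense` recovers `s`.
#'
#' @param sense Character vector of sense stems.
#' @param grammar A [cassette_grammar()].
#' @return Character vector of full oligos.
#' @export
assemble_hairpin <- function(sense, grammar = cassette_grammar()) {
  if (!is.character(sense) || length(sense) == 0L) {
    gcs_stop("gcs_design_constraint", "sense must be a character vector")
  }
  v <- stem_violation(sense, grammar)
  if (any(v != "")) {
    i <- which(v != "")[1L]
    gcs_stop("gcs_design_constraint", "invalid sense stem '%s': %s",
             sense[i], v[i])
  }
  paste0(grammar$leader, sense, grammar$loop, rc_chr(sense),
         grammar$terminator, grammar$trailer)
}

# Internal: the read-matching key for a construct (see count_reads()).
cassette_key <- function(sense, grammar, match_mode = "cassette") {
  switch(match_mode,
    cassette = paste0(sense, grammar$loop, rc_chr(sense)),
    sense = sense,
    gcs_stop("gcs_config_error", "unknown match_mode '%s'", match_mode)
  )
}

#' @export
print.cassette_grammar <- function(x, ...) {
  cat("shRNA cassette grammar\n")
  cat(sprintf("  leader     %s\n  loop       %s\n  terminator %s\n  trailer    %s\n",
              x$leader, x$loop, x$terminator, x$trailer))
  cat(sprintf("  stem range %d-%d nt\n", x$stem_min, x$stem_max))
  invisible(x)
}
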