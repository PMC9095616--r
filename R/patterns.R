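# Epitope patterns: fixed residues with single-position wildcards, the unit
# of "epitope" throughout the package. A pattern is a string over the 20
# canonical residue letters plus '.', with fixed first and last symbols and
# span at most 12 (the peptide length).

#' Validate an epitope pattern
#'
#' A valid pattern is a non-empty string over the canonical residue letters
#' and the single-position wildcard `.`; its first and last symbols are
#' residue letters and its span (string length) is at most 12.
#'
#' @param pattern Pattern string, e.g. `"A..C"`.
#' @return The pattern, invisibly, or an error.
#' @export
epitope_pattern <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || !nzchar(pattern))
    stop_("pattern must be a single non-empty string")
  if (grepl(paste0("[^.", paste(AA_ALPHABET, collapse = ""), "]"), pattern))
    stop_("pattern '%s' contains symbols outside residues + '.'", pattern)
  if (nchar(pattern) > 12L)
    stop_("pattern '%s' has span > 12", pattern)
  ends <- substring(pattern, c(1L, nchar(pattern)), c(1L, nchar(pattern)))
  if (any(ends == "."))
    stop_("pattern '%s' must start and end with a fixed residue", pattern)
  if (pattern_fixed_count(pattern) < 1L)
    stop_("pattern '%s' has no fixed residues", pattern)
  invisible(pattern)
}

#' @rdname epitope_pattern
#' @export
pattern_fixed_count <- function(pattern) nchar(gsub(".", "", pattern, fixed = TRUE))

#' @rdname epitope_pattern
#' @export
pattern_span <- function(pattern) nchar(pattern)

#' Match a pattern against peptides
#'
#' A pattern matches a peptide when it occurs at some offset with every
#' fixed residue identical; wildcard positions are unconstrained. Patterns
#' are plain substring motifs, so matching reduces to a regular-expression
#' scan (`.` is the regex wildcard).
#'
#' @param pattern A valid epitope pattern.
#' @param peptides Character vector of peptides.
#' @return Logical vector, one element per peptide.
#' @export
pattern_matches <- function(pattern, peptides) {
  epitope_pattern(pattern)
  grepl(pattern, peptides)
}

#' @rdname pattern_matches
#' @param peptide A single 12-mer peptide.
#' @export
pattern_match <- function(pattern, peptide) {
  if (nchar(pattern) > nchar(peptide)) {
    epitope_pattern(pattern)
    stop_("pattern span exceeds peptide length")
  }
  pattern_matches(pattern, peptide)
}

#' Abundance of a pattern in a repertoire
#'
#' The abundance of an epitope pattern in a sample is the total normalized
#' read count of the distinct peptides containing it (`count_mode =
#' "reads"`), or the number of distinct matching peptides (`count_mode =
#' "unique_peptides"`). A peptide contributes once regardless of how many
#' offsets match.
#'
#' @param pattern A valid epitope pattern.
#' @param rep A normalized [peptide_repertoire()].
#' @param count_mode `"reads"` (default) or `"unique_peptides"`.
#' @return A single non-negative number.
#' @export
pattern_abundance <- function(pattern, rep,
                              count_mode = c("reads", "unique_peptides")) {
  count_mode <- match.arg(count_mode)
  stopifnot(inherits(rep, "peptide_repertoire"))
  m <- pattern_matches(pattern, names(rep$counts))
  if (count_mode == "reads") sum(rep$counts[m]) else sum(m)
}

# Does `general` subsume `specific`, i.e. does every sequence matching the
# more specific pattern necessarily match the general one? True when
# `general` occurs inside `specific`'s symbol string with every fixed
# residue of `general` landing on the identical fixed residue of
# `specific`.
pattern_subsumes <- function(general, specific) {
  sg <- strsplit(general, "")[[1L]]
  ss <- strsplit(specific, "")[[1L]]
  if (length(sg) > length(ss)) return(FALSE)
  fixed <- which(sg != ".")
  for (o in 0:(length(ss) - length(sg))) {
    if (all(ss[o + fixed] == sg[fixed])) return(TRUE)
  }
  FALSE
}
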