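# Antigen mapping: align discovered patterns to linear database epitopes and
# full antigen protein sequences under fixed-residue-identity semantics;
# recruit antigens supported by both epitope sets; antigen-level abundance
# scores.

#' Read antigen sequences from FASTA
#'
#' The header's first token is taken as the accession, the remainder as the
#' antigen name. Sequences are uppercased; a single trailing `*` is
#' stripped; any remaining non-canonical residue, a duplicate accession or
#' an empty sequence is an error.
#'
#' @param path FASTA file.
#' @return Data frame with columns `accession`, `name`, `sequence`.
#' @export
read_antigen_fasta <- function(path) {
  if (!file.exists(path)) stop_("FASTA not found: %s", path)
  set <- Biostrings::readAAStringSet(path)
  if (!length(set)) stop_("no sequences in %s", path)
  headers <- names(set)
  acc <- sub("\\s.*$", "", headers)
  name <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(acc))
    stop_("duplicate accession in %s: %s", path, acc[duplicated(acc)][1L])
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  if (any(!nzchar(seqs))) stop_("empty sequence for %s", acc[!nzchar(seqs)][1L])
  bad <- grepl(non_canonical_regex(), seqs)
  if (any(bad))
    stop_("non-canonical residues in sequence %s", acc[bad][1L])
  data.frame(accession = unname(acc), name = unname(name),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' @rdname read_antigen_fasta
#' @param antigens Data frame as returned by [read_antigen_fasta()].
#' @export
write_antigen_fasta <- function(antigens, path) {
  set <- Biostrings::AAStringSet(antigens$sequence)
  names(set) <- trimws(paste(antigens$accession, antigens$name))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a linear epitope table
#'
#' @param path CSV with columns `epitope_sequence`, `parent_accession` and
#'   optionally `parent_name`.
#' @return Data frame of linear epitopes.
#' @export
read_linear_epitopes <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("epitope_sequence", "parent_accession")
  if (!all(need %in% names(df)))
    stop_("linear epitope table must have columns %s",
          paste(need, collapse = ", "))
  if (any(nchar(df$epitope_sequence) < 1))
    stop_("empty epitope sequence in %s", path)
  df
}

#' Align a pattern to a protein sequence
#'
#' Reports every offset at which all fixed residues of the pattern are
#' identical to the sequence (wildcards unconstrained); overlapping hits are
#' allowed. Coordinates are 1-based inclusive.
#'
#' @param pattern A valid [epitope_pattern()].
#' @param sequence Protein sequence string.
#' @param accession Accession to record on the hits.
#' @return Data frame of hits (`pattern`, `accession`, `start`, `end`),
#'   sorted by start; zero rows when there is no match.
#' @export
align_pattern_to_sequence <- function(pattern, sequence, accession = NA_character_) {
  epitope_pattern(pattern)
  span <- pattern_span(pattern)
  empty <- data.frame(pattern = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE)
  if (span > nchar(sequence)) return(empty)
  # overlapping matches via zero-width lookahead; '.' is the regex wildcard
  starts <- gregexpr(paste0("(?=", pattern, ")"), sequence, perl = TRUE)[[1L]]
  if (starts[1L] == -1L) return(empty)
  data.frame(pattern = pattern, accession = accession,
             start = as.integer(starts), end = as.integer(starts) + span - 1L,
             stringsAsFactors = FALSE)
}

#' Align many patterns to many antigens
#'
#' @param patterns Character vector of patterns.
#' @param antigens Data frame with `accession` and `sequence` columns.
#' @return Data frame of all hits, one row per (pattern, antigen, offset).
#' @export
align_patterns_to_antigens <- function(patterns, antigens) {
  hits <- list()
  for (p in unique(patterns)) {
    for (i in seq_len(nrow(antigens))) {
      h <- align_pattern_to_sequence(p, antigens$sequence[i],
                                     antigens$accession[i])
      if (nrow(h)) hits[[length(hits) + 1L]] <- h
    }
  }
  if (!length(hits))
    return(data.frame(pattern = character(0), accession = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  rownames(out) <- NULL
  out
}

#' Match patterns against linear database epitopes
#'
#' A pattern matches a database epitope when it occurs within the epitope
#' sequence under fixed-residue semantics (the pattern lies inside the
#' epitope; the reverse containment is not considered).
#'
#' @param patterns Character vector of patterns.
#' @param epitopes Data frame of linear epitopes (see
#'   [read_linear_epitopes()]).
#' @return Data frame with columns `pattern`, `epitope_sequence`,
#'   `parent_accession`, one row per matching pair.
#' @export
match_patterns_to_linear_epitopes <- function(patterns, epitopes) {
  rows <- list()
  for (p in unique(patterns)) {
    m <- vapply(epitopes$epitope_sequence, function(s)
      nrow(align_pattern_to_sequence(p, s)) > 0, logical(1),
      USE.NAMES = FALSE)
    if (any(m))
      rows[[length(rows) + 1L]] <- data.frame(
        pattern = p, epitope_sequence = epitopes$epitope_sequence[m],
        parent_accession = epitopes$parent_accession[m],
        stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pattern = character(0), epitope_sequence = character(0),
                      parent_accession = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Recruit antigens supported by two epitope sets
#'
#' An antigen is recruited when it carries sequence identity to at least one
#' epitope from each of two pattern sets — the accession sets matched by the
#' two sets are intersected.
#'
#' @param hits_a,hits_b Character vectors of parent accessions matched by
#'   pattern set A and B.
#' @return Sorted character vector of recruited accessions.
#' @export
recruit_antigens <- function(hits_a, hits_b) {
  sort_c(intersect(unique(hits_a), unique(hits_b)))
}

#' Antigen-level antibody-response score
#'
#' The mean, over the distinct patterns aligning to the antigen, of each
#' pattern's abundance in the sample; reported raw and as
#' `log10(mean + 1)` (the +1 keeps zero-abundance antigens defined; noted in
#' output metadata). A pattern hitting multiple offsets counts once.
#'
#' @param accession Antigen accession.
#' @param hits Alignment hit data frame (from
#'   [align_patterns_to_antigens()]).
#' @param rep A normalized [peptide_repertoire()].
#' @param count_mode Passed to [pattern_abundance()].
#' @return List with elements `raw` and `log10`.
#' @export
antigen_abundance <- function(accession, hits, rep, count_mode = "reads") {
  pats <- unique(hits$pattern[hits$accession == accession])
  if (!length(pats)) return(list(raw = 0, log10 = 0))
  raw <- mean(vapply(pats, pattern_abundance, numeric(1), rep = rep,
                     count_mode = count_mode))
  list(raw = raw, log10 = log10(raw + 1))
}

#' Antigen score matrix over a cohort
#'
#' @param hits Alignment hit data frame.
#' @param co A [cohort()] of normalized repertoires.
#' @param count_mode Passed to [pattern_abundance()].
#' @return Numeric matrix (antigens x samples) of `log10(mean abundance + 1)`
#'   scores, with attribute `transform = "log10(x+1)"`.
#' @export
antigen_score_matrix <- function(hits, co, count_mode = "reads") {
  accs <- sort_c(unique(hits$accession))
  ids <- co$meta$sample_id
  m <- matrix(0, nrow = length(accs), ncol = length(ids),
              dimnames = list(accs, ids))
  for (id in ids)
    for (a in accs)
      m[a, id] <- antigen_abundance(a, hits, co$repertoires[[id]],
                                    count_mode)$log10
  attr(m, "transform") <- "log10(x+1)"
  m
}
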