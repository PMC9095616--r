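# Peptide repertoires: the per-sample map from 12-mer peptide to read count,
# with cleaning and read-count normalization.

#' Construct a peptide repertoire
#'
#' A peptide repertoire is one sample's map from 12-mer amino-acid peptides
#' to read counts (raw integers before normalization, reals after). Duplicate
#' peptides are merged by summing their counts; peptides are stored in
#' byte-lexicographic order for deterministic downstream output.
#'
#' @param peptides Character vector of peptide sequences.
#' @param counts Numeric vector of non-negative counts, parallel to
#'   `peptides`.
#' @param sample_id Sample identifier.
#' @param normalized Logical; `TRUE` once counts have been scaled to the
#'   normalization target (see [normalize_reads()]).
#' @return An object of class `peptide_repertoire`: a list with elements
#'   `sample_id`, `counts` (named numeric vector), `total` and `normalized`.
#' @seealso [read_repertoire()], [clean_repertoire()], [normalize_reads()]
#' @export
peptide_repertoire <- function(peptides, counts, sample_id = "sample",
                               normalized = FALSE) {
  if (length(peptides) != length(counts))
    stop_("peptides and counts must have equal length")
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0))
    stop_("counts must be non-negative numbers")
  if (anyDuplicated(peptides)) {
    m <- rowsum(counts, peptides)
    peptides <- rownames(m)
    counts <- as.numeric(m[, 1L])
  }
  ord <- order_c(peptides)
  structure(
    list(sample_id = as.character(sample_id),
         counts = stats::setNames(counts[ord], peptides[ord]),
         total = sum(counts),
         normalized = isTRUE(normalized)),
    class = "peptide_repertoire")
}

#' @export
print.peptide_repertoire <- function(x, ...) {
  cat(sprintf("peptide_repertoire '%s': %d unique peptides, total %.6g (%s)\n",
              x$sample_id, length(x$counts), x$total,
              if (x$normalized) "normalized" else "raw"))
  invisible(x)
}

# Check the structural invariants of a repertoire (used by tests and the
# cohort loader). Errors on violation, invisibly TRUE otherwise.
validate_repertoire <- function(rep, target = NULL) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  pep <- names(rep$counts)
  if (length(pep) && (any(nchar(pep) != 12L) ||
                      any(grepl(non_canonical_regex(), pep))))
    stop_("repertoire '%s' contains uncleaned peptides", rep$sample_id)
  if (abs(rep$total - sum(rep$counts)) > 1e-9 * max(1, rep$total))
    stop_("repertoire '%s': total does not equal sum of counts", rep$sample_id)
  if (rep$normalized && !is.null(target) &&
      abs(rep$total - target) > 1e-9 * target)
    stop_("repertoire '%s': normalized total differs from target",
          rep$sample_id)
  invisible(TRUE)
}

non_canonical_regex <- function() {
  paste0("[^", paste(AA_ALPHABET, collapse = ""), "]")
}

#' Read a peptide count table
#'
#' Reads a two-column tab-separated table of peptides and integer read
#' counts. A header line whose first field is `peptide` is skipped.
#' Duplicate peptide rows are summed. The returned repertoire is
#' un-normalized and uncleaned.
#'
#' @param path Path to the TSV file.
#' @param sample_id Sample identifier to attach; defaults to the file name
#'   without extension.
#' @return A [peptide_repertoire()].
#' @export
read_repertoire <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop_("peptide table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop_("empty peptide table: %s", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (identical(fields[[1L]][1L], "peptide")) start <- 2L
  if (start > length(fields)) stop_("empty peptide table: %s", path)
  nf <- lengths(fields[start:length(fields)])
  if (any(nf != 2L)) {
    bad <- which(nf != 2L)[1L] + start - 1L
    stop_("%s: line %d has %d columns, expected 2", path, bad, nf[bad - start + 1L])
  }
  m <- matrix(unlist(fields[start:length(fields)]), ncol = 2L, byrow = TRUE)
  ok <- grepl("^[0-9]+$", m[, 2L])
  if (!all(ok)) {
    bad <- which(!ok)[1L] + start - 1L
    stop_("%s: line %d has non-integer count '%s'", path, bad,
          m[which(!ok)[1L], 2L])
  }
  peptide_repertoire(m[, 1L], as.numeric(m[, 2L]),
                     sample_id = sample_id %||%
                       sub("\\.[^.]*$", "", basename(path)))
}

#' Write a peptide count table
#'
#' Writes the two-column TSV consumed by [read_repertoire()]. Counts are
#' written as plain decimal numbers (integers for raw repertoires).
#'
#' @param rep A [peptide_repertoire()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_repertoire <- function(rep, path) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  cnt <- format(rep$counts, scientific = FALSE, trim = TRUE)
  writeLines(c("peptide\tcount",
               paste(names(rep$counts), cnt, sep = "\t")), path)
  invisible(path)
}

#' Clean a peptide repertoire
#'
#' Removes peptides that cannot come from the 12-mer library: sequences of
#' length other than 12, sequences containing any non-canonical letter
#' (including stop `*` and ambiguous `X`), and any peptide on a user-supplied
#' artefact list. The removal report is attached as attribute
#' `removal_report` (counts of unique peptides removed per rule).
#'
#' @param rep An un-normalized [peptide_repertoire()].
#' @param artefacts Character vector of known artefact peptides to drop
#'   (default none).
#' @return The cleaned repertoire, with `removal_report` attribute.
#' @export
clean_repertoire <- function(rep, artefacts = character()) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  if (rep$normalized) stop_("clean_repertoire expects an un-normalized repertoire")
  pep <- names(rep$counts)
  bad_len <- nchar(pep) != 12L
  bad_res <- !bad_len & grepl(non_canonical_regex(), pep)
  art <- !bad_len & !bad_res & pep %in% artefacts
  keep <- !(bad_len | bad_res | art)
  out <- peptide_repertoire(pep[keep], rep$counts[keep],
                            sample_id = rep$sample_id, normalized = FALSE)
  attr(out, "removal_report") <- list(
    wrong_length = sum(bad_len),
    non_canonical = sum(bad_res),
    artefact = sum(art),
    kept = sum(keep),
    empty = !any(keep))
  out
}

#' Normalize read counts to a fixed sequencing depth
#'
#' Scales every count by `target / total` so that the repertoire sums to the
#' normalization target (3 million reads by default), making samples of
#' different sequencing depth comparable. Counts become real-valued; no
#' rounding is applied, so relative composition is conserved exactly.
#'
#' @param rep A [peptide_repertoire()] with positive total.
#' @param target Normalization target (default 3e6 reads).
#' @return The normalized repertoire (`normalized = TRUE`).
#' @export
normalize_reads <- function(rep, target = 3e6) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  if (!is.numeric(target) || target <= 0) stop_("target must be positive")
  if (rep$total <= 0) stop_("empty repertoire")
  out <- rep
  out$counts <- rep$counts * (target / rep$total)
  out$total <- target
  out$normalized <- TRUE
  out
}
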