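# Cohorts: repertoires plus sample metadata (group, pairing, competition).

COHORT_GROUPS <- c("MelVac", "MelVac-CTRL", "NSCLC", "CTRL-NSCLC",
                   "PEM-Mel", "CTRL-Mel", "OTHER")

#' Construct a cohort
#'
#' Bundles a list of repertoires with a sample sheet and validates the
#' pairing structure: sample ids are unique and in one-to-one correspondence
#' between repertoires and metadata, `paired_with` and `competition_of`
#' references exist and point to a sample of the same subject.
#'
#' @param repertoires List of [peptide_repertoire()] objects.
#' @param meta Data frame with columns `sample_id`, `subject_id`, `group`,
#'   `timepoint`, `paired_with`, `competition_of` (empty string or `NA`
#'   means no reference).
#' @return An object of class `cohort`.
#' @export
cohort <- function(repertoires, meta) {
  ids <- vapply(repertoires, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids))
    stop_("duplicate sample_id: %s", ids[duplicated(ids)][1L])
  if (anyDuplicated(meta$sample_id))
    stop_("duplicate sample_id in sample sheet: %s",
          meta$sample_id[duplicated(meta$sample_id)][1L])
  if (!setequal(ids, meta$sample_id))
    stop_("sample sheet and repertoires do not list the same sample_ids")
  bad_grp <- setdiff(unique(meta$group), COHORT_GROUPS)
  if (length(bad_grp)) stop_("unknown group label: %s", bad_grp[1L])
  meta$paired_with[is.na(meta$paired_with)] <- ""
  meta$competition_of[is.na(meta$competition_of)] <- ""
  check_ref <- function(col) {
    ref <- meta[[col]]
    for (i in which(nzchar(ref))) {
      j <- match(ref[i], meta$sample_id)
      if (is.na(j))
        stop_("%s of %s names unknown sample '%s'", col, meta$sample_id[i],
              ref[i])
      if (meta$subject_id[j] != meta$subject_id[i])
        stop_("%s of %s crosses subjects (%s vs %s)", col, meta$sample_id[i],
              meta$subject_id[i], meta$subject_id[j])
    }
  }
  check_ref("paired_with")
  check_ref("competition_of")
  names(repertoires) <- ids
  structure(list(repertoires = repertoires[meta$sample_id],
                 meta = meta),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d samples, %d subjects\n", nrow(x$meta),
              length(unique(x$meta$subject_id))))
  print(table(x$meta$group))
  invisible(x)
}

#' Read a sample sheet
#'
#' @param path CSV with columns `sample_id`, `subject_id`, `group`,
#'   `timepoint`, `paired_with`, `competition_of`, `file`.
#' @return Data frame of sample metadata.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop_("sample sheet not found: %s", path)
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("sample_id", "subject_id", "group", "timepoint",
            "paired_with", "competition_of", "file")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop_("sample sheet is missing column(s): %s",
          paste(missing, collapse = ", "))
  df[need]
}

#' Load a cohort from a sample sheet and peptide tables
#'
#' Reads every per-sample peptide TSV referenced by the sample sheet, cleans
#' it with the configured artefact list, normalizes to `target` reads and
#' validates the cohort pairing invariants.
#'
#' @param sample_sheet Path to the sample-sheet CSV (see
#'   [read_sample_sheet()]).
#' @param data_dir Directory that the sheet's `file` column is relative to.
#' @param artefacts Artefact peptide list passed to [clean_repertoire()].
#' @param target Normalization target passed to [normalize_reads()].
#' @return A [cohort()] of cleaned, normalized repertoires.
#' @export
load_cohort <- function(sample_sheet, data_dir, artefacts = character(),
                        target = 3e6) {
  meta <- read_sample_sheet(sample_sheet)
  reps <- lapply(seq_len(nrow(meta)), function(i) {
    path <- file.path(data_dir, meta$file[i])
    if (!file.exists(path))
      stop_("peptide table for sample %s not found: %s", meta$sample_id[i],
            path)
    rep <- read_repertoire(path, sample_id = meta$sample_id[i])
    rep <- clean_repertoire(rep, artefacts = artefacts)
    normalize_reads(rep, target = target)
  })
  co <- cohort(reps, meta)
  for (r in co$repertoires) validate_repertoire(r, target = target)
  co
}

# Subset a cohort to the given sample ids, blanking pairing references that
# would dangle outside the subset.
subset_cohort <- function(co, sample_ids) {
  meta <- co$meta[co$meta$sample_id %in% sample_ids, , drop = FALSE]
  meta$paired_with[!meta$paired_with %in% meta$sample_id] <- ""
  meta$competition_of[!meta$competition_of %in% meta$sample_id] <- ""
  cohort(co$repertoires[meta$sample_id], meta)
}

# Convenience accessor.
cohort_repertoire <- function(co, sample_id) {
  r <- co$repertoires[[sample_id]]
  if (is.null(r)) stop_("no such sample in cohort: %s", sample_id)
  r
}
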