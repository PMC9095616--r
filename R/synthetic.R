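# Synthetic cohort generator: background 12-mer repertoires with a
# heavy-tailed count law, planted epitope motifs at configurable
# fold-enrichments, paired pre/post samples, optional competition samples,
# and antigen sequences embedding the planted motifs — with ground-truth
# tables for recovery tests.

check_freqs <- function(freqs) {
  if (is.null(freqs))
    freqs <- stats::setNames(rep(1 / 20, 20), AA_ALPHABET)
  if (is.null(names(freqs)) || !all(names(freqs) %in% AA_ALPHABET))
    stop_("background_freqs must be named with canonical residue letters")
  if (any(freqs < 0) || abs(sum(freqs) - 1) > 1e-9)
    stop_("background_freqs must be non-negative and sum to 1")
  full <- stats::setNames(numeric(20), AA_ALPHABET)
  full[names(freqs)] <- freqs
  full
}

#' Draw background peptides
#'
#' Peptides are drawn with independent identically distributed residues per
#' position from the background frequency distribution (the same mechanism
#' used for the random reference set in vs-random discovery). Uses the
#' current RNG state; call `set.seed()` (or pass seeds to the higher-level
#' generators) for reproducibility.
#'
#' @param n Number of peptides to draw (with replacement; duplicates
#'   possible).
#' @param freqs Named residue probability vector (default uniform).
#' @param length Peptide length (default 12).
#' @return Character vector of length `n`.
#' @export
sample_background_peptides <- function(n, freqs = NULL, length = 12L) {
  freqs <- check_freqs(freqs)
  m <- matrix(sample(AA_ALPHABET, n * length, replace = TRUE, prob = freqs),
              nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' @rdname sample_background_peptides
#' @export
sample_background_peptide <- function(freqs = NULL, length = 12L) {
  sample_background_peptides(1L, freqs, length)
}

# n *distinct* background peptides; errors if the support cannot supply them.
draw_distinct_peptides <- function(n, freqs) {
  if (sum(freqs > 0)^12 < n)
    stop_("cannot draw %d distinct peptides from this residue distribution", n)
  pep <- character(0)
  for (i in 1:1000) {
    add <- sample_background_peptides(ceiling((n - length(pep)) * 1.1) + 10,
                                      freqs)
    pep <- unique(c(pep, add))
    if (length(pep) >= n) return(pep[seq_len(n)])
  }
  stop_("failed to accumulate %d distinct peptides", n)
}

#' Define a planted epitope motif
#'
#' An effect-size knob for the generator: in samples of a targeted group the
#' motif's matching read fraction is `baseline_fraction` in the reference
#' condition (e.g. pre-treatment) and `baseline_fraction * fold` in the
#' query condition (e.g. post-treatment).
#'
#' @param pattern A valid [epitope_pattern()] with at least 4 fixed
#'   residues.
#' @param baseline_fraction Fraction of reads matching the motif in the
#'   reference condition, in `[0, 1]`.
#' @param fold Enrichment of the query condition over baseline;
#'   `baseline_fraction * fold` must not exceed 1.
#' @param target_groups Group labels whose samples carry the motif.
#' @return A list of class `planted_motif`.
#' @export
planted_motif <- function(pattern, baseline_fraction, fold, target_groups) {
  epitope_pattern(pattern)
  if (pattern_fixed_count(pattern) < 4L)
    stop_("planted motifs need >= 4 fixed residues")
  stopifnot(baseline_fraction >= 0, baseline_fraction <= 1, fold > 0,
            baseline_fraction * fold <= 1)
  structure(list(pattern = pattern, baseline_fraction = baseline_fraction,
                 fold = fold, target_groups = as.character(target_groups)),
            class = "planted_motif")
}

default_planted_motifs <- function() {
  list(planted_motif("YKDWH.R", 1e-3, 10, c("MelVac", "PEM-Mel")),
       planted_motif("FQELNK", 1e-3, 10, c("MelVac", "PEM-Mel")),
       planted_motif("HRWP.D", 5e-4, 8, c("MelVac", "PEM-Mel")))
}

#' Synthetic cohort configuration
#'
#' Defaults emulate a desk-scale version of a deep phage-display study:
#' 3e5 reads over 5e4 unique 12-mers per sample (roughly a tenth of real
#' sequencing depth), uniform background residue frequencies, a discrete
#' power-law count distribution, three planted motifs targeting the treated
#' groups, and a study design of paired pre/post vaccination samples
#' (`MelVac`), single-sample checkpoint-inhibitor patients (`PEM-Mel`) and
#' two control groups.
#'
#' @param seed Master integer seed.
#' @param n_subjects_per_group Named integer vector, group label ->
#'   number of subjects.
#' @param reads_per_sample Target raw reads per sample.
#' @param unique_peptides_per_sample Distinct peptides per sample.
#' @param background_freqs Named residue probability vector (default
#'   uniform).
#' @param planted_motifs List of [planted_motif()] objects.
#' @param count_dispersion Tail exponent of the count law; smaller values
#'   give heavier tails.
#' @param competition_depletion `NULL` (default, no competition samples) or
#'   the factor by which motif-matching reads are retained in competition
#'   samples of treated `MelVac` subjects (binomial thinning).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_subjects_per_group = c("MelVac" = 2L,
                                                      "PEM-Mel" = 2L,
                                                      "CTRL-Mel" = 4L,
                                                      "CTRL-NSCLC" = 2L),
                             reads_per_sample = 3e5,
                             unique_peptides_per_sample = 5e4,
                             background_freqs = NULL,
                             planted_motifs = default_planted_motifs(),
                             count_dispersion = 1.5,
                             competition_depletion = NULL) {
  stopifnot(reads_per_sample >= 1, unique_peptides_per_sample >= 1,
            unique_peptides_per_sample <= reads_per_sample,
            count_dispersion > 0)
  if (is.null(names(n_subjects_per_group)) ||
      !all(names(n_subjects_per_group) %in% COHORT_GROUPS))
    stop_("n_subjects_per_group must be named with known group labels")
  if (any(n_subjects_per_group < 0))
    stop_("subject counts must be non-negative")
  for (m in planted_motifs) stopifnot(inherits(m, "planted_motif"))
  if (!is.null(competition_depletion))
    stopifnot(competition_depletion >= 0, competition_depletion <= 1)
  structure(list(seed = as.integer(seed),
                 n_subjects_per_group = n_subjects_per_group,
                 reads_per_sample = reads_per_sample,
                 unique_peptides_per_sample = unique_peptides_per_sample,
                 background_freqs = check_freqs(background_freqs),
                 planted_motifs = planted_motifs,
                 count_dispersion = count_dispersion,
                 competition_depletion = competition_depletion),
            class = "synthetic_config")
}

# Greedily pick peptides from idx_pool (shuffled) until their counts sum to
# `need` reads, preferring small counts so the overshoot stays small.
select_for_mass <- function(counts, idx_pool, need) {
  if (need <= 0 || !length(idx_pool)) return(integer(0))
  cap <- max(2, 0.05 * need)
  small <- idx_pool[counts[idx_pool] <= cap]
  rest <- setdiff(idx_pool, small)
  pool <- c(small[sample.int(length(small))], rest[sample.int(length(rest))])
  cum <- cumsum(counts[pool])
  k <- which(cum >= need)[1L]
  if (is.na(k)) k <- length(pool)
  pool[seq_len(k)]
}

# Impose a motif's fixed residues on peptides at random admissible offsets.
impose_motif <- function(peptides, pattern) {
  sym <- strsplit(pattern, "")[[1L]]
  fixed <- which(sym != ".")
  span <- length(sym)
  offs <- sample.int(12L - span + 1L, length(peptides), replace = TRUE) - 1L
  for (o in unique(offs)) {
    idx <- which(offs == o)
    for (j in fixed)
      substr(peptides[idx], o + j, o + j) <- sym[j]
  }
  peptides
}

#' Generate one synthetic repertoire
#'
#' Draws distinct background peptides, assigns heavy-tailed counts (discrete
#' power law, exponent `count_dispersion`, scaled to `reads_per_sample`),
#' and rewrites a subset of background peptides so that each planted motif
#' targeting `group` reaches its configured matching read fraction
#' (`baseline_fraction` in the reference condition,
#' `baseline_fraction * fold` in the query condition). The result is cleaned
#' and returned with raw integer counts; normalize with [normalize_reads()].
#'
#' @param cfg A [synthetic_config()].
#' @param group Group label of the sample (decides which motifs apply).
#' @param condition `"reference"` or `"query"`.
#' @param seed Integer seed for this sample's draw.
#' @param sample_id Sample identifier.
#' @return A cleaned, un-normalized [peptide_repertoire()].
#' @export
generate_repertoire <- function(cfg, group, condition = c("reference", "query"),
                                seed = cfg$seed, sample_id = "synthetic") {
  condition <- match.arg(condition)
  stopifnot(inherits(cfg, "synthetic_config"))
  with_seed(seed, {
    n <- cfg$unique_peptides_per_sample
    pep <- draw_distinct_peptides(n, cfg$background_freqs)
    u <- stats::runif(n)
    x <- ceiling((1 - u)^(-1 / cfg$count_dispersion))
    counts <- pmax(1, round(x * cfg$reads_per_sample / sum(x)))
    for (m in cfg$planted_motifs) {
      if (!group %in% m$target_groups) next
      f <- m$baseline_fraction * if (condition == "query") m$fold else 1
      if (f > 0.9) stop_("infeasible motif fraction %.3f", f)
      total <- sum(counts)
      matching <- grepl(m$pattern, pep)
      need <- f * total - sum(counts[matching])
      if (need <= 0) next
      sel <- select_for_mass(counts, which(!matching), need)
      pep[sel] <- impose_motif(pep[sel], m$pattern)
    }
    clean_repertoire(peptide_repertoire(pep, counts, sample_id = sample_id))
  })
}

#' Generate synthetic antigen sequences with embedded motifs
#'
#' Random background protein sequences; each planted motif's fixed residues
#' are written into a random subset of antigens at recorded (1-based)
#' offsets, avoiding overlaps between embeddings. The truth table lists
#' every embedding.
#'
#' @param cfg A [synthetic_config()].
#' @param n_antigens Number of antigens.
#' @param length Sequence length (must be at least the longest motif span).
#' @param seed Integer seed.
#' @param max_embeds_per_motif Upper bound on antigens carrying each motif.
#' @return List with `antigens` (data frame: `accession`, `name`,
#'   `sequence`) and `truth` (data frame: `pattern`, `accession`, `start`).
#' @export
generate_antigens <- function(cfg, n_antigens = 8L, length = 300L,
                              seed = cfg$seed, max_embeds_per_motif = 3L) {
  stopifnot(inherits(cfg, "synthetic_config"), n_antigens >= 1)
  spans <- vapply(cfg$planted_motifs, function(m) pattern_span(m$pattern), 1L)
  if (length(spans) && length < max(spans))
    stop_("antigen length shorter than the longest motif span")
  with_seed(seed, {
    seqs <- vapply(seq_len(n_antigens), function(i)
      paste(sample(AA_ALPHABET, length, replace = TRUE,
                   prob = cfg$background_freqs), collapse = ""),
      character(1))
    acc <- sprintf("SYNP%02d", seq_len(n_antigens))
    occupied <- vector("list", n_antigens)
    truth <- list()
    for (m in cfg$planted_motifs) {
      span <- pattern_span(m$pattern)
      sym <- strsplit(m$pattern, "")[[1L]]
      fixed <- which(sym != ".")
      n_embed <- sample.int(min(max_embeds_per_motif, n_antigens), 1L)
      into <- sample.int(n_antigens, n_embed)
      for (a in into) {
        start <- NA_integer_
        for (try in 1:100) {
          s <- sample.int(length - span + 1L, 1L)
          clash <- any(vapply(occupied[[a]], function(iv)
            s <= iv[2L] && iv[1L] <= s + span - 1L, logical(1)))
          if (!clash) { start <- s; break }
        }
        if (is.na(start)) next
        occupied[[a]] <- c(occupied[[a]], list(c(start, start + span - 1L)))
        for (j in fixed)
          substr(seqs[a], start + j - 1L, start + j - 1L) <- sym[j]
        truth[[length(truth) + 1L]] <-
          data.frame(pattern = m$pattern, accession = acc[a], start = start,
                     stringsAsFactors = FALSE)
      }
    }
    list(antigens = data.frame(accession = acc,
                               name = paste("synthetic antigen",
                                            seq_len(n_antigens)),
                               sequence = seqs, stringsAsFactors = FALSE),
         truth = if (length(truth)) do.call(rbind, truth)
                 else data.frame(pattern = character(0),
                                 accession = character(0),
                                 start = integer(0)))
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Builds the study design the analysis assumes: paired pre/post samples for
#' every `MelVac` subject (pre samples labelled `MelVac-CTRL`, mutually
#' paired), single query samples for `PEM-Mel` subjects, single background
#' samples for control groups, and — when `competition_depletion` is set —
#' a competition sample per `MelVac` subject in which planted-motif matching
#' reads are binomially thinned by the depletion factor.
#'
#' @param cfg A [synthetic_config()].
#' @return List with `cohort` (a [cohort()] of raw repertoires), and `truth`
#'   (list: `motifs` data frame, `sample_fractions` data frame of expected
#'   matching read fractions per sample and motif, and the `config`).
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  reps <- list()
  meta <- list()
  fractions <- list()
  add <- function(rep, subject, group, timepoint, paired = "", comp = "",
                  cond = "reference", applies = FALSE) {
    reps[[length(reps) + 1L]] <<- rep
    meta[[length(meta) + 1L]] <<- data.frame(
      sample_id = rep$sample_id, subject_id = subject, group = group,
      timepoint = timepoint, paired_with = paired, competition_of = comp,
      stringsAsFactors = FALSE)
    for (m in cfg$planted_motifs) {
      targeted <- group %in% m$target_groups ||
        (group == "MelVac-CTRL" && "MelVac" %in% m$target_groups)
      f <- if (applies && targeted)
        m$baseline_fraction * (if (cond == "query") m$fold else 1) else 0
      fractions[[length(fractions) + 1L]] <<- data.frame(
        sample_id = rep$sample_id, pattern = m$pattern, expected_fraction = f,
        stringsAsFactors = FALSE)
    }
  }
  for (g in names(cfg$n_subjects_per_group)) {
    ns <- cfg$n_subjects_per_group[[g]]
    if (ns == 0) next
    for (i in seq_len(ns)) {
      subject <- sprintf("%s%d", gsub("-", "", g), i)
      if (g == "MelVac") {
        pre_id <- paste0(subject, "_pre")
        post_id <- paste0(subject, "_post")
        pre <- generate_repertoire(cfg, "MelVac", "reference",
                                   seed = seed_stream(cfg$seed, pre_id),
                                   sample_id = pre_id)
        post <- generate_repertoire(cfg, "MelVac", "query",
                                    seed = seed_stream(cfg$seed, post_id),
                                    sample_id = post_id)
        add(pre, subject, "MelVac-CTRL", "pre", paired = post_id,
            cond = "reference", applies = TRUE)
        add(post, subject, "MelVac", "post", paired = pre_id,
            cond = "query", applies = TRUE)
        if (!is.null(cfg$competition_depletion)) {
          comp_id <- paste0(subject, "_comp")
          comp <- with_seed(seed_stream(cfg$seed, comp_id), {
            cnt <- post$counts
            pep <- names(cnt)
            hit <- rep(FALSE, length(pep))
            for (m in cfg$planted_motifs)
              if ("MelVac" %in% m$target_groups)
                hit <- hit | grepl(m$pattern, pep)
            cnt[hit] <- stats::rbinom(sum(hit), size = as.integer(cnt[hit]),
                                      prob = cfg$competition_depletion)
            keep <- cnt > 0
            peptide_repertoire(pep[keep], cnt[keep], sample_id = comp_id)
          })
          add(comp, subject, "MelVac", "post_competition", comp = post_id,
              cond = "query", applies = FALSE)
        }
      } else {
        sid <- paste0(subject, "_s1")
        cond <- if (g %in% unlist(lapply(cfg$planted_motifs,
                                         `[[`, "target_groups")))
          "query" else "reference"
        rep <- generate_repertoire(cfg, g, cond,
                                   seed = seed_stream(cfg$seed, sid),
                                   sample_id = sid)
        add(rep, subject, g, "single", cond = cond, applies = TRUE)
      }
    }
  }
  motifs <- do.call(rbind, lapply(cfg$planted_motifs, function(m)
    data.frame(pattern = m$pattern, baseline_fraction = m$baseline_fraction,
               fold = m$fold,
               target_groups = paste(m$target_groups, collapse = ";"),
               stringsAsFactors = FALSE)))
  list(cohort = cohort(reps, do.call(rbind, meta)),
       truth = list(motifs = motifs,
                    sample_fractions = do.call(rbind, fractions),
                    config = cfg))
}

#' Write a synthetic cohort to disk
#'
#' Writes the per-sample peptide TSVs, the sample-sheet CSV, the planted
#' motif truth table and (optionally) the antigen FASTA and its truth table
#' — the exact formats the loader and pipeline consume. Output is
#' byte-deterministic given the generator seed.
#'
#' @param sim Output of [generate_cohort()].
#' @param dir Output directory (created if missing).
#' @param antigens Optional output of [generate_antigens()].
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(sim, dir, antigens = NULL) {
  dir.create(file.path(dir, "data"), recursive = TRUE, showWarnings = FALSE)
  meta <- sim$cohort$meta
  meta$file <- file.path("data", paste0(meta$sample_id, ".tsv"))
  for (r in sim$cohort$repertoires)
    write_repertoire(r, file.path(dir, "data", paste0(r$sample_id, ".tsv")))
  utils::write.csv(meta, file.path(dir, "samples.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.table(sim$truth$motifs, file.path(dir, "truth_motifs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(antigens)) {
    write_antigen_fasta(antigens$antigens, file.path(dir, "antigens.fasta"))
    utils::write.table(antigens$truth, file.path(dir, "truth_antigens.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
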