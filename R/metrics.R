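# Immunoprofile comparison and summary metrics: cosine similarity of top-N
# peptide profiles, immunodominant epitope ranking, per-patient Z-score
# maps, pre/post abundance ratios and competition relative abundance.

#' Top-N peptides of a repertoire
#'
#' The `n` highest-abundance peptides, ties broken lexicographically by
#' peptide sequence; all peptides when the repertoire holds fewer than `n`.
#'
#' @param rep A normalized [peptide_repertoire()].
#' @param n Number of peptides (default 2500).
#' @return Data frame with columns `peptide`, `abundance`, in rank order.
#' @export
top_n_peptides <- function(rep, n = 2500L) {
  stopifnot(inherits(rep, "peptide_repertoire"), n >= 1)
  pep <- names(rep$counts)
  ord <- order_c(-rep$counts, pep)
  ord <- ord[seq_len(min(n, length(ord)))]
  data.frame(peptide = pep[ord], abundance = unname(rep$counts[ord]),
             stringsAsFactors = FALSE)
}

#' Cosine similarity index of two immunoprofiles
#'
#' The cosine of the angle between the two samples' top-`n` peptide
#' abundance vectors. The axes are the union of both samples' top-`n`
#' peptide lists; by default a sample contributes its abundance only for
#' peptides inside its own top-`n` list and 0 elsewhere, tying both
#' magnitude and membership to the top profile (set
#' `mask_to_top = FALSE` to use full-repertoire values on the union axes
#' instead). Returns 0 when either vector is all-zero.
#'
#' @param rep_a,rep_b Normalized [peptide_repertoire()]s.
#' @param n Top-list size (default 2500).
#' @param mask_to_top Logical; see Details.
#' @return CSI in `[0, 1]`.
#' @export
cosine_similarity <- function(rep_a, rep_b, n = 2500L, mask_to_top = TRUE) {
  stopifnot(inherits(rep_a, "peptide_repertoire"),
            inherits(rep_b, "peptide_repertoire"))
  if (!length(rep_a$counts) || !length(rep_b$counts))
    stop_("empty repertoire")
  top_a <- top_n_peptides(rep_a, n)
  top_b <- top_n_peptides(rep_b, n)
  axes <- union(top_a$peptide, top_b$peptide)
  value_on <- function(rep, top) {
    v <- numeric(length(axes))
    if (mask_to_top) {
      i <- match(top$peptide, axes)
      v[i] <- top$abundance
    } else {
      j <- match(axes, names(rep$counts))
      v[!is.na(j)] <- rep$counts[j[!is.na(j)]]
    }
    v
  }
  va <- value_on(rep_a, top_a)
  vb <- value_on(rep_b, top_b)
  na <- sqrt(sum(va^2))
  nb <- sqrt(sum(vb^2))
  if (na == 0 || nb == 0) return(0)
  min(1, sum(va * vb) / (na * nb))
}

#' Pairwise CSI matrix over a cohort
#'
#' @param co A [cohort()] of normalized repertoires.
#' @param n Top-list size.
#' @return Symmetric samples-by-samples matrix of CSI values (unit
#'   diagonal).
#' @export
csi_matrix <- function(co, n = 2500L) {
  ids <- co$meta$sample_id
  m <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (i in seq_along(ids)) {
    m[i, i] <- cosine_similarity(co$repertoires[[ids[i]]],
                                 co$repertoires[[ids[i]]], n)
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- cosine_similarity(co$repertoires[[ids[i]]],
                                              co$repertoires[[ids[j]]], n)
    }
  }
  m
}

#' Top-k immunodominant epitopes
#'
#' Ranks a set of epitope patterns by their abundance in a designated
#' sample (highest first, ties lexicographic) and returns the top `k`.
#'
#' @param patterns Character vector of epitope patterns.
#' @param rank_rep The designated [peptide_repertoire()] whose abundances
#'   define the ranking.
#' @param k Number of epitopes to keep (default 50).
#' @param count_mode Passed to [pattern_abundance()].
#' @return Data frame with columns `pattern`, `abundance`, in rank order.
#' @export
top_k_epitopes <- function(patterns, rank_rep, k = 50L, count_mode = "reads") {
  patterns <- unique(patterns)
  ab <- vapply(patterns, pattern_abundance, numeric(1), rep = rank_rep,
               count_mode = count_mode)
  ord <- order_c(-ab, patterns)
  ord <- ord[seq_len(min(k, length(ord)))]
  data.frame(pattern = patterns[ord], abundance = unname(ab[ord]),
             stringsAsFactors = FALSE)
}

#' Abundance matrix of epitopes over samples
#'
#' @param patterns Character vector of epitope patterns (rows).
#' @param co A [cohort()] of normalized repertoires (columns).
#' @param count_mode Passed to [pattern_abundance()].
#' @return Numeric matrix, patterns x samples; absent matches are 0.
#' @export
build_abundance_matrix <- function(patterns, co, count_mode = "reads") {
  patterns <- unique(patterns)
  ids <- co$meta$sample_id
  m <- matrix(0, length(patterns), length(ids),
              dimnames = list(patterns, ids))
  for (id in ids) {
    rep <- co$repertoires[[id]]
    pep <- names(rep$counts)
    for (p in patterns) {
      hit <- grepl(p, pep)
      m[p, id] <- if (count_mode == "reads") sum(rep$counts[hit]) else sum(hit)
    }
  }
  m
}

#' Per-patient Z-score map of epitope abundances
#'
#' Mean-centers and autoscales a patient's epitope-by-sample abundance
#' sub-matrix: one mean and one sample standard deviation (n-1 denominator)
#' are computed over all entries, and every entry is standardized with them.
#' With `apply_cap`, values above the patient's `cap_percentile` percentile
#' of the z-scores are capped at that percentile (one-sided, upper cap).
#'
#' @param mat Numeric matrix of a patient's epitope abundances (epitopes x
#'   paired samples), at least 2 values, not all equal.
#' @param cap_percentile Cap percentile (default 97.5).
#' @param apply_cap Logical; apply the upper cap (default `TRUE`).
#' @return Matrix of z-scores with the same dimensions.
#' @export
zscore_map <- function(mat, cap_percentile = 97.5, apply_cap = TRUE) {
  mat <- as.matrix(mat)
  if (length(mat) < 2L) stop_("need at least 2 values")
  s <- stats::sd(as.vector(mat))
  if (s == 0) stop_("constant matrix")
  z <- (mat - mean(mat)) / s
  if (apply_cap) {
    cap <- stats::quantile(as.vector(z), cap_percentile / 100, names = FALSE)
    z[z > cap] <- cap
  }
  z
}

#' Post/pre abundance ratio on a log10 scale
#'
#' `log10((post + 1) / (pre + 1))`: 0 means unchanged reactivity, positive
#' values a rise after treatment, negative a decrease. The +1 offsets keep
#' zero abundances defined.
#'
#' @param post,pre Non-negative abundances (vectorized).
#' @return log10 ratio(s).
#' @export
abundance_ratio <- function(post, pre) {
  stopifnot(all(post >= 0), all(pre >= 0))
  log10((post + 1) / (pre + 1))
}

#' Relative abundance under competition
#'
#' Abundance in the competed sample normalized to the paired uncompeted
#' sample; values well below 1 indicate that pre-blocking the serum removed
#' the antibodies binding the epitope.
#'
#' @param competed,uncompeted Abundances; `uncompeted` must be positive.
#' @return `competed / uncompeted` (vectorized).
#' @export
competition_relative_abundance <- function(competed, uncompeted) {
  if (any(uncompeted <= 0)) stop_("uncompeted abundance must be positive")
  competed / uncompeted
}
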