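# Discriminative epitope discovery: exhaustive fixed-residue pattern search
# scored by fold enrichment and hypergeometric p-values.

#' Discovery parameters
#'
#' Thresholds for [discover()]. `min_fold` defaults to 2 in discriminative
#' mode (query vs paired reference sample) and 10 in vs-random mode (query
#' vs randomly generated reference set); `max_p` defaults to the 1e-8
#' hypergeometric cutoff. `min_support` is the minimum number of distinct
#' matching query peptides a pattern needs to be considered (support is
#' monotone under pattern extension, so it is the search's only pruning
#' rule, keeping the enumeration exhaustive).
#'
#' @param min_fixed Minimum number of fixed residue positions in a reported
#'   epitope (default 4).
#' @param max_span Maximum pattern span (default 12, the peptide length).
#' @param min_fold Minimum fold enrichment; `NULL` selects the per-mode
#'   default.
#' @param max_p Hypergeometric p-value cutoff (default 1e-8).
#' @param min_support Minimum distinct matching query peptides (default 10).
#' @param count_mode Units for reported abundances and fold:
#'   `"reads"` (normalized read counts, default) or `"unique_peptides"`.
#' @return A list of class `discovery_params`.
#' @export
discovery_params <- function(min_fixed = 4L, max_span = 12L, min_fold = NULL,
                             max_p = 1e-8, min_support = 10L,
                             count_mode = c("reads", "unique_peptides")) {
  count_mode <- match.arg(count_mode)
  stopifnot(min_fixed >= 1, max_span >= 1, max_span <= 12,
            is.null(min_fold) || min_fold > 0, max_p > 0, min_support >= 1)
  structure(list(min_fixed = as.integer(min_fixed),
                 max_span = as.integer(max_span),
                 min_fold = min_fold, max_p = max_p,
                 min_support = as.integer(min_support),
                 count_mode = count_mode),
            class = "discovery_params")
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability `P(X >= k)` for the urn model behind discovery:
#' `N` distinct peptides in query plus reference, of which `K` match the
#' pattern; `n` peptides are in the query, `k` of them matching. Computed in
#' log space via the upper tail of the hypergeometric distribution, so it
#' stays accurate down to the smallest representable p-values.
#'
#' @param k Matching distinct peptides in the query.
#' @param n Distinct peptides in the query.
#' @param K Matching distinct peptides overall.
#' @param N Distinct peptides overall.
#' @return p in (0, 1].
#' @export
hypergeometric_pvalue <- function(k, n, K, N) {
  if (any(k != round(k) | n != round(n) | K != round(K) | N != round(N)))
    stop_("urn counts must be integers")
  if (any(k < 0 | K < 0 | n > N | K > N | k > pmin(n, K)))
    stop_("invalid urn: need 0 <= k <= min(n, K), n <= N, K <= N")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Fold enrichment of a pattern between two samples
#'
#' Ratio of match proportions, `(k_q/n_q) / ((k_r + 1)/n_r)`, with a +1
#' pseudocount on the reference matches so that reference-absent patterns
#' get a large but finite fold (conservative direction; never applied to the
#' query).
#'
#' @param k_q,n_q Matching and total abundance in the query, in the
#'   configured count units.
#' @param k_r,n_r Same for the reference.
#' @return Positive real fold enrichment.
#' @export
fold_enrichment <- function(k_q, n_q, k_r, n_r) {
  stopifnot(n_q > 0, n_r > 0, k_q >= 0, k_r >= 0)
  (k_q / n_q) / ((k_r + 1) / n_r)
}

#' Generate a random reference peptide set
#'
#' Background repertoire used as the comparison set in vs-random discovery:
#' `n_unique` distinct peptides drawn i.i.d. from the residue frequency
#' distribution, each with count 1, then normalized.
#'
#' @param n_unique Number of distinct peptides.
#' @param freqs Named residue probability vector (default uniform over the
#'   20 canonical letters).
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param target Normalization target.
#' @return A normalized [peptide_repertoire()].
#' @export
generate_random_reference <- function(n_unique, freqs = NULL, seed = 1L,
                                      target = 3e6) {
  stopifnot(n_unique >= 1)
  freqs <- check_freqs(freqs)
  n_support <- sum(freqs > 0)
  if (n_support^12 < n_unique)
    stop_("cannot draw %d distinct peptides from a %d-letter support",
          n_unique, n_support)
  pep <- with_seed(seed, draw_distinct_peptides(n_unique, freqs))
  normalize_reads(peptide_repertoire(pep, rep(1, n_unique),
                                     sample_id = "random_reference"),
                  target = target)
}

#' Discover enriched epitope patterns
#'
#' Exhaustive discriminative pattern search: enumerates every fixed-residue
#' pattern (wildcard gaps allowed, ends fixed, span bounded) by breadth-first
#' extension over match lists, pruning only on minimum query support, and
#' reports exactly the patterns passing the fixed-position, fold and
#' hypergeometric thresholds. The hypergeometric urn is always counted in
#' distinct unique peptides; fold and reported abundances use the configured
#' `count_mode`.
#'
#' @param query,reference Cleaned, normalized [peptide_repertoire()]s. In
#'   `vs_random` mode the reference should come from
#'   [generate_random_reference()].
#' @param params A [discovery_params()] object (default parameters if
#'   `NULL`).
#' @param mode `"discriminative"` (paired sample reference, min fold 2) or
#'   `"vs_random"` (random reference, min fold 10).
#' @return A data frame of class `enrichment_results` with columns
#'   `pattern`, `fixed_count`, `span`, `k_query`, `n_query`, `k_ref`,
#'   `n_ref`, `fold`, `p_value`, `mode`, sorted by ascending p-value, ties
#'   by descending fold then pattern.
#' @export
discover <- function(query, reference, params = NULL,
                     mode = c("discriminative", "vs_random")) {
  mode <- match.arg(mode)
  params <- params %||% discovery_params()
  stopifnot(inherits(params, "discovery_params"))
  min_fold <- params$min_fold %||% if (mode == "discriminative") 2 else 10
  stopifnot(inherits(query, "peptide_repertoire"),
            inherits(reference, "peptide_repertoire"))
  if (!query$normalized || !reference$normalized)
    stop_("discover expects normalized repertoires")
  if (!length(query$counts)) stop_("empty query repertoire")
  validate_repertoire(query)
  validate_repertoire(reference)

  Mq <- peptide_code_matrix(names(query$counts))
  Mr <- peptide_code_matrix(names(reference$counts))
  if (params$count_mode == "reads") {
    wq <- unname(query$counts); nq_tot <- query$total
    wr <- unname(reference$counts); nr_tot <- reference$total
  } else {
    wq <- rep(1, nrow(Mq)); nq_tot <- nrow(Mq)
    wr <- rep(1, max(nrow(Mr), 1L)); nr_tot <- max(nrow(Mr), 1L)
  }
  raw <- cpp_discover(Mq, wq, nq_tot, Mr, wr, nr_tot,
                      params$min_support, params$min_fixed, params$max_span,
                      min_fold, params$max_p,
                      paste(AA_ALPHABET, collapse = ""))
  n_out <- length(raw$pattern)
  res <- data.frame(pattern = raw$pattern, fixed_count = raw$fixed_count,
                    span = raw$span, k_query = raw$k_query,
                    n_query = rep(nq_tot, n_out),
                    k_ref = raw$k_ref, n_ref = rep(nr_tot, n_out),
                    fold = raw$fold, p_value = raw$p_value,
                    mode = rep(mode, n_out), stringsAsFactors = FALSE)
  res <- res[order_c(res$p_value, -res$fold, res$pattern), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "params") <- params
  class(res) <- c("enrichment_results", "data.frame")
  res
}

# 12-mer peptides -> integer code matrix (rows peptides, cols positions).
peptide_code_matrix <- function(peptides) {
  if (!length(peptides))
    return(matrix(integer(0), nrow = 0, ncol = 12))
  lookup <- integer(128)
  lookup[utf8ToInt(paste(AA_ALPHABET, collapse = ""))] <- seq_len(20L)
  codes <- lookup[utf8ToInt(paste(peptides, collapse = ""))]
  matrix(codes, ncol = 12L, byrow = TRUE)
}

#' Reduce discovery results to core epitopes
#'
#' Removes redundancy among discovered patterns: a pattern is dropped when
#' its set of matching query peptides is a subset of a retained pattern's
#' match set with smaller-or-equal p-value. Among patterns with equal
#' p-value and identical match sets the one with more fixed positions (then
#' the lexicographically smallest) is kept.
#'
#' @param results An `enrichment_results` data frame from one [discover()]
#'   call.
#' @param query The query repertoire the results came from.
#' @return The retained subset, same class and column layout.
#' @export
reduce_to_core <- function(results, query) {
  stopifnot(inherits(query, "peptide_repertoire"))
  if (!nrow(results)) return(results)
  peptides <- names(query$counts)
  sets <- lapply(results$pattern, function(p) which(grepl(p, peptides)))
  ord <- order_c(results$p_value, -results$fixed_count, results$pattern)
  kept <- integer(0)
  for (i in ord) {
    subsumed <- FALSE
    for (j in kept) {
      if (length(sets[[i]]) <= length(sets[[j]]) &&
          results$p_value[j] <= results$p_value[i] &&
          all(sets[[i]] %in% sets[[j]])) {
        subsumed <- TRUE
        break
      }
    }
    if (!subsumed) kept <- c(kept, i)
  }
  out <- results[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an enrichment result table
#'
#' TSV with columns `pattern`, `fixed_count`, `span`, `k_query`, `n_query`,
#' `k_ref`, `n_ref`, `fold`, `p_value`, `mode`.
#'
#' @param results An `enrichment_results` data frame.
#' @param path Output path.
#' @return `path` (writer) or the data frame (reader).
#' @export
write_enrichment <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_enrichment
#' @export
read_enrichment <- function(path) {
  res <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(res) <- c("enrichment_results", "data.frame")
  res
}
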