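# Independent brute-force oracles used across the suite. Each oracle is a
# direct transliteration of the quantity's definition, kept free of the
# package's own search/scan code paths.

# Exact hypergeometric upper tail by combinatorial summation. choose() on
# integer arguments is exact in doubles throughout the urn sizes used here,
# so the summation is accurate far below the comparison tolerance.
oracle_hyper_tail <- function(k, n, K, N) {
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Naive all-offsets alignment scan: character-by-character comparison.
oracle_align_starts <- function(pattern, sequence) {
  ps <- strsplit(pattern, "")[[1L]]
  ss <- strsplit(sequence, "")[[1L]]
  span <- length(ps)
  if (span > length(ss)) return(integer(0))
  fixed <- which(ps != ".")
  starts <- integer(0)
  for (o in 0:(length(ss) - span)) {
    if (all(ss[o + fixed] == ps[fixed])) starts <- c(starts, o + 1L)
  }
  starts
}

oracle_pattern_matches <- function(pattern, peptides) {
  vapply(peptides, function(p) length(oracle_align_starts(pattern, p)) > 0,
         logical(1), USE.NAMES = FALSE)
}

# Every pattern (wildcard-interior grammar, fixed ends) occurring in at
# least one of the given peptides, up to max_span.
oracle_candidate_patterns <- function(peptides, max_span) {
  out <- character(0)
  for (pep in peptides) {
    L <- nchar(pep)
    for (o in 1:L) {
      for (s in 1:min(max_span, L - o + 1L)) {
        win <- strsplit(substring(pep, o, o + s - 1L), "")[[1L]]
        interior <- if (s > 2) 2:(s - 1L) else integer(0)
        masks <- if (length(interior))
          expand.grid(rep(list(c(FALSE, TRUE)), length(interior)))
        else data.frame(row.names = 1)
        for (r in seq_len(nrow(masks))) {
          w <- win
          if (length(interior))
            w[interior[unlist(masks[r, ])]] <- "."
          out <- c(out, paste(w, collapse = ""))
        }
      }
    }
  }
  unique(out)
}

# Full brute-force discovery over the bounded pattern space; mirrors the
# documented output contract (thresholds, urn, ordering) by direct
# evaluation of every candidate.
oracle_discover <- function(query, reference, min_fixed, max_span, min_fold,
                            max_p, min_support, count_mode = "reads") {
  qpep <- names(query$counts)
  rpep <- names(reference$counts)
  cands <- oracle_candidate_patterns(qpep, max_span)
  cands <- cands[vapply(cands, function(p)
    nchar(gsub(".", "", p, fixed = TRUE)) >= min_fixed, logical(1))]
  rows <- list()
  for (p in cands) {
    mq <- oracle_pattern_matches(p, qpep)
    if (sum(mq) < min_support) next
    mr <- oracle_pattern_matches(p, rpep)
    if (count_mode == "reads") {
      kq <- sum(query$counts[mq]); nq <- query$total
      kr <- sum(reference$counts[mr]); nr <- reference$total
    } else {
      kq <- sum(mq); nq <- length(qpep)
      kr <- sum(mr); nr <- length(rpep)
    }
    fold <- (kq / nq) / ((kr + 1) / nr)
    if (fold < min_fold) next
    pv <- oracle_hyper_tail(sum(mq), length(qpep), sum(mq) + sum(mr),
                            length(qpep) + length(rpep))
    if (!(pv < max_p)) next
    rows[[length(rows) + 1L]] <- data.frame(
      pattern = p, k_query = kq, k_ref = kr, fold = fold, p_value = pv,
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(pattern = character(0), k_query = numeric(0),
                      k_ref = numeric(0), fold = numeric(0),
                      p_value = numeric(0)))
  df <- do.call(rbind, rows)
  df <- df[order(df$p_value, -df$fold, df$pattern, method = "radix"), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

# AUC by explicit enumeration of all (positive, negative) pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Youden's J by sweeping every candidate threshold directly.
oracle_youden <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  thr <- c(sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  J <- sens + spec - 1
  i <- order(-J, -spec, thr)[1L]
  list(threshold = thr[i], sensitivity = sens[i], specificity = spec[i],
       youden = J[i])
}

# Small random repertoire fixture over a reduced alphabet (so that shared
# motifs recur and discovery output is non-trivial).
random_small_repertoire <- function(n, alphabet = c("A", "C", "D", "E", "G",
                                                    "K"),
                                    sample_id = "toy", normalized = TRUE) {
  pep <- unique(replicate(n * 2, paste(sample(alphabet, 12, replace = TRUE),
                                       collapse = "")))[seq_len(n)]
  rep <- peptide_repertoire(pep, sample.int(20, n, replace = TRUE),
                            sample_id = sample_id)
  if (normalized) normalize_reads(rep) else rep
}

# Tiny generator config used across tests.
small_config <- function(seed = 1L, ...) {
  synthetic_config(seed = seed,
                   n_subjects_per_group = c("MelVac" = 1L, "PEM-Mel" = 1L,
                                            "CTRL-Mel" = 2L,
                                            "CTRL-NSCLC" = 1L),
                   reads_per_sample = 5e4,
                   unique_peptides_per_sample = 1e4, ...)
}
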