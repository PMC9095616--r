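test_that("hypergeometric tail matches exact combinatorial values", {
  expect_equal(hypergeometric_pvalue(0, 4, 5, 10), 1)
  expect_equal(hypergeometric_pvalue(4, 4, 5, 10), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeometric_pvalue(2, 3, 3, 6), 0.5, tolerance = 1e-12)
  # monotone non-increasing in k
  p <- vapply(0:5, hypergeometric_pvalue, numeric(1), n = 8, K = 5, N = 20)
  expect_true(all(diff(p) <= 0))
  # bound violations error
  expect_error(hypergeometric_pvalue(6, 5, 5, 10), "invalid urn")
  expect_error(hypergeometric_pvalue(1, 11, 5, 10), "invalid urn")
})

test_that("fold enrichment applies the reference pseudocount", {
  expect_equal(fold_enrichment(20, 100, 9, 100), 2)
  expect_true(is.finite(fold_enrichment(10, 100, 0, 100)))
  expect_gt(fold_enrichment(10, 100, 0, 100), 0)
  expect_equal(fold_enrichment(1e5, 1e6, 1e5 - 1, 1e6), 1, tolerance = 1e-4)
})

test_that("random reference sets are reproducible and background-like", {
  r1 <- generate_random_reference(100, seed = 5)
  r2 <- generate_random_reference(100, seed = 5)
  expect_identical(r1$counts, r2$counts)
  expect_equal(length(r1$counts), 100L)
  expect_true(r1$normalized)
  # analytic occurrence rate of a 4-fixed contiguous probe
  big <- generate_random_reference(1e4, seed = 6)
  exp_m <- 9 * (1 / 20)^4 * 1e4
  obs <- pattern_abundance("ACDE", big, count_mode = "unique_peptides")
  expect_lt(abs(obs - exp_m), 3.5 * sqrt(exp_m) + 1)
  # degenerate distribution cannot supply distinct peptides
  expect_error(generate_random_reference(
    5, freqs = setNames(c(1, rep(0, 19)), AA_ALPHABET), seed = 1),
    "distinct")
})

test_that("discover finds a planted extreme pattern and nothing on nulls", {
  set.seed(19)
  bg <- unique(replicate(60, paste(sample(AA_ALPHABET, 12, replace = TRUE),
                                   collapse = "")))
  carriers <- vapply(bg[1:30], function(p) {
    substr(p, 4, 7) <- "WHKD"
    p
  }, character(1), USE.NAMES = FALSE)
  query <- normalize_reads(peptide_repertoire(
    unique(c(carriers, bg[31:40])), rep(1, length(unique(c(carriers,
                                                           bg[31:40]))))))
  reference <- normalize_reads(peptide_repertoire(bg[41:60], rep(1, 20)))
  res <- discover(query, reference,
                  discovery_params(min_support = 5, max_p = 1e-4),
                  mode = "discriminative")
  expect_true("WHKD" %in% res$pattern)
  # identical repertoires yield nothing at the default thresholds
  res0 <- discover(query, query, mode = "discriminative")
  expect_equal(nrow(res0), 0L)
  # empty query errors
  empty <- peptide_repertoire(character(0), numeric(0))
  empty$normalized <- TRUE
  expect_error(discover(empty, reference), "empty query")
})

test_that("discover equals the brute-force enumeration oracle on toy sets", {
  set.seed(23)
  for (case in 1:6) {
    q <- random_small_repertoire(25, sample_id = "q")
    r <- random_small_repertoire(25, sample_id = "r")
    # irregular thresholds avoid exact p == max_p / fold == min_fold ties,
    # which two numerically different but equally correct implementations
    # may resolve oppositely
    params <- discovery_params(min_fixed = 2, max_span = 6, min_fold = 1.47,
                               max_p = 0.2937, min_support = 2)
    got <- discover(q, r, params, mode = "discriminative")
    want <- oracle_discover(q, r, min_fixed = 2, max_span = 6,
                            min_fold = 1.47, max_p = 0.2937, min_support = 2)
    # identical pattern sets with identical statistics (canonical order by
    # pattern; the reported order itself is checked below)
    g <- got[order(got$pattern, method = "radix"), , drop = FALSE]
    w <- want[order(want$pattern, method = "radix"), , drop = FALSE]
    expect_identical(g$pattern, w$pattern)
    expect_equal(g$k_query, w$k_query, tolerance = 1e-9)
    expect_equal(g$k_ref, w$k_ref, tolerance = 1e-9)
    expect_equal(g$fold, w$fold, tolerance = 1e-9)
    expect_equal(g$p_value, w$p_value, tolerance = 1e-9)
    # output honours its own ordering contract
    expect_identical(order(got$p_value, -got$fold, got$pattern,
                           method = "radix"),
                     seq_len(nrow(got)))
  }
})

test_that("reported results re-validate from raw abundances and the urn", {
  set.seed(29)
  q <- random_small_repertoire(30, sample_id = "q")
  r <- random_small_repertoire(30, sample_id = "r")
  res <- discover(q, r, discovery_params(min_fixed = 2, max_span = 5,
                                         min_fold = 1.2, max_p = 0.9,
                                         min_support = 2))
  expect_gt(nrow(res), 0)
  for (i in seq_len(nrow(res))) {
    p <- res$pattern[i]
    expect_equal(pattern_abundance(p, q), res$k_query[i], tolerance = 1e-9)
    expect_equal(pattern_abundance(p, r), res$k_ref[i], tolerance = 1e-9)
    uq <- pattern_abundance(p, q, count_mode = "unique_peptides")
    ur <- pattern_abundance(p, r, count_mode = "unique_peptides")
    expect_equal(hypergeometric_pvalue(uq, length(q$counts), uq + ur,
                                       length(q$counts) + length(r$counts)),
                 res$p_value[i], tolerance = 1e-12)
    expect_equal(fold_enrichment(res$k_query[i], res$n_query[i],
                                 res$k_ref[i], res$n_ref[i]),
                 res$fold[i], tolerance = 1e-12)
  }
  # deterministic ordered output
  res2 <- discover(q, r, discovery_params(min_fixed = 2, max_span = 5,
                                          min_fold = 1.2, max_p = 0.9,
                                          min_support = 2))
  expect_identical(res, res2)
})

test_that("reduce_to_core removes subsumed patterns per the containment rule", {
  q <- normalize_reads(peptide_repertoire(
    c("AAAWHKDAAAAA", "CCCWHKDCCCCC", "GGGWHKDGGGGG", "AAAAAAAAAAAA"),
    c(5, 5, 5, 5)))
  res <- data.frame(pattern = c("WHKD", "WHK."),
                    fixed_count = c(4L, 3L), span = c(4L, 4L),
                    k_query = c(1, 1), n_query = 1, k_ref = 0, n_ref = 1,
                    fold = c(5, 5), p_value = c(1e-12, 1e-10),
                    mode = "discriminative", stringsAsFactors = FALSE)
  class(res) <- c("enrichment_results", "data.frame")
  out <- reduce_to_core(res, q)
  expect_identical(out$pattern, "WHKD")
  # disjoint match sets are both kept
  q2 <- normalize_reads(peptide_repertoire(
    c("AAAWHKDAAAAA", "CCCWHKDCCCCC", "GGGGGGGGGGGG"), c(5, 5, 5)))
  res2 <- res
  res2$pattern <- c("WHKD", "GGGG")
  out2 <- reduce_to_core(res2, q2)
  expect_setequal(out2$pattern, c("WHKD", "GGGG"))
})

test_that("reduce_to_core agrees with the pairwise containment oracle", {
  set.seed(31)
  q <- random_small_repertoire(40, sample_id = "q")
  r <- random_small_repertoire(40, sample_id = "r")
  res <- discover(q, r, discovery_params(min_fixed = 2, max_span = 5,
                                         min_fold = 1.1, max_p = 0.95,
                                         min_support = 2))
  expect_gt(nrow(res), 5)
  out <- reduce_to_core(res, q)
  peptides <- names(q$counts)
  sets <- lapply(res$pattern, function(p)
    which(oracle_pattern_matches(p, peptides)))
  names(sets) <- res$pattern
  # oracle: iterate candidates in (p, -fixed, pattern) order, keep those not
  # contained in an already-kept pattern's match set with p <= own
  ord <- order(res$p_value, -res$fixed_count, res$pattern, method = "radix")
  kept <- character(0)
  for (i in ord) {
    contained <- any(vapply(kept, function(kp) {
      res$p_value[res$pattern == kp] <= res$p_value[i] &&
        all(sets[[res$pattern[i]]] %in% sets[[kp]])
    }, logical(1)))
    if (!contained) kept <- c(kept, res$pattern[i])
  }
  expect_setequal(out$pattern, kept)
})
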