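test_that("background peptide sampling follows the residue distribution", {
  # point-mass distribution
  f <- setNames(c(1, rep(0, 19)), AA_ALPHABET)
  set.seed(1)
  expect_identical(sample_background_peptide(f), "AAAAAAAAAAAA")
  # determinism
  set.seed(99); a <- sample_background_peptides(5)
  set.seed(99); b <- sample_background_peptides(5)
  expect_identical(a, b)
  # uniform frequencies: per-position counts within 3 binomial SE of 1/20
  set.seed(2)
  n <- 1e5
  pep <- sample_background_peptides(n)
  pos1 <- substring(pep, 1, 1)
  freq <- table(factor(pos1, levels = AA_ALPHABET)) / n
  se <- sqrt(0.05 * 0.95 / n)
  expect_true(all(abs(freq - 0.05) < 3.3 * se))
  # invalid distribution errors
  expect_error(sample_background_peptides(5, c(A = 0.5)), "sum to 1")
})

test_that("generated repertoires hit the planted motif read fractions", {
  cfg <- synthetic_config(
    seed = 3, reads_per_sample = 3e5, unique_peptides_per_sample = 3e4,
    planted_motifs = list(planted_motif("WHKD.E", 1e-3, 10, "MelVac")))
  q <- generate_repertoire(cfg, "MelVac", "query", seed = 31)
  frac_q <- pattern_abundance("WHKD.E", normalize_reads(q)) / 3e6
  expect_lt(abs(frac_q - 0.01) / 0.01, 0.2)
  r <- generate_repertoire(cfg, "MelVac", "reference", seed = 32)
  frac_r <- pattern_abundance("WHKD.E", normalize_reads(r)) / 3e6
  expect_lt(abs(frac_r - 0.001) / 0.001, 0.25)
  # empirical fold between conditions recovers the configured fold
  expect_lt(abs(frac_q / frac_r - 10) / 10, 0.25)
  # untargeted group stays at background level
  c0 <- generate_repertoire(cfg, "CTRL-Mel", "reference", seed = 33)
  bg <- pattern_abundance("WHKD.E", normalize_reads(c0)) / 3e6
  # background probability of a 5-fixed contiguous-window motif
  p_bg <- 7 * (1 / 20)^5
  expect_lt(bg, 10 * p_bg + 1e-4)
  # determinism
  q2 <- generate_repertoire(cfg, "MelVac", "query", seed = 31)
  expect_identical(q$counts, q2$counts)
})

test_that("generator without motifs matches analytic background rates", {
  cfg <- synthetic_config(seed = 5, reads_per_sample = 1e5,
                          unique_peptides_per_sample = 2e4,
                          planted_motifs = list())
  rep <- generate_repertoire(cfg, "CTRL-Mel", "reference", seed = 51)
  n <- length(rep$counts)
  probe <- "ACDE"
  # expected unique-peptide matches: 9 windows x (1/20)^4 per peptide
  exp_u <- n * 9 * (1 / 20)^4
  obs_u <- pattern_abundance(probe, normalize_reads(rep),
                             count_mode = "unique_peptides")
  expect_lt(abs(obs_u - exp_u), 3.5 * sqrt(exp_u) + 1)
})

test_that("generate_antigens embeds motifs verifiably and reports truth", {
  cfg <- small_config(seed = 8)
  ant <- generate_antigens(cfg, n_antigens = 20, length = 200, seed = 81)
  expect_equal(nrow(ant$antigens), 20L)
  expect_gt(nrow(ant$truth), 0L)
  for (i in seq_len(nrow(ant$truth))) {
    seq <- ant$antigens$sequence[ant$antigens$accession ==
                                   ant$truth$accession[i]]
    hits <- align_pattern_to_sequence(ant$truth$pattern[i], seq)
    expect_true(ant$truth$start[i] %in% hits$start)
  }
  # no motifs -> empty truth
  cfg0 <- synthetic_config(seed = 8, planted_motifs = list())
  ant0 <- generate_antigens(cfg0, n_antigens = 2, length = 50, seed = 82)
  expect_equal(nrow(ant0$truth), 0L)
})

test_that("generate_cohort builds the paired study design with ground truth", {
  cfg <- synthetic_config(seed = 13,
                          n_subjects_per_group = c("MelVac" = 2L),
                          reads_per_sample = 2e4,
                          unique_peptides_per_sample = 5e3)
  sim <- generate_cohort(cfg)
  meta <- sim$cohort$meta
  expect_equal(nrow(meta), 4L)
  post <- meta[meta$group == "MelVac", ]
  pre <- meta[meta$group == "MelVac-CTRL", ]
  expect_equal(nrow(post), 2L)
  expect_identical(sort(post$paired_with), sort(pre$sample_id))
  expect_identical(meta$subject_id[match(post$paired_with, meta$sample_id)],
                   post$subject_id)
  expect_equal(nrow(sim$truth$sample_fractions),
               4L * length(cfg$planted_motifs))
  # determinism: regenerating gives identical repertoires
  sim2 <- generate_cohort(cfg)
  expect_identical(lapply(sim$cohort$repertoires, `[[`, "counts"),
                   lapply(sim2$cohort$repertoires, `[[`, "counts"))
})

test_that("competition samples deplete motif-matching reads as configured", {
  base <- list(planted_motif("WHKDE", 2e-3, 10, "MelVac"))
  for (depl in c(1.0, 0.1)) {
    cfg <- synthetic_config(seed = 17,
                            n_subjects_per_group = c("MelVac" = 1L),
                            reads_per_sample = 3e5,
                            unique_peptides_per_sample = 3e4,
                            planted_motifs = base,
                            competition_depletion = depl)
    sim <- generate_cohort(cfg)
    meta <- sim$cohort$meta
    comp_id <- meta$sample_id[nzchar(meta$competition_of)]
    parent_id <- meta$competition_of[meta$sample_id == comp_id]
    comp <- normalize_reads(sim$cohort$repertoires[[comp_id]])
    parent <- normalize_reads(sim$cohort$repertoires[[parent_id]])
    rel <- competition_relative_abundance(
      pattern_abundance("WHKDE", comp), pattern_abundance("WHKDE", parent))
    if (depl == 1.0) {
      expect_equal(rel, 1, tolerance = 0.02)
    } else {
      expect_lt(abs(rel - depl) / depl, 0.25)
    }
  }
})

test_that("cohort writing is byte-deterministic under a fixed seed", {
  cfg <- synthetic_config(seed = 23,
                          n_subjects_per_group = c("MelVac" = 1L,
                                                   "CTRL-Mel" = 1L),
                          reads_per_sample = 1e4,
                          unique_peptides_per_sample = 2e3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_cohort(generate_cohort(cfg), d1)
  write_cohort(generate_cohort(cfg), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))))
})
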