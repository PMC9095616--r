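test_that("wilcoxon rank-sum approximates the exact null on tiny samples", {
  # exhaustive permutation oracle for x={1,2}, y={3,4}: two-sided p = 1/3
  got <- wilcoxon_rank_sum(c(1, 2), c(3, 4))
  expect_lt(abs(got$p_value - 1 / 3), 0.15)
  # identical groups are null
  expect_gte(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)
  # all-identical values are defined with p = 1
  expect_equal(wilcoxon_rank_sum(c(5, 5), c(5, 5, 5))$p_value, 1)
  # matches the reference implementation with continuity correction
  set.seed(53)
  x <- rnorm(15); y <- rnorm(20, 0.5)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(wilcoxon_rank_sum(x, y)$p_value, ref$p.value)
})

test_that("roc_points counts confusion matrices exactly", {
  pts <- roc_points(c(5, 6, 7, 1, 2, 3), c(TRUE, TRUE, TRUE, FALSE, FALSE,
                                           FALSE))
  at4 <- pts[pts$threshold == 5, ]  # first separating cutpoint
  expect_equal(at4$sensitivity, 1)
  expect_equal(at4$specificity, 1)
  inf <- pts[is.infinite(pts$threshold), ]
  expect_equal(inf$sensitivity, 0)
  expect_equal(inf$specificity, 1)
  expect_error(roc_points(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # random case vs direct counting oracle
  set.seed(59)
  sc <- sample(1:20, 50, replace = TRUE)
  lb <- sample(c(TRUE, FALSE), 50, replace = TRUE)
  pts2 <- roc_points(sc, lb)
  for (i in seq_len(nrow(pts2))) {
    t <- pts2$threshold[i]
    expect_equal(pts2$sensitivity[i], mean(sc[lb] >= t))
    expect_equal(pts2$specificity[i], mean(sc[!lb] < t))
  }
})

test_that("youden_optimal equals the brute-force threshold sweep", {
  yo <- youden_optimal(c(5, 6, 7, 1, 2, 3),
                       c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(yo$youden, 1)
  expect_equal(yo$threshold, 5)  # lowest separating evaluated cutpoint
  yo2 <- youden_optimal(c(1, 5, 6, 2, 3, 4),
                        c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(yo2$youden, 2 / 3, tolerance = 1e-12)
  expect_equal(yo2$threshold, 5)
  expect_equal(yo2$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(yo2$specificity, 1)
  set.seed(61)
  for (i in 1:20) {
    sc <- sample(1:15, 40, replace = TRUE)
    lb <- c(rep(TRUE, 20), rep(FALSE, 20))
    expect_identical(youden_optimal(sc, lb), oracle_youden(sc, lb))
  }
})

test_that("auc equals pair enumeration and the standard properties", {
  expect_equal(auc(c(0.9, 0.4, 0.1, 0.5), c(1, 1, 0, 0)), 0.75)
  expect_equal(auc(rep(2, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  set.seed(67)
  for (i in 1:10) {
    sc <- sample(1:30, 60, replace = TRUE)
    lb <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.4, 0.6))
    if (!any(lb) || all(lb)) next
    expect_equal(auc(sc, lb), oracle_auc(sc, lb), tolerance = 1e-12)
    # label flip symmetry
    expect_equal(auc(sc, !lb), 1 - auc(sc, lb), tolerance = 1e-12)
    # invariance under monotone transform
    expect_equal(auc(exp(sc / 10), lb), auc(sc, lb), tolerance = 1e-12)
    j1 <- youden_optimal(sc, lb)$youden
    j2 <- youden_optimal(exp(sc / 10), lb)$youden
    expect_equal(j1, j2, tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent ROC implementation", {
  set.seed(71)
  sc <- rnorm(80)
  lb <- sample(c(TRUE, FALSE), 80, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc(sc, lb), ref, tolerance = 1e-9)
})

test_that("rank_markers enforces floors and ordering, and recovers plants", {
  # a perfectly separating epitope ranks first with J = 1
  mat <- rbind(perfect = c(10, 9, 8, 1, 2, 3),
               flat = rep(1, 6),
               weak = c(5, 1, 5, 1, 5, 1))
  labels <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  mk <- rank_markers(mat, labels, k = 15)
  expect_equal(mk$pattern[1], "perfect")
  expect_equal(mk$youden[1], 1)
  expect_true(all(mk$sensitivity > 0.72 & mk$specificity > 0.67))
  # identical distributions leave nothing
  mk0 <- rank_markers(rbind(a = rep(2, 6), b = rep(3, 6)), labels)
  expect_equal(nrow(mk0), 0L)
  # 3 planted discriminative rows among 100 nulls end up on top
  hits_top <- 0L
  for (s in 1:20) {
    set.seed(300 + s)
    n <- 24
    lb <- rep(c(TRUE, FALSE), each = n / 2)
    null_rows <- matrix(rlnorm(100 * n, 3, 1), nrow = 100,
                        dimnames = list(sprintf("null%03d", 1:100), NULL))
    plant_rows <- matrix(rlnorm(3 * n, 3, 1), nrow = 3,
                         dimnames = list(c("plantA", "plantB", "plantC"),
                                         NULL))
    plant_rows[, lb] <- plant_rows[, lb] * 40
    mm <- rbind(plant_rows, null_rows)
    top5 <- rank_markers(mm, lb, k = 5)$pattern
    if (all(c("plantA", "plantB", "plantC") %in% top5))
      hits_top <- hits_top + 1L
  }
  expect_gte(hits_top, 18L)
})

test_that("fit_logistic recovers parameters and flags separation", {
  # parameter recovery at n = 2000, beta = (0, 2)
  set.seed(73)
  x <- rnorm(2000)
  y <- rbinom(2000, 1, plogis(0 + 2 * x))
  fit <- fit_logistic(matrix(x, dimnames = list(NULL, "m1")), y == 1)
  se <- sqrt(diag(vcov(glm(y ~ x, family = binomial()))))
  expect_lt(abs(fit$coefficients[["(Intercept)"]] - 0), 3 * se[1])
  expect_lt(abs(fit$coefficients[["m1"]] - 2), 3 * se[2])
  expect_true(fit$converged)
  expect_gt(fit$auc, 0.8)
  # complete separation: AUC 1, flagged non-converged
  xs <- c(1, 2, 3, 10, 11, 12)
  ys <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  sep <- fit_logistic(matrix(xs, dimnames = list(NULL, "m1")), ys)
  expect_equal(sep$auc, 1)
  expect_false(sep$converged)
  expect_equal(sep$sensitivity, 1)
  expect_equal(sep$specificity, 1)
  # duplicated columns are dropped with a warning, fit proceeds
  X <- cbind(a = x, b = x)
  expect_warning(fit2 <- fit_logistic(X, y == 1), "duplicated")
  expect_identical(fit2$markers, "a")
  expect_error(fit_logistic(matrix(1:4, ncol = 1), rep(TRUE, 4)),
               "per class")
})

test_that("best_subset maximizes combined AUC with the tie rules", {
  set.seed(79)
  n <- 40
  lb <- rep(c(TRUE, FALSE), each = n / 2)
  perfect <- ifelse(lb, 10, 1) + rnorm(n, 0, 0.1)
  noise1 <- rnorm(n)
  noise2 <- rnorm(n)
  mat <- cbind(good = perfect, n1 = noise1, n2 = noise2)
  best <- best_subset(mat, lb, max_size = 3)
  expect_equal(best$auc, 1)
  expect_identical(best$subset, "good")   # smallest subset wins the tie
  # two complementary weak markers beat each singleton
  u <- rnorm(n)
  v <- ifelse(lb, 2, 0) - u + rnorm(n, 0, 0.3)
  mat2 <- cbind(u = u, v = v)
  pair <- best_subset(mat2, lb, max_size = 2)
  a_u <- fit_logistic(mat2[, "u", drop = FALSE], lb)$auc
  a_v <- fit_logistic(mat2[, "v", drop = FALSE], lb)$auc
  expect_identical(sort(pair$subset), c("u", "v"))
  expect_gt(pair$auc, max(a_u, a_v))
  # max_size = 1 reduces to argmax of single-marker AUCs
  best1 <- best_subset(mat2, lb, max_size = 1)
  expect_equal(best1$auc, max(a_u, a_v))
})
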