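# Group-differentiation statistics: Wilcoxon rank-sum, per-epitope ROC with
# Youden-optimal cutoffs, marker ranking, combined logistic models with AUC.

#' Wilcoxon rank-sum test with continuity correction
#'
#' Two-sided rank-sum test using midranks for ties, the normal approximation
#' with tie-corrected variance, and continuity correction 0.5 (the base R
#' test with `exact = FALSE, correct = TRUE`). When every value across both
#' groups is identical the test is undefined and p = 1 is returned.
#'
#' @param x,y Numeric vectors, each non-empty.
#' @return List with `statistic` (the rank-sum W) and `p_value`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p_value = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = TRUE))
  p <- wt$p.value
  if (is.na(p)) p <- 1
  list(statistic = unname(wt$statistic), p_value = min(1, p))
}

#' ROC points for a score vector
#'
#' One point per candidate threshold (every distinct score plus `+Inf`),
#' with a positive call when `score >= threshold`. Sensitivity and
#' specificity are exact confusion-matrix proportions.
#'
#' @param scores Numeric scores.
#' @param labels Logical (or 0/1) labels, `TRUE` = positive class; both
#'   classes must be present.
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  if (!any(labels) || all(labels)) stop_("both classes must be present")
  thr <- c(sort(unique(scores)), Inf)
  pos <- scores[labels]
  neg <- scores[!labels]
  data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(t) mean(pos >= t), numeric(1)),
    specificity = vapply(thr, function(t) mean(neg < t), numeric(1)))
}

#' Youden-optimal operating point
#'
#' The ROC point maximizing Youden's J = sensitivity + specificity - 1;
#' ties are broken by higher specificity, then lower threshold.
#'
#' @inheritParams roc_points
#' @return List with `threshold`, `sensitivity`, `specificity`, `youden`.
#' @export
youden_optimal <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  J <- pts$sensitivity + pts$specificity - 1
  i <- order(-J, -pts$specificity, pts$threshold)[1L]
  list(threshold = pts$threshold[i], sensitivity = pts$sensitivity[i],
       specificity = pts$specificity[i], youden = J[i])
}

#' Area under the ROC curve
#'
#' Rank-statistic (Mann-Whitney) formulation: the fraction of
#' (positive, negative) pairs in which the positive score exceeds the
#' negative, counting ties as half.
#'
#' @inheritParams roc_points
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels)
  n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop_("both classes must be present")
  r <- rank(scores)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Rank epitope markers by group discrimination
#'
#' For every epitope row of an abundance matrix, finds the Youden-optimal
#' cutoff and the Wilcoxon rank-sum p-value between the two groups, keeps
#' markers whose sensitivity and specificity exceed the floors, ranks by
#' descending Youden's J (ties by ascending p, then pattern) and returns
#' the top `k`.
#'
#' @param mat Abundance matrix, epitopes x samples (see
#'   [build_abundance_matrix()]).
#' @param labels Logical vector per sample, `TRUE` = case.
#' @param min_sens,min_spec Performance floors (defaults 0.72 and 0.67,
#'   strict inequalities).
#' @param k Maximum number of markers returned (default 15).
#' @return Data frame of class `marker_performance` with columns `pattern`,
#'   `threshold`, `sensitivity`, `specificity`, `youden`, `wilcoxon_p`;
#'   possibly fewer than `k` rows.
#' @export
rank_markers <- function(mat, labels, min_sens = 0.72, min_spec = 0.67,
                         k = 15L) {
  labels <- as.logical(labels)
  stopifnot(ncol(mat) == length(labels))
  rows <- lapply(rownames(mat), function(p) {
    sc <- mat[p, ]
    yo <- youden_optimal(sc, labels)
    wp <- wilcoxon_rank_sum(sc[labels], sc[!labels])$p_value
    data.frame(pattern = p, threshold = yo$threshold,
               sensitivity = yo$sensitivity, specificity = yo$specificity,
               youden = yo$youden, wilcoxon_p = wp, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  df <- df[df$sensitivity > min_sens & df$specificity > min_spec, ,
           drop = FALSE]
  df <- df[order_c(-df$youden, df$wilcoxon_p, df$pattern), , drop = FALSE]
  df <- df[seq_len(min(k, nrow(df))), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("marker_performance", "data.frame")
  df
}

#' Fit a combined logistic biomarker model
#'
#' Maximum-likelihood logistic regression (iteratively reweighted least
#' squares, log-likelihood tolerance 1e-8, at most 100 iterations) of the
#' class labels on the supplied feature columns (conventionally
#' `log10(x + 1)`-transformed abundances). Constant and duplicated feature
#' columns are dropped with a warning. On complete separation the fit stops
#' at the iteration cap, is flagged `converged = FALSE`, and scores, AUC and
#' the Youden-optimal operating point are still reported (the ROC summary is
#' separation-robust).
#'
#' @param features Numeric matrix, samples x markers, with column names.
#' @param labels Logical vector per sample; at least 2 samples per class.
#' @return List of class `combined_model`: `markers`, `coefficients`
#'   (intercept first), `auc`, `sensitivity`, `specificity`, `threshold`
#'   (on the linear-predictor scale), `converged`, `scores`, `warnings`.
#' @export
fit_logistic <- function(features, labels) {
  labels <- as.logical(labels)
  features <- as.matrix(features)
  stopifnot(nrow(features) == length(labels))
  if (sum(labels) < 2 || sum(!labels) < 2)
    stop_("need at least 2 samples per class")
  warn <- character(0)
  keep <- rep(TRUE, ncol(features))
  for (j in seq_len(ncol(features))) {
    if (!keep[j]) next
    if (length(unique(features[, j])) == 1L) {
      keep[j] <- FALSE
      warn <- c(warn, sprintf("dropped constant column '%s'",
                              colnames(features)[j]))
      next
    }
    for (i in seq_len(j - 1L)) {
      if (keep[i] && isTRUE(all.equal(features[, i], features[, j],
                                      check.attributes = FALSE))) {
        keep[j] <- FALSE
        warn <- c(warn, sprintf("dropped duplicated column '%s'",
                                colnames(features)[j]))
        break
      }
    }
  }
  for (w in warn) warning(w, call. = FALSE)
  X <- features[, keep, drop = FALSE]
  if (!ncol(X)) stop_("no usable feature columns")
  dat <- data.frame(.y = as.numeric(labels), X, check.names = FALSE)
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  scores <- as.numeric(stats::predict(fit, type = "link"))
  yo <- youden_optimal(scores, labels)
  structure(list(markers = colnames(X),
                 coefficients = stats::coef(fit),
                 auc = auc(scores, labels),
                 sensitivity = yo$sensitivity,
                 specificity = yo$specificity,
                 threshold = yo$threshold,
                 converged = fit$converged && !separated,
                 scores = scores,
                 warnings = warn),
            class = "combined_model")
}

#' @export
print.combined_model <- function(x, ...) {
  cat(sprintf("combined logistic model: %s\n",
              paste(x$markers, collapse = " + ")))
  cat(sprintf("  AUC %.4f, sens %.3f, spec %.3f%s\n", x$auc, x$sensitivity,
              x$specificity,
              if (x$converged) "" else "  [did not converge: separation]"))
  invisible(x)
}

#' Best small marker subset by combined-model AUC
#'
#' Fits a logistic model for every non-empty candidate subset of size up to
#' `max_size` and returns the model with the highest AUC; ties prefer the
#' smaller subset, then lexicographic marker order (subsets are enumerated
#' in that order, and only a strictly higher AUC displaces the incumbent).
#'
#' @param mat Feature matrix, samples x markers (already transformed).
#' @param labels Logical class labels.
#' @param candidates Candidate marker (column) names; at most 20.
#' @param max_size Maximum subset size (default 3).
#' @return The winning `combined_model`, with element `subset` recording the
#'   chosen markers.
#' @export
best_subset <- function(mat, labels, candidates = colnames(mat),
                        max_size = 3L) {
  stopifnot(length(candidates) >= 1, length(candidates) <= 20,
            all(candidates %in% colnames(mat)))
  candidates <- sort_c(unique(candidates))
  best <- NULL
  for (size in seq_len(min(max_size, length(candidates)))) {
    for (idx in utils::combn(length(candidates), size, simplify = FALSE)) {
      sub <- candidates[idx]
      model <- suppressWarnings(
        fit_logistic(mat[, sub, drop = FALSE], labels))
      if (is.null(best) || model$auc > best$auc) {
        model$subset <- sub
        best <- model
      }
    }
  }
  best
}
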