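#' Mean absolute prediction error in raw score units
#'
#' @param truth,predicted equal-length numeric score vectors
#' @return list with `mean` and `sd` of |truth - predicted|
#' @export
mean_prediction_error <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  e <- abs(truth - predicted)
  list(mean = mean(e), sd = if (length(e) > 1) sd(e) else 0)
}

#' Intraclass correlation ICC(3,k)
#'
#' Two-way mixed-effects, consistency, average-measures ICC with the
#' blocks as targets and the k raters (here expert and model, k = 2) as
#' fixed columns: ICC(3,k) = (MSR - MSE) / MSR from the two-way ANOVA
#' mean squares. Consistency ignores fixed rater offsets, so a constant
#' shift between raters still yields 1.
#'
#' @param ratings n x k numeric matrix (n targets, k raters)
#' @return ICC value, or NA when any rater column is constant (no
#'   between-target variance to apportion)
#' @export
icc_3k <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 targets and 2 raters")
  if (any(apply(ratings, 2, function(col) var(col) == 0))) return(NA_real_)
  grand <- mean(ratings)
  rm_ <- rowMeans(ratings); cm <- colMeans(ratings)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((ratings - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / msr
}

#' Random-labels permutation test
#'
#' Shuffles the true-label vector (preserving its multiset, hence the
#' score distribution) `n_permutations` times and recomputes the metric
#' against the fixed predictions. The p-value uses the add-one
#' convention, p = (1 + #extreme) / (n + 1), so it can never be 0.
#' Extremeness direction: `"greater"` for skill metrics (ICC, r), where
#' a null >= observed counts; `"less"` for error metrics.
#'
#' @param metric function(truth, predicted) -> scalar
#' @param truth,predicted score vectors
#' @param n_permutations number of shuffles
#' @param direction "greater" or "less"
#' @param seed RNG seed for the shuffles
#' @return list: `p`, `observed`, `null` (vector of permuted metric values)
#' @export
permutation_test <- function(metric, truth, predicted,
                             n_permutations = 1000,
                             direction = c("greater", "less"), seed = 42) {
  direction <- match.arg(direction)
  observed <- metric(truth, predicted)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(i)
      metric(sample(truth), predicted), numeric(1))
  })
  ok <- is.finite(null)
  extreme <- if (direction == "greater") sum(null[ok] >= observed)
             else sum(null[ok] <= observed)
  list(p = (1 + extreme) / (n_permutations + 1), observed = observed,
       null = null)
}

#' Mann-Whitney U condition contrasts with Bonferroni correction
#'
#' Two-sided Mann-Whitney U per feature per contrast; the exact
#' distribution is used for small tie-free groups (min n <= 8), the
#' tie-corrected normal approximation otherwise. p-values are multiplied
#' by `bonferroni_m` (default: the number of tests performed) and capped
#' at 1.
#'
#' @param features data.frame of block features plus a grouping column
#' @param feature_names features to test
#' @param group_col name of the condition column
#' @param contrasts list of length-2 character vectors (group a, group b)
#' @param bonferroni_m number of simultaneous tests for the correction
#' @return data.frame: feature, contrast, n_a, n_b, U, p, p_corrected
#' @export
condition_contrast <- function(features, feature_names, group_col = "condition",
                               contrasts, bonferroni_m = NULL) {
  rows <- NULL
  for (ct in contrasts) {
    a <- features[features[[group_col]] == ct[1], , drop = FALSE]
    b <- features[features[[group_col]] == ct[2], , drop = FALSE]
    if (!nrow(a) || !nrow(b)) {
      message("skipping contrast ", ct[1], " vs ", ct[2], ": empty group")
      next
    }
    for (f in feature_names) {
      x <- a[[f]][is.finite(a[[f]])]
      y <- b[[f]][is.finite(b[[f]])]
      if (length(x) < 1 || length(y) < 1) next
      use_exact <- min(length(x), length(y)) <= 8 &&
        !any(duplicated(c(x, y)))
      wt <- suppressWarnings(wilcox.test(x, y, exact = use_exact,
                                         correct = !use_exact))
      rows <- rbind(rows, data.frame(
        feature = f, contrast = paste(ct[1], "vs", ct[2]),
        n_a = length(x), n_b = length(y),
        U = unname(wt$statistic), p = wt$p.value,
        stringsAsFactors = FALSE))
    }
  }
  if (is.null(rows)) return(rows)
  m <- if (is.null(bonferroni_m)) nrow(rows) else bonferroni_m
  rows$p_corrected <- pmin(1, rows$p * m)
  rows
}

#' Mean-decrease-impurity feature importance
#'
#' Normalized Gini-impurity decrease per feature from the trained random
#' forest, summing to 1, sorted descending (ties broken by feature
#' order).
#'
#' @param model a trained `tap_model`
#' @return data.frame: feature, importance
#' @export
feature_importance <- function(model) {
  if (!inherits(model, "tap_model") || is.null(model$rf))
    stop("a trained tap_model is required")
  imp <- randomForest::importance(model$rf, type = 2)[, 1]
  tot <- sum(imp)
  if (tot > 0) imp <- imp / tot
  ord <- order(-imp, seq_along(imp))
  data.frame(feature = names(imp)[ord], importance = unname(imp[ord]),
             stringsAsFactors = FALSE)
}

#' Per-subject correlation between true and predicted scores
#'
#' Subjects whose true scores have no variance get an NA coefficient
#' (a correlation is undefined there) but stay in the table.
#'
#' @param truth,predicted score vectors
#' @param subject_id per-block subject identifiers
#' @return data.frame: subject_id, n, pearson_r (NA when undefined)
#' @export
per_subject_correlations <- function(truth, predicted, subject_id) {
  out <- lapply(split(seq_along(truth), subject_id), function(idx) {
    r <- if (var(truth[idx]) > 0 && var(predicted[idx]) > 0)
      cor(truth[idx], predicted[idx]) else NA_real_
    data.frame(n = length(idx), pearson_r = r)
  })
  res <- do.call(rbind, out)
  data.frame(subject_id = names(out), n = res$n, pearson_r = res$pearson_r,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full evaluation report
#'
#' The statistical battery for a set of predictions against expert
#' labels: mean absolute error (with sd), ICC(3,k), Pearson r, the
#' multiclass confusion matrix, random-labels permutation p-values for
#' the error and ICC, and the per-subject correlation table.
#'
#' @param truth,predicted score vectors
#' @param subject_id optional per-block subject identifiers
#' @param params evaluation parameter list (see [default_config()])
#' @return object of class `tap_eval`
#' @export
evaluate_predictions <- function(truth, predicted, subject_id = NULL,
                                 params = default_config()$evaluate) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  err <- mean_prediction_error(truth, predicted)
  icc <- icc_3k(cbind(truth, predicted))
  r <- if (var(truth) > 0 && var(predicted) > 0) cor(truth, predicted)
       else NA_real_
  cm <- table(true = factor(truth, levels = 0:4),
              predicted = factor(predicted, levels = 0:4))
  perm_err <- permutation_test(function(t, p) mean(abs(t - p)),
                               truth, predicted, params$n_permutations,
                               "less", seed = params$permutation_seed)
  perm_icc <- permutation_test(function(t, p) icc_3k(cbind(t, p)),
                               truth, predicted, params$n_permutations,
                               "greater",
                               seed = sub_seed(params$permutation_seed, 2))
  per_subj <- if (!is.null(subject_id))
    per_subject_correlations(truth, predicted, subject_id) else NULL
  structure(list(
    n = length(truth),
    mean_error = err$mean, sd_error = err$sd,
    icc3k = icc, pearson_r = r, confusion = cm,
    p_error = perm_err$p, p_icc = perm_icc$p,
    null_error_mean = mean(perm_err$null[is.finite(perm_err$null)]),
    per_subject = per_subj, alpha = params$alpha),
    class = "tap_eval")
}

#' @export
print.tap_eval <- function(x, ...) {
  cat(sprintf("<tap_eval> n = %d blocks\n", x$n))
  cat(sprintf("  mean error %.3f (sd %.3f), permutation p = %.4g\n",
              x$mean_error, x$sd_error, x$p_error))
  cat(sprintf("  ICC(3,k) %.3f, permutation p = %.4g; Pearson r %.3f\n",
              x$icc3k, x$p_icc, x$pearson_r))
  cat("  confusion matrix (true x predicted):\n")
  print(x$confusion[rowSums(x$confusion) > 0, colSums(x$confusion) > 0,
                    drop = FALSE])
  if (!is.null(x$per_subject)) {
    nd <- sum(is.na(x$per_subject$pearson_r))
    cat(sprintf("  per-subject r: %d subjects (%d undefined, constant scores)\n",
                nrow(x$per_subject), nd))
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report a `tap_eval`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_eval_report <- function(report, path) {
  out <- list(
    n = report$n, mean_error = report$mean_error, sd_error = report$sd_error,
    icc3k = report$icc3k, pearson_r = report$pearson_r,
    p_error = report$p_error, p_icc = report$p_icc,
    confusion = as.data.frame(report$confusion),
    per_subject = report$per_subject)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
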