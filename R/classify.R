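#' Subject-exclusive stratified development/holdout split
#'
#' Randomized search over whole-subject assignments until both sides'
#' per-class score proportions and site proportions each differ from the
#' full-cohort proportions by at most `split_tolerance`, and the block
#' count ratio is within `split_ratio_tolerance` of `split_ratio`.
#' Subject exclusivity is guaranteed by construction: a subject's blocks
#' all land on one side.
#'
#' @param labels label data.frame (source_id, block_index, subject_id,
#'   site, score, ...)
#' @param params classification parameter list (see [default_config()])
#' @return list: `dev_subjects`, `holdout_subjects`, `iterations`,
#'   `max_gap` (worst achieved class/site proportion gap)
#' @export
split_dataset <- function(labels, params = default_config()$classify) {
  subjects <- unique(labels$subject_id)
  if (length(subjects) < 2) stop("need at least 2 subjects to split")
  full_cls <- prop.table(table(factor(labels$score, levels = 0:4)))
  full_site <- prop.table(table(labels$site))
  n_total <- nrow(labels)
  blocks_per <- table(labels$subject_id)[subjects]
  target_hold <- round((1 - params$split_ratio) * length(subjects))
  gap_of <- function(idx) {
    sub <- labels[labels$subject_id %in% idx, ]
    g1 <- max(abs(prop.table(table(factor(sub$score, levels = 0:4))) - full_cls))
    g2 <- max(abs(prop.table(table(factor(sub$site, levels = names(full_site)))) -
                    full_site))
    max(g1, g2)
  }
  best <- Inf
  result <- NULL
  with_seed(params$split_seed, {
    for (it in seq_len(params$split_max_iter)) {
      nh <- max(1, target_hold + sample(-1:1, 1))
      hold <- sample(subjects, nh)
      dev <- setdiff(subjects, hold)
      ratio <- sum(blocks_per[dev]) / n_total
      if (abs(ratio - params$split_ratio) > params$split_ratio_tolerance) next
      g <- max(gap_of(hold), gap_of(dev))
      if (g < best) best <- g
      if (g <= params$split_tolerance) {
        result <- list(dev_subjects = sort(dev), holdout_subjects = sort(hold),
                       iterations = it, max_gap = g)
        break
      }
    }
  })
  if (is.null(result))
    stop(sprintf(
      "no admissible split in %d iterations; best proportion gap %.3f (tolerance %.3f)",
      params$split_max_iter, best, params$split_tolerance))
  result
}

#' Apply the hierarchical scoring rules to one feature vector
#'
#' Rule layer applied before the classifier: blocks with at least
#' `few_tap_cutoff` taps defer to the random forest; among few-tap blocks,
#' those with block RMS below the training 10th percentile of few-tap
#' blocks score 4 (barely any movement), those whose mean raise velocity
#' exceeds the training velocity threshold defer (few but well-performed
#' taps), and the remainder score 3.
#'
#' @param feature_vec one-row block feature data.frame
#' @param training_context list with `rms10` (10th-percentile RMS cut) and
#'   `vel_thr` (velocity override threshold), both derived from training
#'   data only
#' @param params classification parameter list
#' @return list: `action` ("score" or "defer"), `score` (NA when
#'   deferred), `rule` in none / few_taps_3 / few_taps_4 /
#'   velocity_override_deferred
#' @export
apply_rules <- function(feature_vec, training_context,
                        params = default_config()$classify) {
  if (is.null(training_context$rms10) || is.null(training_context$vel_thr))
    stop("training context with rms10 and vel_thr is required")
  if (feature_vec$n_taps >= params$few_tap_cutoff)
    return(list(action = "defer", score = NA_integer_, rule = "none"))
  rms <- feature_vec$rms_norm_block
  if (is.finite(rms) && rms < training_context$rms10)
    return(list(action = "score", score = 4L, rule = "few_taps_4"))
  rv <- feature_vec$raise_vel_mean
  if (is.finite(rv) && rv > training_context$vel_thr)
    return(list(action = "defer", score = NA_integer_,
                rule = "velocity_override_deferred"))
  list(action = "score", score = 3L, rule = "few_taps_3")
}

# median imputation parameters from training features only
impute_medians <- function(x) {
  vapply(x, function(col) {
    m <- median(col[is.finite(col)])
    if (is.finite(m)) m else 0
  }, numeric(1))
}

apply_imputation <- function(x, medians) {
  for (nm in names(medians)) {
    bad <- !is.finite(x[[nm]])
    if (any(bad)) x[[nm]][bad] <- medians[[nm]]
  }
  x
}

#' Train the tapping-score prediction model
#'
#' Derives the rule-layer thresholds and imputation medians from the
#' development data only, then fits a seeded random forest (1000 trees,
#' class-frequency-balanced weights) on the rule-deferred blocks with
#' scores 0-3 (score-4 blocks are excluded from classifier training).
#' Stratified cross-validation fold metrics are recorded.
#'
#' @param features block feature data.frame (rows match `labels`)
#' @param labels label data.frame with `score`
#' @param params classification parameter list
#' @return object of class `tap_model`: rf fit, rule context, imputation
#'   medians, feature order, fold metrics
#' @export
train_tap_model <- function(features, labels,
                            params = default_config()$classify) {
  stopifnot(nrow(features) == nrow(labels))
  keep <- labels$score %in% 0:3
  features <- features[keep, , drop = FALSE]
  score <- labels$score[keep]
  present <- sort(unique(score))
  if (!all(0:3 %in% present)) {
    cnt <- table(factor(score, levels = 0:3))
    stop("development data must contain all classes 0-3; counts: ",
         paste(names(cnt), cnt, sep = ":", collapse = " "))
  }
  cols <- classifier_columns()
  x <- features[cols]
  # rule context, training data only
  few <- features$n_taps < params$few_tap_cutoff
  rms10 <- if (any(few))
    quantile(features$rms_norm_block[few], params$score4_rms_percentile / 100,
             na.rm = TRUE, names = FALSE)
  else -Inf
  good <- score <= 1
  vel_thr <- if (any(good))
    median(features$raise_vel_mean[good], na.rm = TRUE) else Inf
  ctx <- list(rms10 = rms10, vel_thr = vel_thr)
  medians <- impute_medians(x)
  x_imp <- apply_imputation(x, medians)
  # classifier trains on rule-deferred blocks
  defer <- vapply(seq_len(nrow(features)), function(i)
    apply_rules(features[i, ], ctx, params)$action == "defer", logical(1))
  xd <- x_imp[defer, , drop = FALSE]
  yd <- factor(score[defer], levels = 0:3)
  if (!all(table(yd) >= 1)) {
    cnt <- table(yd)
    stop("rule-deferred training data lost a class; counts: ",
         paste(names(cnt), cnt, sep = ":", collapse = " "))
  }
  # class-frequency-balanced priors
  cw <- as.numeric(length(yd) / (nlevels(yd) * pmax(1, table(yd))))
  cvf <- params$cv_folds
  folds <- with_seed(sub_seed(params$rf_seed, 1), {
    # score-stratified fold assignment
    fa <- integer(length(yd))
    for (cl in levels(yd)) {
      idx <- which(yd == cl)
      fa[idx] <- sample(rep_len(seq_len(cvf), length(idx)))
    }
    fa
  })
  fold_metrics <- NULL
  for (f in seq_len(cvf)) {
    tr <- folds != f
    if (length(unique(yd[tr])) < 4 || !any(!tr)) next
    fit <- with_seed(sub_seed(params$rf_seed, 10 + f),
      randomForest::randomForest(
        xd[tr, , drop = FALSE], droplevels(yd[tr]),
        ntree = max(100, params$rf_trees %/% 4)))
    pr <- as.integer(as.character(predict(fit, xd[!tr, , drop = FALSE])))
    tru <- as.integer(as.character(yd[!tr]))
    fold_metrics <- rbind(fold_metrics, data.frame(
      fold = f, n = sum(!tr), accuracy = mean(pr == tru),
      mean_abs_error = mean(abs(pr - tru))))
  }
  rf <- with_seed(params$rf_seed,
    randomForest::randomForest(xd, yd, ntree = params$rf_trees,
                               classwt = cw, importance = FALSE))
  structure(list(rf = rf, context = ctx, medians = medians,
                 feature_names = cols, fold_metrics = fold_metrics,
                 params = params, n_train = nrow(xd)),
            class = "tap_model")
}

#' @export
print.tap_model <- function(x, ...) {
  cat(sprintf("<tap_model> RF %d trees on %d blocks, %d features\n",
              x$rf$ntree, x$n_train, length(x$feature_names)))
  cat(sprintf("  rules: few-tap RMS 10th pct = %.4g, velocity override > %.3g m/s\n",
              x$context$rms10, x$context$vel_thr))
  if (!is.null(x$fold_metrics))
    cat(sprintf("  CV mean abs error: %.3f\n", mean(x$fold_metrics$mean_abs_error)))
  invisible(x)
}

#' Predict tapping scores for block feature vectors
#'
#' Applies the rule layer first; rule-deferred blocks are scored by the
#' random forest into 0-3. Every block receives exactly one path, recorded
#' in `rule_applied`. Class posteriors (columns `prob_0`..`prob_3`) are
#' reported for classifier-scored blocks and NA for rule-scored ones.
#'
#' @param object a trained [train_tap_model()] model
#' @param features block feature data.frame (must contain the training
#'   feature columns)
#' @param ... unused
#' @return data.frame: source_id, block_index, predicted_score,
#'   rule_applied, prob_0..prob_3
#' @export
predict.tap_model <- function(object, features, ...) {
  miss <- setdiff(object$feature_names, names(features))
  if (length(miss))
    stop("feature columns missing (order contract violated): ",
         paste(miss, collapse = ", "))
  n <- nrow(features)
  x <- apply_imputation(features[object$feature_names], object$medians)
  score <- integer(n); rule <- character(n)
  prob <- matrix(NA_real_, n, 4, dimnames = list(NULL, paste0("prob_", 0:3)))
  defer_idx <- integer(0)
  for (i in seq_len(n)) {
    r <- apply_rules(features[i, ], object$context, object$params)
    rule[i] <- r$rule
    if (r$action == "score") score[i] <- r$score else defer_idx <- c(defer_idx, i)
  }
  if (length(defer_idx)) {
    pr <- predict(object$rf, x[defer_idx, , drop = FALSE], type = "prob")
    score[defer_idx] <- as.integer(colnames(pr)[max.col(pr, ties.method = "first")])
    prob[defer_idx, ] <- pr
  }
  cbind(data.frame(source_id = features$source_id,
                   block_index = features$block_index,
                   predicted_score = score, rule_applied = rule,
                   stringsAsFactors = FALSE),
        as.data.frame(prob))
}

#' Save / load a trained model
#'
#' @param model a `tap_model`
#' @param path file path
#' @return `path` invisibly / the model
#' @export
save_tap_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_tap_model
#' @export
load_tap_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "tap_model")) stop("not a tap_model file: ", path)
  m
}
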