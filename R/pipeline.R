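#' Extract features from one preprocessed trace
#'
#' Preprocess a raw trace, detect blocks and taps, and compute the block
#' feature vectors and per-tap long table.
#'
#' @param trace raw [acc_trace()]
#' @param config pipeline configuration
#' @return list: `features` (data.frame, one row per detected block),
#'   `tap_table` (long per-tap data.frame), `blocks`, `report`
#' @export
extract_trace_features <- function(trace, config = default_config()) {
  pp <- preprocess_trace(trace, config)
  blocks <- detect_blocks(pp$svm, config$blocks)
  feats <- NULL; tap_long <- NULL
  if (nrow(blocks)) {
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      idx <- b$start:(b$end - 1)
      sv <- pp$svm$values[idx]
      bd <- pp$trace$data[idx, , drop = FALSE]
      imp <- detect_impacts(sv, pp$svm$rate, config$taps)
      taps <- delineate_taps(imp, bd, pp$svm$rate, config$taps)
      fv <- extract_block_features(taps, bd, sv, pp$svm$rate,
                                   config$features,
                                   source_id = trace$source_id,
                                   block_index = b$block_index)
      tt <- attr(fv, "tap_table")
      if (nrow(tt)) {
        long <- data.frame(source_id = trace$source_id,
                           block_index = b$block_index,
                           tap_index = rep(tt$tap_index, length(TAP_FEATURES)),
                           feature = rep(TAP_FEATURES, each = nrow(tt)),
                           value = unlist(tt[TAP_FEATURES], use.names = FALSE))
        tap_long <- rbind(tap_long, long)
      }
      attr(fv, "tap_table") <- NULL
      feats <- rbind(feats, fv)
    }
  }
  list(features = feats, tap_table = tap_long, blocks = blocks,
       report = pp$report, svm = pp$svm)
}

#' Batch feature extraction
#'
#' Processes every input independently; a failing input is reported in
#' the manifest and skipped, never aborting the batch.
#'
#' @param inputs character vector of file paths, or a list of
#'   [acc_trace()] objects
#' @param config pipeline configuration
#' @param rate sampling rate passed to [read_trace()] for 3-column files
#' @param out_dir optional directory: features/tap CSVs and inspection
#'   plots are written there
#' @param plots emit per-trace block-detection PNGs (requires `out_dir`)
#' @return list: `features`, `tap_table`, `manifest` (one row per input
#'   with terminal status)
#' @export
run_extract <- function(inputs, config = default_config(), rate = NULL,
                        out_dir = NULL, plots = FALSE) {
  if (!length(inputs)) stop("no inputs given")
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  feats <- NULL; taps <- NULL; manifest <- NULL
  for (i in seq_along(inputs)) {
    inp <- if (is.list(inputs) && !inherits(inputs, "acc_trace"))
      inputs[[i]] else inputs[i]
    id <- if (inherits(inp, "acc_trace")) inp$source_id else basename(inp)
    res <- tryCatch({
      tr <- if (inherits(inp, "acc_trace")) inp else read_trace(inp, rate = rate)
      ex <- extract_trace_features(tr, config)
      if (plots && !is.null(out_dir) && !is.null(ex$blocks))
        plot_block_detection(ex$svm, ex$blocks,
                             file.path(out_dir, paste0(id, "_blocks.png")),
                             title = id)
      ex
    }, error = function(e) e)
    if (inherits(res, "error")) {
      warning("input '", id, "' failed: ", conditionMessage(res))
      manifest <- rbind(manifest, data.frame(
        input = id, status = "failed", n_blocks = NA_integer_,
        n_taps = NA_integer_, message = conditionMessage(res),
        stringsAsFactors = FALSE))
    } else {
      feats <- rbind(feats, res$features)
      taps <- rbind(taps, res$tap_table)
      manifest <- rbind(manifest, data.frame(
        input = id, status = "ok",
        n_blocks = if (is.null(res$features)) 0L else nrow(res$features),
        n_taps = if (is.null(res$features)) 0L else sum(res$features$n_taps),
        message = "", stringsAsFactors = FALSE))
    }
  }
  if (all(manifest$status == "failed")) stop("all inputs failed")
  if (!is.null(out_dir) && !is.null(feats))
    write_features(feats, file.path(out_dir, "features.csv"), taps)
  list(features = feats, tap_table = taps, manifest = manifest)
}

#' Train a score model from features and labels
#'
#' Splits the cohort subject-exclusively (stratified by score and site),
#' trains on the development side, and returns the model with a training
#' report.
#'
#' @param features block feature data.frame
#' @param labels label data.frame (see [read_labels()])
#' @param config pipeline configuration
#' @return list: `model`, `split`, `report` (split composition and fold
#'   metrics), `dev`, `holdout` (merged feature+label frames)
#' @export
run_train <- function(features, labels, config = default_config()) {
  merged <- merge(features, labels, by = c("source_id", "block_index"))
  dropped <- nrow(features) - nrow(merged)
  if (dropped > 0)
    warning(dropped, " block(s) without labels excluded from training")
  split <- split_dataset(merged, config$classify)
  dev <- merged[merged$subject_id %in% split$dev_subjects, ]
  hold <- merged[merged$subject_id %in% split$holdout_subjects, ]
  model <- train_tap_model(dev[feature_columns()], dev, config$classify)
  report <- list(
    n_dev = nrow(dev), n_holdout = nrow(hold),
    n_dropped = dropped,
    dev_class_counts = table(factor(dev$score, levels = 0:4)),
    holdout_class_counts = table(factor(hold$score, levels = 0:4)),
    split_iterations = split$iterations, split_gap = split$max_gap,
    fold_metrics = model$fold_metrics)
  list(model = model, split = split, report = report, dev = dev,
       holdout = hold)
}

#' Predict scores and (optionally) evaluate them
#'
#' @param model a trained `tap_model`
#' @param features block feature data.frame
#' @param labels optional label data.frame; when given, the evaluation
#'   battery runs on the labelled blocks
#' @param config pipeline configuration
#' @return list: `predictions` (always), `evaluation` (`tap_eval` or NULL)
#' @export
run_predict_and_eval <- function(model, features, labels = NULL,
                                 config = default_config()) {
  preds <- predict(model, features)
  evaluation <- NULL
  if (!is.null(labels)) {
    merged <- merge(preds, labels, by = c("source_id", "block_index"))
    if (nrow(merged))
      evaluation <- evaluate_predictions(merged$score, merged$predicted_score,
                                         merged$subject_id, config$evaluate)
  }
  list(predictions = preds, evaluation = evaluation)
}
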