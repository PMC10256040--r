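#' Default pipeline configuration
#'
#' Every numeric threshold used anywhere in the pipeline, in one nested
#' list. Values follow the published tapping-assessment defaults where one
#' exists (250 Hz target rate, 2-48 Hz band, 10 x 99th-percentile artifact
#' rule, eight 125 ms segments per second, 0.5 x sd activity threshold,
#' 30% segment activity, 2 s merge gap, 0.32 s minimum block, 20%-of-max
#' peak thresholds, 166 ms refractory, <9 taps rule, 10th-percentile RMS
#' rule, 75/25 subject-stratified split, 1000-tree random forest, n = 1000
#' permutations); the remainder are package choices documented in the
#' methods vignette.
#'
#' @return nested named list of parameters
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$preprocess$band_high
default_config <- function() {
  list(
    seed = 42,
    preprocess = list(
      target_rate = 250,
      band_low = 2,
      band_high = 48,
      filter_order = 4,
      notch_freq = 50,
      notch_q = 35,
      artifact_factor = 10,
      artifact_percentile = 99,
      ms2_detect_low = 5,
      ms2_detect_high = 15,
      flip_ratio = 1.5
    ),
    blocks = list(
      segment_len = 0.125,
      window_segments = 10,
      activity_threshold_factor = 0.5,
      activity_floor_mult = 2.5,
      segment_active_pct = 30,
      min_active_segments = 3,
      merge_gap = 2.0,
      min_block_len = 0.32
    ),
    taps = list(
      peak_height_frac = 0.20,
      diff_frac = 0.20,
      min_separation = 0.166,
      raise_search = 0.5
    ),
    features = list(
      entropy_bins = 64,
      impact_rms_halfwidth = 0.040,
      first_n_taps = 15
    ),
    classify = list(
      few_tap_cutoff = 9,
      score4_rms_percentile = 10,
      rf_trees = 1000,
      rf_seed = 42,
      cv_folds = 5,
      split_ratio = 0.75,
      split_seed = 42,
      split_tolerance = 0.03,
      split_ratio_tolerance = 0.07,
      split_max_iter = 100000
    ),
    evaluate = list(
      n_permutations = 1000,
      alpha = 0.05,
      permutation_seed = 42
    )
  )
}

# flatten a nested list to dotted keys (depth 2 is all we use)
flatten_config <- function(cfg) {
  out <- list()
  for (nm in names(cfg)) {
    v <- cfg[[nm]]
    if (is.list(v)) {
      for (k in names(v)) out[[paste(nm, k, sep = ".")]] <- v[[k]]
    } else out[[nm]] <- v
  }
  out
}

unflatten_config <- function(flat) {
  out <- list()
  for (key in names(flat)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1) {
      out[[parts]] <- flat[[key]]
    } else {
      if (is.null(out[[parts[1]]])) out[[parts[1]]] <- list()
      out[[parts[1]]][[parts[2]]] <- flat[[key]]
    }
  }
  out
}

#' Write a configuration to a flat YAML file
#'
#' Keys are dotted (\code{section.parameter}) so the file stays a flat
#' key: value enumeration of every default.
#'
#' @param cfg nested configuration list (see [default_config()])
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(flatten_config(cfg), path)
  invisible(path)
}

#' Read a configuration file, merged over the defaults
#'
#' @param path YAML file with dotted flat keys as written by
#'   [write_config()]; missing keys keep their default values.
#' @return nested configuration list
#' @export
read_config <- function(path) {
  flat <- yaml::read_yaml(path)
  user <- unflatten_config(flat)
  cfg <- default_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]])) {
      for (k in names(user[[nm]])) cfg[[nm]][[k]] <- user[[nm]][[k]]
    } else cfg[[nm]] <- user[[nm]]
  }
  cfg
}
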