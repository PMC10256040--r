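#' Shannon entropy of an amplitude histogram
#'
#' Values are binned into `bins` equal-width bins over their range;
#' entropy is -sum(p log2 p) over occupied bins, in bits (a.u.). A
#' constant sequence occupies one bin and scores 0.
#'
#' @param values numeric vector (>= 1 finite value)
#' @param bins number of histogram bins (>= 2)
#' @return entropy in bits, or NA for empty input
#' @export
shannon_entropy <- function(values, bins = 64) {
  values <- values[is.finite(values)]
  if (!length(values)) return(NA_real_)
  rng <- range(values)
  if (rng[1] == rng[2]) return(0)
  idx <- pmin(bins, floor((values - rng[1]) / (rng[2] - rng[1]) * bins) + 1)
  p <- tabulate(idx, nbins = bins) / length(values)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Duration-normalized root mean square
#'
#' sqrt(mean(values^2)) divided by the duration in seconds; amplitude and
#' brevity both push the value up, mirroring the clinical demand for
#' "large and fast" taps.
#'
#' @param values numeric vector
#' @param duration_s duration in seconds (> 0)
#' @return normalized RMS in g/s terms, NA for empty input
#' @export
rms_norm <- function(values, duration_s) {
  values <- values[is.finite(values)]
  if (!length(values)) return(NA_real_)
  stopifnot(duration_s > 0)
  sqrt(mean(values^2)) / duration_s
}

#' Peak finger-raising velocity
#'
#' Cumulative trapezoidal integral of the raise-window acceleration
#' (converted from g to m/s^2), starting from zero; the feature is the
#' maximum of the running integral, i.e. the peak upward velocity reached
#' while the finger opens.
#'
#' @param accel_g acceleration samples over the raise window, in g
#' @param rate sampling rate in Hz
#' @return peak velocity in m/s, NA for fewer than 2 samples
#' @export
raise_velocity <- function(accel_g, rate = 250) {
  if (length(accel_g) < 2) return(NA_real_)
  v <- pracma::cumtrapz(accel_g * GRAVITY_MS2)[, 1] / rate
  max(c(0, v))
}

#' Jerkiness as directional-change rate
#'
#' Counts strict sign changes in the first difference of the signal and
#' divides by the duration: the rate at which acceleration changes
#' direction. (The count-rate reading of "jerkiness" is used; it is not a
#' third derivative in m/s^3.)
#'
#' @param values numeric vector (>= 3 samples)
#' @param duration_s duration in seconds
#' @return directional changes per second, NA for short input
#' @export
jerkiness <- function(values, duration_s) {
  if (length(values) < 3) return(NA_real_)
  d <- diff(values)
  d <- d[d != 0]
  if (length(d) < 2) return(0 / duration_s)
  sum(diff(sign(d)) != 0) / duration_s
}

#' Linear decrement slope of a per-tap feature
#'
#' Ordinary-least-squares slope of feature value against tap start time;
#' the within-block decrement. For entropy and inter-tap interval the
#' absolute slope is used (variability direction is not meaningful).
#'
#' @param values per-tap feature values
#' @param times tap start times in seconds
#' @param absolute take the absolute slope
#' @return slope per second, NA when fewer than 2 valid points
#' @export
decrement_slope <- function(values, times, absolute = FALSE) {
  ok <- is.finite(values) & is.finite(times)
  if (sum(ok) < 2) return(NA_real_)
  x <- times[ok]; y <- values[ok]
  if (var(x) == 0) return(NA_real_)
  s <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (absolute) abs(s) else s
}

#' Coefficient of variation (population sd / mean)
#'
#' @param values numeric vector
#' @return sd/mean over finite values, NA when fewer than 2 values or
#'   zero mean
#' @export
coef_var <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 2) return(NA_real_)
  m <- mean(values)
  if (m == 0) return(NA_real_)
  sqrt(mean((values - m)^2)) / m
}

# per-tap kinematic feature names, in fixed order
TAP_FEATURES <- c("iti", "tap_rms", "impact_rms", "raise_vel", "jerk", "entropy")
# features aggregated with the absolute decrement
ABS_DECREMENT <- c("iti", "entropy")

#' Fixed column order of the block feature vector
#'
#' @return character vector of column names, the contract between feature
#'   extraction, file output and the classifier
#' @export
feature_columns <- function() {
  c("source_id", "block_index", "n_taps", "n_taps_used", "duration_s",
    "tap_freq", "tap_dur_mean", "rms_norm_block", "entropy_block",
    "jerkiness_block",
    as.vector(t(outer(TAP_FEATURES, c("mean", "cv", "decr"),
                      function(f, s) paste(f, s, sep = "_")))))
}

#' Numeric feature columns used by the classifier
#' @return character vector (everything except provenance columns)
#' @export
classifier_columns <- function() {
  setdiff(feature_columns(), c("source_id", "block_index"))
}

#' Per-tap kinematic feature table for one block
#'
#' @param taps tap table from [delineate_taps()] (indices relative to the
#'   block start)
#' @param block_data matrix of the block's tri-axial filtered samples
#' @param svm_block numeric vector of the block's SVM samples
#' @param rate sampling rate in Hz
#' @param params feature parameter list (see [default_config()])
#' @return data.frame with one row per tap: `tap_index` (0-based),
#'   `t_start` (s, block-relative) and one column per feature in
#'   `TAP_FEATURES` order
#' @export
tap_features <- function(taps, block_data, svm_block, rate = 250,
                         params = default_config()$features) {
  nt <- nrow(taps)
  if (!nt)
    return(data.frame(tap_index = integer(0), t_start = numeric(0),
                      iti = numeric(0), tap_rms = numeric(0),
                      impact_rms = numeric(0), raise_vel = numeric(0),
                      jerk = numeric(0), entropy = numeric(0)))
  ax <- which.max(apply(block_data, 2, var))
  hw <- round(params$impact_rms_halfwidth * rate)
  n <- length(svm_block)
  rows <- lapply(seq_len(nt), function(k) {
    tp <- taps[k, ]
    dur <- (tp$tap_end - tp$tap_start) / rate
    sl <- svm_block[tp$tap_start:(tp$tap_end - 1)]
    iwin <- svm_block[max(1, tp$impact - hw):min(n, tp$impact + hw)]
    rv <- if (isTRUE(tp$valid_raise))
      raise_velocity(block_data[tp$raise_start:(tp$raise_end - 1), ax], rate)
    else NA_real_
    data.frame(
      tap_index = k - 1L,
      t_start = (tp$tap_start - 1) / rate,
      iti = if (k < nt) (taps$impact[k + 1] - taps$impact[k]) / rate else NA_real_,
      tap_rms = rms_norm(sl, dur),
      impact_rms = sqrt(mean(iwin^2)),
      raise_vel = rv,
      jerk = jerkiness(sl, dur),
      entropy = shannon_entropy(sl, params$entropy_bins))
  })
  do.call(rbind, rows)
}

#' Block feature vector
#'
#' Computes the full fixed-order kinematic feature vector for one block:
#' block-level features over the whole block span, per-tap features over
#' the first `first_n_taps` taps (or all), and their mean / coefficient
#' of variation / decrement aggregates. `n_taps` always counts ALL
#' detected taps (the few-taps classification rule depends on it).
#' Degenerate blocks produce NA markers, never errors.
#'
#' @param taps tap table from [delineate_taps()]
#' @param block_data matrix of block tri-axial filtered samples
#' @param svm_block numeric vector of block SVM samples
#' @param rate sampling rate in Hz
#' @param params feature parameter list
#' @param source_id,block_index provenance
#' @return one-row data.frame in [feature_columns()] order, with the
#'   per-tap table attached as attribute `"tap_table"`
#' @export
extract_block_features <- function(taps, block_data, svm_block, rate = 250,
                                   params = default_config()$features,
                                   source_id = "trace", block_index = 0L) {
  dur <- length(svm_block) / rate
  n_all <- nrow(taps)
  n_used <- if (is.finite(params$first_n_taps))
    min(n_all, params$first_n_taps) else n_all
  tf_all <- tap_features(taps, block_data, svm_block, rate, params)
  tf <- head(tf_all, n_used)
  out <- data.frame(
    source_id = source_id, block_index = block_index,
    n_taps = n_all, n_taps_used = n_used, duration_s = dur,
    tap_freq = n_all / dur,
    tap_dur_mean = if (n_used)
      mean((head(taps$tap_end, n_used) - head(taps$tap_start, n_used)) / rate)
    else NA_real_,
    rms_norm_block = rms_norm(svm_block, dur),
    entropy_block = shannon_entropy(svm_block, params$entropy_bins),
    jerkiness_block = jerkiness(svm_block, dur),
    stringsAsFactors = FALSE)
  for (f in TAP_FEATURES) {
    v <- tf[[f]]
    fin <- v[is.finite(v)]
    out[[paste0(f, "_mean")]] <- if (length(fin)) mean(fin) else NA_real_
    out[[paste0(f, "_cv")]] <- coef_var(v)
    out[[paste0(f, "_decr")]] <- decrement_slope(v, tf$t_start,
                                                 absolute = f %in% ABS_DECREMENT)
  }
  out <- out[feature_columns()]
  attr(out, "tap_table") <- tf_all
  out
}
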