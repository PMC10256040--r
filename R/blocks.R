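# Segment boundaries tiling the series into 125 ms pieces. At 250 Hz a
# segment is 31.25 samples; alternating 31/32-sample segments make eight
# of them tile one second exactly. Returns half-open [start, end) pairs,
# 1-based starts; the trailing partial segment is dropped.
segment_bounds <- function(n, rate, segment_len) {
  spseg <- rate * segment_len                 # samples per segment (may be fractional)
  nseg <- floor(n / spseg)
  if (nseg < 1) return(matrix(numeric(0), ncol = 2))
  edges <- floor((0:nseg) * spseg)
  cbind(start = edges[-length(edges)] + 1, end = edges[-1] + 1)
}

# activity threshold for an SVM series: 0.5 x sd, guarded by a noise
# floor so a tap-free trace cannot become globally "active". The floor
# self-calibrates to the sensor noise envelope: the SVM median is
# rest-dominated in protocol-compliant recordings (>= 50% rest).
activity_threshold <- function(svm, params) {
  max(params$activity_threshold_factor * sd(svm$values),
      params$activity_floor_mult * median(svm$values))
}

#' Per-segment activity percentage
#'
#' Splits the SVM series into non-overlapping 125 ms segments (eight per
#' second, realized as alternating 31/32-sample windows at 250 Hz) and
#' returns, per segment, the percentage of samples exceeding the activity
#' threshold: 0.5 x the sd of the whole SVM series, floored at
#' `activity_floor_mult` x the SVM median (a rest-dominated noise-envelope
#' estimate, so tap-free traces stay inactive).
#'
#' @param svm an [svm_series()] at 250 Hz
#' @param params block-detection parameter list
#' @return numeric vector of activity percentages in \[0, 100\]
#' @export
segment_activity <- function(svm, params = default_config()$blocks) {
  b <- segment_bounds(length(svm$values), svm$rate, params$segment_len)
  if (!nrow(b)) return(numeric(0))
  thr <- activity_threshold(svm, params)
  vapply(seq_len(nrow(b)), function(i) {
    seg <- svm$values[b[i, 1]:(b[i, 2] - 1)]
    100 * mean(seg > thr)
  }, numeric(1))
}

#' Label 1.25 s windows as active
#'
#' Groups consecutive runs of 10 segments into non-overlapping windows;
#' a window is active when more than two of its segments (i.e. at least
#' three) have an activity percentage above `segment_active_pct`.
#'
#' @param activity per-segment activity percentages
#' @param params block-detection parameter list
#' @return logical vector, one per complete window
#' @export
label_active_windows <- function(activity, params = default_config()$blocks) {
  w <- params$window_segments
  nw <- floor(length(activity) / w)
  if (nw < 1) return(logical(0))
  vapply(seq_len(nw), function(i) {
    seg <- activity[((i - 1) * w + 1):(i * w)]
    sum(seg > params$segment_active_pct) >= params$min_active_segments
  }, logical(1))
}

#' Merge nearby active windows and drop short ones
#'
#' Converts maximal runs of active windows to sample intervals, merges
#' intervals separated by less than `merge_gap` seconds (to fixpoint),
#' then discards intervals shorter than `min_block_len` seconds.
#'
#' @param windows logical active-window labels
#' @param rate sampling rate in Hz
#' @param n_total total samples in the trace (caps the last block)
#' @param params block-detection parameter list
#' @return data.frame of disjoint ordered blocks with 1-based half-open
#'   sample columns `start`, `end` and `duration` in seconds
#' @export
merge_and_filter <- function(windows, rate, n_total,
                             params = default_config()$blocks) {
  empty <- data.frame(start = integer(0), end = integer(0), duration = numeric(0))
  if (!length(windows) || !any(windows)) return(empty)
  wlen <- params$window_segments * params$segment_len * rate   # samples per window
  r <- rle(windows)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  act <- which(r$values)
  iv <- cbind(floor((starts[act] - 1) * wlen) + 1,
              pmin(floor(ends[act] * wlen) + 1, n_total + 1))
  # merge runs closer than merge_gap (single left-to-right pass reaches
  # the fixpoint on sorted disjoint intervals)
  gap <- params$merge_gap * rate
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1) {
    for (i in 2:nrow(iv)) {
      last <- nrow(merged)
      if (iv[i, 1] - merged[last, 2] < gap) merged[last, 2] <- iv[i, 2]
      else merged <- rbind(merged, iv[i, ])
    }
  }
  dur <- (merged[, 2] - merged[, 1]) / rate
  keep <- dur >= params$min_block_len
  if (!any(keep)) return(empty)
  data.frame(start = merged[keep, 1], end = merged[keep, 2],
             duration = dur[keep])
}

# refine window-quantized block bounds at segment (125 ms) resolution:
# walk outward over the per-segment activity, bridging inactive runs
# shorter than merge_gap exactly as the window-level merge does
refine_block_bounds <- function(blocks, activity, rate, n_total, params) {
  if (!nrow(blocks)) return(blocks)
  sb <- segment_bounds(n_total, rate, params$segment_len)
  nseg <- nrow(sb)
  active_seg <- activity > params$segment_active_pct
  bridge <- ceiling(params$merge_gap / params$segment_len)
  seg_of <- function(sample) min(nseg, max(1L, findInterval(sample, sb[, 1])))
  for (i in seq_len(nrow(blocks))) {
    # forward from the block end
    lim <- if (i < nrow(blocks)) seg_of(blocks$start[i + 1]) - 1L else nseg
    s0 <- seg_of(blocks$end[i] - 1)
    last_active <- NA_integer_
    gap <- 0
    k <- s0 + 1L
    while (k <= lim) {
      if (active_seg[k]) { last_active <- k; gap <- 0 } else gap <- gap + 1
      if (gap >= bridge) break
      k <- k + 1L
    }
    if (!is.na(last_active)) blocks$end[i] <- sb[last_active, 2]
    # backward from the block start
    lim <- if (i > 1) seg_of(blocks$end[i - 1]) + 1 else 1
    s0 <- seg_of(blocks$start[i])
    first_active <- NA_integer_
    gap <- 0
    k <- s0 - 1
    while (k >= lim) {
      if (active_seg[k]) { first_active <- k; gap <- 0 } else gap <- gap + 1
      if (gap >= bridge) break
      k <- k - 1
    }
    if (!is.na(first_active)) blocks$start[i] <- sb[first_active, 1]
  }
  blocks$duration <- (blocks$end - blocks$start) / rate
  blocks
}

#' Detect active tapping blocks in an SVM series
#'
#' Composition of [segment_activity()], [label_active_windows()] and
#' [merge_and_filter()], followed by boundary refinement at segment
#' (125 ms) resolution: block edges are extended over adjacent active
#' segments, bridging inactive runs shorter than the merge gap, so
#' boundaries are not quantized to the 1.25 s window grid.
#'
#' @param svm an [svm_series()] at 250 Hz
#' @param params block-detection parameter list
#' @return data.frame of blocks (`start`, `end` half-open 1-based sample
#'   interval, `duration` s, `block_index` 0-based)
#' @export
detect_blocks <- function(svm, params = default_config()$blocks) {
  act <- segment_activity(svm, params)
  win <- label_active_windows(act, params)
  blocks <- merge_and_filter(win, svm$rate, length(svm$values), params)
  blocks <- refine_block_bounds(blocks, act, svm$rate, length(svm$values),
                                params)
  if (nrow(blocks)) blocks$block_index <- seq_len(nrow(blocks)) - 1L
  else blocks$block_index <- integer(0)
  blocks
}
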