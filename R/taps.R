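#' Detect tap impact peaks within a block
#'
#' Finds the sharp index-finger-on-thumb impact peaks in an SVM slice.
#' Three criteria, applied in order: (1) local maxima higher than
#' `peak_height_frac` x the block SVM maximum; (2) the first difference of
#' the SVM must exceed `diff_frac` x its maximum somewhere in the
#' half-refractory window before the peak, and fall below `diff_frac` x
#' its minimum in the window after it (steep rise and steep fall); (3) a
#' refractory period of `min_separation` seconds, resolved by keeping the
#' higher of two competing peaks.
#'
#' @param svm_block numeric vector: SVM samples of one block
#' @param rate sampling rate in Hz
#' @param params tap-detection parameter list (see [default_config()])
#' @return sorted integer vector of impact sample indices (1-based,
#'   relative to the start of `svm_block`)
#' @export
detect_impacts <- function(svm_block, rate = 250,
                           params = default_config()$taps) {
  n <- length(svm_block)
  refrac <- ceiling(params$min_separation * rate)
  if (n <= refrac) return(integer(0))
  height_thr <- params$peak_height_frac * max(svm_block)
  # local maxima above the height threshold (plateaus take the first sample)
  d0 <- diff(svm_block)
  cand <- which(d0[-length(d0)] > 0 & d0[-1] <= 0) + 1L
  cand <- cand[svm_block[cand] > height_thr]
  if (!length(cand)) return(integer(0))
  # differential criterion: steep rise before, steep fall after
  dthr_up <- params$diff_frac * max(d0)
  dthr_dn <- params$diff_frac * min(d0)
  half <- max(1L, floor(refrac / 2))
  ok <- vapply(cand, function(i) {
    pre <- d0[max(1L, i - half):(i - 1L)]
    post <- d0[i:min(length(d0), i + half - 1L)]
    any(pre > dthr_up) && any(post < dthr_dn)
  }, logical(1))
  cand <- cand[ok]
  if (!length(cand)) return(integer(0))
  # refractory resolution: greedily keep higher peaks
  ord <- cand[order(-svm_block[cand], cand)]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(kept - i) >= refrac)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Delineate tap intervals and raise windows
#'
#' A tap spans impact-to-impact (the last tap ends at the block end). The
#' raise window -- the index finger opening after an impact -- starts at
#' the first positive excursion of the dominant-variance axis after the
#' impact transient has returned to zero, and ends at that excursion's
#' first zero-crossing (the end of the first sinusoid), capped at
#' `raise_search` seconds.
#'
#' @param impacts impact sample indices relative to the block start
#' @param block_data matrix of the block's tri-axial (filtered) samples
#' @param rate sampling rate in Hz
#' @param params tap-detection parameter list
#' @return data.frame, one row per tap: `impact`, half-open `tap_start`,
#'   `tap_end`, `raise_start`, `raise_end` (NA when invalid),
#'   `valid_raise`; indices 1-based relative to the block start
#' @export
delineate_taps <- function(impacts, block_data, rate = 250,
                           params = default_config()$taps) {
  if (!length(impacts))
    return(data.frame(impact = integer(0), tap_start = integer(0),
                      tap_end = integer(0), raise_start = integer(0),
                      raise_end = integer(0), valid_raise = logical(0)))
  n <- nrow(block_data)
  ax <- which.max(apply(block_data, 2, var))
  sig <- block_data[, ax]
  cap <- round(params$raise_search * rate)
  ends <- c(impacts[-1], n + 1L)
  res <- lapply(seq_along(impacts), function(k) {
    i0 <- impacts[k]
    lim <- min(i0 + cap, ends[k] - 1L, n)
    rs <- NA_integer_; re <- NA_integer_
    j <- i0
    # step over the (positive) impact transient
    while (j <= lim && sig[j] > 0) j <- j + 1L
    # onset of the positive raise excursion
    while (j <= lim && sig[j] <= 0) j <- j + 1L
    if (j <= lim) {
      rs <- j
      while (j <= lim && sig[j] > 0) j <- j + 1L
      if (j <= lim && j > rs + 1L) re <- j
    }
    valid <- !is.na(rs) && !is.na(re)
    data.frame(impact = i0, tap_start = i0, tap_end = ends[k],
               raise_start = if (valid) rs else NA_integer_,
               raise_end = if (valid) re else NA_integer_,
               valid_raise = valid)
  })
  do.call(rbind, res)
}
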