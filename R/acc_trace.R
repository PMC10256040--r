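#' Construct a tri-axial acceleration trace
#'
#' The raw currency of the pipeline: a uniformly sampled tri-axial
#' accelerometer series with sampling-rate and unit metadata. Values are
#' in g once preprocessed; raw traces may arrive in m/s^2 (detected and
#' rescaled by [standardize_units()]).
#'
#' @param data numeric matrix with columns x, y, z (one row per sample)
#' @param rate sampling frequency in Hz (> 0)
#' @param unit one of "g", "m_s2", "unknown"
#' @param missing_mask logical vector, one per sample; TRUE marks samples
#'   replaced during artifact removal
#' @param source_id recording identifier
#' @param hand "left", "right" or "unknown"
#' @return object of class `acc_trace`
#' @export
#' @examples
#' tr <- acc_trace(matrix(rnorm(300), ncol = 3), rate = 250)
#' n_samples(tr)
acc_trace <- function(data, rate, unit = "unknown",
                      missing_mask = NULL, source_id = "trace",
                      hand = "unknown") {
  data <- as.matrix(data)
  if (ncol(data) != 3) stop("acc_trace data must have exactly 3 columns (x, y, z)")
  if (nrow(data) < 1) stop("acc_trace needs at least one sample")
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0)
    stop("rate must be a single positive number")
  unit <- match.arg(unit, c("g", "m_s2", "unknown"))
  hand <- match.arg(hand, c("left", "right", "unknown"))
  if (is.null(missing_mask)) missing_mask <- rep(FALSE, nrow(data))
  if (length(missing_mask) != nrow(data))
    stop("missing_mask length must equal the number of samples")
  colnames(data) <- c("x", "y", "z")
  structure(
    list(data = data, rate = rate, unit = unit,
         missing_mask = missing_mask, source_id = source_id, hand = hand),
    class = "acc_trace")
}

#' Number of samples in a trace
#' @param trace an `acc_trace`
#' @return integer sample count
#' @export
n_samples <- function(trace) nrow(trace$data)

#' Trace duration in seconds
#' @param trace an `acc_trace`
#' @return duration (n samples / rate)
#' @export
trace_duration <- function(trace) n_samples(trace) / trace$rate

#' @export
print.acc_trace <- function(x, ...) {
  cat(sprintf("<acc_trace '%s'> %d samples @ %g Hz (%.2f s), unit=%s, hand=%s, %d flagged\n",
              x$source_id, n_samples(x), x$rate, trace_duration(x),
              x$unit, x$hand, sum(x$missing_mask)))
  invisible(x)
}

#' Signal-vector-magnitude series
#'
#' Holds the per-sample magnitude sqrt(x^2 + y^2 + z^2) of a trace and its
#' rate; `missing` carries over the trace's artifact mask.
#'
#' @param values non-negative numeric vector
#' @param rate sampling rate in Hz
#' @param missing logical mask, same length as `values`
#' @return object of class `svm_series`
#' @export
svm_series <- function(values, rate, missing = NULL) {
  if (is.null(missing)) missing <- rep(FALSE, length(values))
  stopifnot(length(missing) == length(values), all(values >= 0 | is.na(values)))
  structure(list(values = values, rate = rate, missing = missing),
            class = "svm_series")
}

#' @export
print.svm_series <- function(x, ...) {
  cat(sprintf("<svm_series> %d samples @ %g Hz, max %.3g\n",
              length(x$values), x$rate, max(x$values, na.rm = TRUE)))
  invisible(x)
}
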