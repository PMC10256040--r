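make_trace <- function(data, rate, unit = "unknown")
  acc_trace(data, rate = rate, unit = unit)

test_that("resampling reaches exactly 250 Hz and preserves content", {
  # a 5 Hz sine sampled at 1000 Hz must match the analytic sine on the
  # 250 Hz grid after resampling
  fs <- 1000
  t <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- sin(2 * pi * 5 * t)
  tr <- make_trace(cbind(x, x, x), fs)
  out <- resample_trace(tr)
  expect_equal(out$rate, 250)
  expect_equal(n_samples(out), 1250)
  tg <- seq(0, by = 1 / 250, length.out = 1250)
  expect_lt(max(abs(out$data[, 1] - sin(2 * pi * 5 * tg))), 1e-3)
  # identity at 250 Hz
  tr250 <- make_trace(matrix(rnorm(300), ncol = 3), 250)
  expect_identical(resample_trace(tr250)$data, tr250$data)
  # sub-250 rates are refused
  expect_error(resample_trace(make_trace(matrix(0, 10, 3), 100)),
               "unsupported rate")
})

test_that("resampling from every supported device rate lands on 250 Hz", {
  for (fs in c(250, 500, 1000, 2000, 4000)) {
    n <- fs * 2
    tr <- make_trace(matrix(rnorm(3 * n), ncol = 3), fs)
    out <- resample_trace(tr)
    expect_equal(out$rate, 250)
    # duration preserved within one output sample
    expect_lte(abs(n_samples(out) / 250 - n / fs), 1 / 250)
  }
})

test_that("unit standardization detects m/s^2 by resting magnitude", {
  n <- 1000
  rest_si <- cbind(rnorm(n, 0, 0.1), rnorm(n, 0, 0.1), rnorm(n, 9.80665, 0.1))
  tr <- suppressMessages(standardize_units(make_trace(rest_si, 250)))
  expect_equal(tr$unit, "g")
  expect_equal(median(sqrt(rowSums(tr$data^2))), 1.0, tolerance = 0.05)
  # a trace already in g passes through untouched
  rest_g <- rest_si / 9.80665
  tr_g <- standardize_units(make_trace(rest_g, 250, unit = "g"))
  expect_identical(unname(tr_g$data), rest_g)
  # all-zero trace unchanged, unit marker preserved
  z <- make_trace(matrix(0, 100, 3), 250)
  expect_identical(standardize_units(z)$unit, "unknown")
})

test_that("bandpass removes DC, attenuates 50 Hz, preserves the passband", {
  n <- 2500
  tt <- seq(0, by = 1 / 250, length.out = n)
  r <- function(v) sqrt(mean(v^2))
  dc <- make_trace(matrix(1, n, 3), 250)
  out <- bandpass_trace(dc)
  expect_lt(mean(abs(out$data[, 1])), 1e-3)
  tone50 <- make_trace(matrix(sin(2 * pi * 50 * tt), n, 3), 250)
  out50 <- bandpass_trace(tone50)
  # steady-state attenuation (the filter's settling ring at the trace
  # edges is excluded from the frequency-response measurement)
  mid <- 251:(n - 250)
  expect_lt(r(out50$data[mid, 1]) / r(tone50$data[mid, 1]), 0.1)   # >= 20 dB
  tone5 <- make_trace(matrix(sin(2 * pi * 5 * tt), n, 3), 250)
  out5 <- bandpass_trace(tone5)
  expect_equal(r(out5$data[, 1]) / r(tone5$data[, 1]), 1.0, tolerance = 0.05)
  # too-short input is refused
  expect_error(bandpass_trace(make_trace(matrix(0, 50, 3), 250)), "too short")
})

test_that("orientation flips are detected on the dominant axis", {
  n <- 5000
  # asymmetric signal: sharp negative excursions (flipped impacts)
  y <- rnorm(n, 0, 0.1)
  y[seq(100, n, by = 100)] <- -2.0
  tr <- make_trace(cbind(y * 0.3, y, y * 0.2), 250)
  oc <- correct_orientation(tr)
  expect_true(oc$flipped)
  expect_equal(oc$trace$data[, 2], -y, tolerance = 1e-12)
  # a sign-symmetric trace is left alone, and correction is one-shot:
  # re-correcting a corrected trace never flips again
  oc2 <- correct_orientation(oc$trace)
  expect_false(oc2$flipped)
  sym <- make_trace(cbind(sin(1:n / 5), cos(1:n / 7), rnorm(n, 0, 0.1)), 250)
  expect_false(correct_orientation(sym)$flipped)
})

test_that("artifact counts equal an independent threshold scan", {
  set.seed(42)
  for (rep in 1:5) {
    m <- matrix(rnorm(3000), ncol = 3)
    spikes <- sample(1000, 3)
    m[spikes, 1] <- 50 * sign(rnorm(3))
    # independent scan: per axis |v| > 10 * 99th percentile of |v|
    expected <- 0
    for (ax in 1:3) {
      thr <- 10 * quantile(abs(m[, ax]), 0.99)
      expected <- expected + sum(abs(m[, ax]) > thr)
    }
    out <- suppressMessages(remove_artifacts(make_trace(m, 250)))
    expect_equal(sum(out$missing_mask), expected)
    # replaced values are finite and interpolated inside the data range
    expect_true(all(is.finite(out$data)))
    expect_lt(max(abs(out$data[, 1])), 50)
  }
  # clean trace: nothing flagged
  clean <- make_trace(matrix(rnorm(3000), ncol = 3), 250)
  expect_equal(sum(remove_artifacts(clean)$missing_mask), 0)
})

test_that("SVM matches the per-sample definition", {
  expect_equal(compute_svm(make_trace(matrix(c(3, 4, 0), 1), 250))$values, 5)
  expect_equal(compute_svm(make_trace(matrix(0, 1, 3), 250))$values, 0)
  m <- matrix(rnorm(300), ncol = 3)
  sv <- compute_svm(make_trace(m, 250))
  brute <- vapply(seq_len(nrow(m)), function(i)
    sqrt(m[i, 1]^2 + m[i, 2]^2 + m[i, 3]^2), numeric(1))
  expect_equal(sv$values, brute, tolerance = 1e-12)
  expect_true(all(sv$values >= 0))
})

test_that("preprocessing decisions are idempotent and quirks are neutralized", {
  rec <- generate_recording(c(1, 1), seed = 31)
  pp <- preprocess_trace(rec$trace)
  # a second pass flips nothing, rescales nothing, flags nothing new
  expect_false(correct_orientation(pp$trace)$flipped)
  expect_identical(standardize_units(pp$trace)$data, pp$trace$data)
  count_taps <- function(trace) {
    p <- suppressMessages(preprocess_trace(trace))
    bl <- detect_blocks(p$svm)
    sum(vapply(seq_len(nrow(bl)), function(i)
      length(detect_impacts(p$svm$values[bl$start[i]:(bl$end[i] - 1)])),
      numeric(1)))
  }
  # quirk-on vs quirk-off twins, same seed: tap counts within 5%
  plain <- generate_recording(c(1, 2), seed = 77)
  quirky <- generate_recording(c(1, 2), seed = 77, rate = 1000,
                               quirks = list(units_ms2 = TRUE, invert = TRUE,
                                             line_noise = TRUE,
                                             artifacts = TRUE))
  n1 <- count_taps(plain$trace)
  n2 <- count_taps(quirky$trace)
  expect_lte(abs(n1 - n2) / n1, 0.05)
})

test_that("an inverted twin recording yields equivalent tap recall", {
  plain <- generate_recording(c(0, 1), seed = 55)
  flipped <- generate_recording(c(0, 1), seed = 55, quirks = list(invert = TRUE))
  recall_of <- function(rec) {
    pp <- suppressMessages(preprocess_trace(rec$trace))
    bl <- detect_blocks(pp$svm)
    truth <- unlist(rec$truth$impacts)
    det <- c()
    for (i in seq_len(nrow(bl))) {
      imp <- detect_impacts(pp$svm$values[bl$start[i]:(bl$end[i] - 1)])
      det <- c(det, (bl$start[i] - 2 + imp) / 250)
    }
    mean(vapply(truth, function(t0) any(abs(det - t0) <= 0.04), logical(1)))
  }
  expect_lte(abs(recall_of(plain) - recall_of(flipped)), 0.05)
})
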