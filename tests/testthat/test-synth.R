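test_that("severity profiles are monotone in the clinical direction", {
  p <- lapply(0:4, severity_profile)
  rates <- vapply(p, `[[`, numeric(1), "tap_rate")
  amps <- vapply(p, `[[`, numeric(1), "impact_amp")
  jit <- vapply(p, `[[`, numeric(1), "iti_jitter_cv")
  hes <- vapply(p, `[[`, numeric(1), "hesitation_prob")
  expect_true(all(diff(rates) < 0))
  expect_true(all(diff(amps) < 0))
  expect_true(all(diff(jit) > 0))
  expect_true(all(diff(hes) >= 0))
  # single-knob override for ablations
  expect_equal(severity_profile(2, tap_rate = 9)$tap_rate, 9)
  expect_error(severity_profile(7))
})

test_that("generated taps carry a dominant impact transient and annotation", {
  set.seed(1)
  for (sev in 0:3) {
    prof <- severity_profile(sev)
    tap <- generate_tap(prof, iti_s = 0.5)
    y <- tap$data[, 2]
    # the impact transient tops the raise amplitude for every profile
    expect_gt(max(y[1:8]), prof$raise_amp * 0.8)
    expect_true(tap$raise[1] > tap$impact_t)
    expect_lt(tap$raise[2], 0.5)
    # the annotated raise window carries a positive half-sine whose
    # integral matches the closed form (checked on the noiseless waveform)
    prof_noiseless <- tap$raise[2] - tap$raise[1]
    expect_equal(prof_noiseless, prof$raise_dur, tolerance = 1e-9)
  }
  # seeded determinism: same seed, byte-identical snippet
  a <- local({ set.seed(123); generate_tap(severity_profile(1), 0.4) })
  b <- local({ set.seed(123); generate_tap(severity_profile(1), 0.4) })
  expect_identical(a, b)
})

test_that("recordings honour the block/rest protocol and ground truth", {
  rec <- generate_recording(c(0, 2, 3), rest_dur = 10, seed = 5)
  tb <- rec$truth$blocks
  expect_equal(nrow(tb), 3)
  expect_equal(tb$severity, c(0, 2, 3))
  # 10 s blocks separated by >= 10 s rest, leading rest included
  expect_equal(tb$start[1], 10)
  expect_true(all(tb$end - tb$start >= 9.5 & tb$end - tb$start <= 10.5))
  expect_true(all(tb$start[-1] - tb$end[-3] >= 10 - 1e-9))
  # impacts lie inside their block, spaced >= 166 ms for severity <= 3
  for (b in 1:3) {
    imp <- rec$truth$impacts[[b]]
    expect_true(all(imp >= tb$start[b] & imp <= tb$end[b]))
    if (length(imp) > 1) expect_true(all(diff(imp) >= 0.166))
  }
  # expected tap counts scale with the profile rate
  expect_gt(length(rec$truth$impacts[[1]]), 25)
  expect_lt(length(rec$truth$impacts[[3]]), 25)
  # rest-only recording
  rest <- generate_recording(integer(0), seed = 6)
  expect_equal(nrow(rest$truth$blocks), 0)
  # determinism
  expect_identical(generate_recording(c(1, 2), seed = 9)$trace$data,
                   generate_recording(c(1, 2), seed = 9)$trace$data)
})

test_that("severity-4 blocks stay below nine near-noise taps", {
  n_taps <- vapply(1:5, function(s)
    length(generate_recording(4, seed = 800 + s)$truth$impacts[[1]]),
    numeric(1))
  expect_true(all(n_taps < 9))
})

test_that("acquisition quirks change the raw trace as advertised", {
  base <- generate_recording(1, seed = 12)
  si <- generate_recording(1, seed = 12, quirks = list(units_ms2 = TRUE))
  expect_equal(si$trace$unit, "m_s2")
  expect_equal(median(sqrt(rowSums(si$trace$data^2))), 9.80665,
               tolerance = 0.5)
  inv <- generate_recording(1, seed = 12, quirks = list(invert = TRUE))
  expect_equal(inv$trace$data, -base$trace$data, tolerance = 1e-12)
  hi <- generate_recording(1, seed = 12, rate = 1000)
  expect_equal(hi$trace$rate, 1000)
  expect_equal(nrow(hi$trace$data), 4 * nrow(base$trace$data), tolerance = 0.01)
})

test_that("cohorts match the requested class mix with exclusive subjects", {
  coh <- generate_cohort(n_subjects = 24, blocks_per_subject = 10, seed = 42)
  lab <- coh$labels
  expect_equal(nrow(lab), 240)
  expect_equal(length(unique(lab$subject_id)), 24)
  mix <- prop.table(table(factor(lab$score, levels = 0:3)))
  req <- c(0.116, 0.422, 0.309, 0.153)
  expect_true(all(abs(mix - req) <= 0.05))
  # per-block label equals the generated severity ground truth
  for (s in c(1, 7, 20)) {
    rec <- coh$recordings[[s]]
    sub <- lab[lab$source_id == rec$trace$source_id, ]
    expect_equal(sub$score, rec$truth$blocks$severity)
  }
  # different seeds: different traces, similar marginals
  coh2 <- generate_cohort(24, 10, seed = 43)
  expect_false(identical(coh2$recordings[[1]]$trace$data,
                         coh$recordings[[1]]$trace$data))
  mix2 <- prop.table(table(factor(coh2$labels$score, levels = 0:3)))
  expect_true(all(abs(mix2 - req) <= 0.05))
})

test_that("kinematic effect directions are monotone across severity", {
  # severity-0 blocks: larger normalized RMS and raise velocity, steadier
  # rhythm (lower ITI coefVar) than severity-3 blocks
  feats <- list()
  for (sev in c(0, 3)) {
    rows <- NULL
    for (s in 1:4) {
      rec <- generate_recording(rep(sev, 2), seed = 900 + 10 * sev + s)
      ex <- suppressMessages(extract_trace_features(rec$trace))
      rows <- rbind(rows, ex$features)
    }
    feats[[as.character(sev)]] <- rows
  }
  f0 <- feats[["0"]]; f3 <- feats[["3"]]
  expect_gt(mean(f0$rms_norm_block), mean(f3$rms_norm_block))
  expect_gt(mean(f0$tap_rms_mean, na.rm = TRUE),
            mean(f3$tap_rms_mean, na.rm = TRUE))
  expect_gt(mean(f0$raise_vel_mean, na.rm = TRUE),
            mean(f3$raise_vel_mean, na.rm = TRUE))
  expect_lt(mean(f0$iti_cv, na.rm = TRUE), mean(f3$iti_cv, na.rm = TRUE))
})

test_that("generator and detector are mutually consistent on easy input", {
  hits <- 0; total <- 0; tp <- 0; nt <- 0
  for (s in 1:4) {
    rec <- generate_recording(sample(0:1, 2, replace = TRUE), seed = 950 + s)
    pp <- suppressMessages(preprocess_trace(rec$trace))
    bl <- detect_blocks(pp$svm)
    m <- match_truth_blocks(bl, rec$truth$blocks)
    hits <- hits + m$recall_hits; total <- total + 2
    det <- c()
    for (i in seq_len(nrow(bl)))
      det <- c(det, (bl$start[i] - 2 +
                       detect_impacts(pp$svm$values[bl$start[i]:(bl$end[i] - 1)])) / 250)
    truth <- unlist(rec$truth$impacts)
    nt <- nt + length(truth)
    tp <- tp + sum(vapply(truth, function(t0) any(abs(det - t0) <= 0.04),
                          logical(1)))
  }
  expect_equal(hits / total, 1.0)
  expect_gte(tp / nt, 0.9)
})

test_that("fixtures written to disk re-enter the pipeline cleanly", {
  dir <- withr::local_tempdir()
  make_fixtures(dir, n_subjects = 2, blocks_per_subject = 2, seed = 3)
  files <- list.files(dir, pattern = "_rec\\.csv$", full.names = TRUE)
  expect_length(files, 2)
  tr <- read_trace(files[1], rate = 250)
  expect_equal(trace_duration(tr), 50, tolerance = 1)
  lab <- read_labels(file.path(dir, "labels.csv"))
  expect_equal(nrow(lab), 4)
})
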