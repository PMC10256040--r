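#' Severity profile for the synthetic tapping generator
#'
#' Maps a UPDRS Item 3.4 severity (0 normal .. 4 barely able to tap) to
#' generator parameters: tap rate, impact and raise amplitudes, raise
#' duration, fractional amplitude decrement per second, inter-tap-interval
#' jitter, and hesitation probability. Defaults are monotone in severity:
#' amplitude and rate fall, jitter/decrement/hesitations rise. Severity 4
#' produces fewer than nine detectable taps per 10 s at near-noise
#' amplitude. Any field can be overridden for ablation experiments.
#'
#' @param severity integer 0-4
#' @param ... named overrides of individual profile fields
#' @return list of profile parameters
#' @export
#' @examples
#' severity_profile(0)$tap_rate > severity_profile(3)$tap_rate
severity_profile <- function(severity, ...) {
  stopifnot(severity %in% 0:4)
  base <- list(
    list(tap_rate = 3.8, iti_jitter_cv = 0.05, impact_amp = 2.2,
         impact_sd = 0.25, raise_amp = 0.85, raise_sd = 0.08,
         raise_dur = 0.10, amp_decrement = 0.004, hesitation_prob = 0.00),
    list(tap_rate = 3.2, iti_jitter_cv = 0.10, impact_amp = 1.6,
         impact_sd = 0.20, raise_amp = 0.60, raise_sd = 0.07,
         raise_dur = 0.11, amp_decrement = 0.015, hesitation_prob = 0.03),
    list(tap_rate = 2.4, iti_jitter_cv = 0.18, impact_amp = 1.05,
         impact_sd = 0.15, raise_amp = 0.40, raise_sd = 0.05,
         raise_dur = 0.13, amp_decrement = 0.035, hesitation_prob = 0.08),
    list(tap_rate = 1.6, iti_jitter_cv = 0.30, impact_amp = 0.50,
         impact_sd = 0.08, raise_amp = 0.20, raise_sd = 0.04,
         raise_dur = 0.16, amp_decrement = 0.055, hesitation_prob = 0.18),
    list(tap_rate = 0.6, iti_jitter_cv = 0.50, impact_amp = 0.07,
         impact_sd = 0.02, raise_amp = 0.035, raise_sd = 0.01,
         raise_dur = 0.22, amp_decrement = 0.02, hesitation_prob = 0.50)
  )[[severity + 1]]
  base$severity <- severity
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  base
}

# baseline accelerometer noise, in g
SYNTH_NOISE_SD <- 0.015

# noiseless dominant-axis tap waveform over n samples: impact transient,
# raise half-sine, closing half-sine; all timing in seconds
tap_waveform <- function(n, rate, iti_s, imp_amp, rai_amp, rai_dur) {
  t <- (seq_len(n) - 1) / rate
  imp_dur <- 0.024
  clo_dur <- min(rai_dur * 1.2, iti_s * 0.4)
  y <- numeric(n)
  ii <- t < imp_dur
  y[ii] <- y[ii] + imp_amp * sin(pi * t[ii] / imp_dur)
  r0 <- imp_dur + 0.008
  ri <- t >= r0 & t < r0 + rai_dur
  y[ri] <- y[ri] + rai_amp * sin(pi * (t[ri] - r0) / rai_dur)
  c0 <- max(r0 + rai_dur, iti_s - clo_dur)
  ci <- t >= c0
  y[ci] <- y[ci] - 0.9 * rai_amp * sin(pi * (t[ci] - c0) / clo_dur)
  list(y = y, impact_t = imp_dur / 2, raise = c(r0, r0 + rai_dur))
}

# draw the rate-independent per-tap parameters for one tap
draw_tap_params <- function(profile, amp_scale = 1) {
  list(imp_amp = max(0.01, rnorm(1, profile$impact_amp, profile$impact_sd)) *
         amp_scale,
       rai_amp = max(0.005, rnorm(1, profile$raise_amp, profile$raise_sd)) *
         amp_scale,
       sc = runif(2, 0.2, 0.5))
}

#' Generate one synthetic tap snippet
#'
#' Dominant-axis waveform over one inter-tap interval: a sharp positive
#' impact transient (<= 30 ms half-sine) at the interval start, a positive
#' half-sine raise (finger opening), and a negative half-sine closing just
#' before the next impact. The other two axes are attenuated copies
#' (0.2-0.5 x) plus noise.
#'
#' @param profile a [severity_profile()]
#' @param iti_s interval to the next impact, seconds
#' @param rate sampling rate in Hz
#' @param amp_scale multiplicative amplitude scale (decrement within block)
#' @return list: `data` (n x 3 matrix, g; axis 2 dominant), `impact_t`
#'   (apex time, s, relative to snippet start), `raise` (c(start, end), s)
#' @export
generate_tap <- function(profile, iti_s = 1 / profile$tap_rate, rate = 250,
                         amp_scale = 1) {
  n <- max(8L, round(iti_s * rate))
  pars <- draw_tap_params(profile, amp_scale)
  wf <- tap_waveform(n, rate, iti_s, pars$imp_amp, pars$rai_amp,
                     profile$raise_dur)
  data <- cbind(x = pars$sc[1] * wf$y + rnorm(n, 0, SYNTH_NOISE_SD),
                y = wf$y + rnorm(n, 0, SYNTH_NOISE_SD),
                z = pars$sc[2] * wf$y + rnorm(n, 0, SYNTH_NOISE_SD))
  list(data = data, impact_t = wf$impact_t, raise = wf$raise)
}

#' Generate a synthetic tapping recording with ground truth
#'
#' Emulates the clinical protocol: 10-second tapping blocks separated by
#' rest (baseline noise plus a 1 g gravity offset on the z axis), with a
#' leading rest period. Optional acquisition quirks reproduce real-world
#' nuisances: higher sampling rate, SI units, inverted sensor mounting,
#' 50 Hz line noise, and artifact spikes.
#'
#' @param severities integer vector of per-block severities (0-4); its
#'   length sets the number of blocks
#' @param rest_dur rest duration between blocks, seconds (>= the 10 s
#'   protocol pause by default)
#' @param block_dur tapping block duration, seconds
#' @param rate output sampling rate in Hz (250-5000)
#' @param quirks list of toggles: `units_ms2`, `invert`, `line_noise`,
#'   `artifacts` (all default FALSE)
#' @param seed integer seed; all randomness derives from it
#' @param source_id recording identifier
#' @return list: `trace` (an [acc_trace()]) and `truth` -- ground truth in
#'   seconds (`blocks` data.frame start/end/severity, `impacts` and
#'   `raises` per block)
#' @export
generate_recording <- function(severities, rest_dur = 10, block_dur = 10,
                               rate = 250, quirks = list(), seed = 1,
                               source_id = "synthetic") {
  q <- modifyList(list(units_ms2 = FALSE, invert = FALSE,
                       line_noise = FALSE, artifacts = FALSE), quirks)
  stopifnot(rate >= 250, rate <= 5000)
  with_seed(seed, {
    n_blocks <- length(severities)
    segs <- list(); truth_blocks <- NULL
    impacts <- list(); raises <- list()
    t_cursor <- 0
    noise_mat <- function(dur) {
      n <- round(dur * rate)
      cbind(rnorm(n, 0, SYNTH_NOISE_SD), rnorm(n, 0, SYNTH_NOISE_SD),
            rnorm(n, 0, SYNTH_NOISE_SD))
    }
    rest <- function(dur) {
      m <- noise_mat(dur)
      m[, 3] <- m[, 3] + 1   # static gravity on z
      m
    }
    # phase 1: draw every block's tap schedule and per-tap parameters
    # first, in a rate-independent order, so recordings generated at
    # different sampling rates from one seed share identical taps and
    # identical ground truth
    scheds <- vector("list", n_blocks)
    spans <- numeric(n_blocks)
    for (b in seq_len(n_blocks)) {
      prof <- severity_profile(severities[b])
      sched <- list(); tb <- 0
      while (tb < block_dur) {
        iti <- (1 / prof$tap_rate) * max(0.4, 1 + rnorm(1, 0, prof$iti_jitter_cv))
        if (prof$severity <= 3) iti <- max(0.18, iti)
        if (runif(1) < prof$hesitation_prob) iti <- iti * runif(1, 1.8, 3)
        iti <- min(iti, block_dur - tb)
        if (iti < 0.1) break
        pars <- draw_tap_params(prof, max(0.25, 1 - prof$amp_decrement * tb))
        sched[[length(sched) + 1]] <- list(t0 = tb, iti = iti, pars = pars)
        tb <- tb + iti
      }
      scheds[[b]] <- sched
      spans[b] <- tb
    }
    # phase 2: synthesize waveform and noise at the requested rate
    segs[[1]] <- rest(rest_dur)
    t_cursor <- rest_dur
    for (b in seq_len(n_blocks)) {
      prof <- severity_profile(severities[b])
      block_imp <- numeric(0); block_rai <- NULL
      sched <- scheds[[b]]
      tb <- spans[b]
      if (!length(sched)) {
        bdata <- noise_mat(block_dur)
      } else {
        n_block <- round(tb * rate)
        starts <- vapply(sched, function(s) round(s$t0 * rate), numeric(1))
        ends <- c(starts[-1], n_block)
        xs <- numeric(n_block); ys <- numeric(n_block); zs <- numeric(n_block)
        for (k in seq_along(sched)) {
          s <- sched[[k]]
          n_k <- ends[k] - starts[k]
          if (n_k < 2) next
          wf <- tap_waveform(n_k, rate, s$iti, s$pars$imp_amp,
                             s$pars$rai_amp, prof$raise_dur)
          seg <- (starts[k] + 1):ends[k]
          xs[seg] <- s$pars$sc[1] * wf$y
          ys[seg] <- wf$y
          zs[seg] <- s$pars$sc[2] * wf$y
          block_imp <- c(block_imp, t_cursor + starts[k] / rate + wf$impact_t)
          block_rai <- rbind(block_rai,
                             t_cursor + starts[k] / rate + wf$raise)
        }
        bdata <- cbind(xs, ys, zs) + noise_mat(n_block / rate)
      }
      bdata[, 3] <- bdata[, 3] + 1   # gravity on z during tapping too
      segs[[length(segs) + 1]] <- bdata
      truth_blocks <- rbind(truth_blocks,
                            data.frame(start = t_cursor,
                                       end = t_cursor + nrow(bdata) / rate,
                                       severity = severities[b]))
      impacts[[b]] <- block_imp
      raises[[b]] <- block_rai
      t_cursor <- t_cursor + nrow(bdata) / rate
      segs[[length(segs) + 1]] <- rest(rest_dur)
      t_cursor <- t_cursor + rest_dur
    }
    data <- do.call(rbind, segs)
    if (q$line_noise) {
      tt <- (seq_len(nrow(data)) - 1) / rate
      data <- data + 0.05 * sin(2 * pi * 50 * tt)
    }
    if (q$artifacts) {
      n_art <- 3
      pos <- sample(nrow(data), n_art)
      for (ax in 1:3) {
        thr <- 10 * quantile(abs(data[, ax]), 0.99, names = FALSE)
        data[pos, ax] <- 2 * thr * sign(data[pos, ax] + 1e-9)
      }
    }
    if (q$invert) data <- -data
    unit <- "g"
    if (q$units_ms2) { data <- data * GRAVITY_MS2; unit <- "m_s2" }
    if (is.null(truth_blocks))
      truth_blocks <- data.frame(start = numeric(0), end = numeric(0),
                                 severity = integer(0))
    list(trace = acc_trace(data, rate = rate, unit = unit,
                           source_id = source_id),
         truth = list(blocks = truth_blocks, impacts = impacts,
                      raises = raises))
  })
}

#' Generate a synthetic multi-subject cohort
#'
#' Subjects carry a base severity drawn from `severity_mix` (default: the
#' naturally unbalanced clinical class distribution 0: 11.6%, 1: 42.2%,
#' 2: 30.9%, 3: 15.3%); each block's severity is the base shifted by
#' therapeutic-condition fluctuation (+/-1 with probability 0.1 each,
#' clamped to 0-3), so subject identity carries real information and
#' subject-exclusive splitting matters. Blocks cycle through the four
#' med/stim ON/OFF condition tags; sites alternate by subject.
#'
#' @param n_subjects number of subjects (>= 2)
#' @param blocks_per_subject tapping blocks per subject
#' @param severity_mix probabilities of base severities 0-3
#' @param rate sampling rate in Hz
#' @param quirks quirk toggles passed to [generate_recording()]
#' @param seed integer seed
#' @return list: `recordings` (list of generate_recording outputs, one per
#'   subject) and `labels` (data.frame source_id, block_index, subject_id,
#'   site, condition, score)
#' @export
generate_cohort <- function(n_subjects = 36, blocks_per_subject = 10,
                            severity_mix = c(0.116, 0.422, 0.309, 0.153),
                            rate = 250, quirks = list(), seed = 1) {
  stopifnot(n_subjects >= 2)
  mix <- severity_mix / sum(severity_mix)
  conditions <- c("medOff_stimOff", "medOn_stimOff", "medOff_stimOn",
                  "medOn_stimOn")
  # condition shifts (+/-1 w.p. 0.1, clamped) redistribute labels; draw the
  # subject base severities from the shift-compensated prior so the BLOCK
  # label marginal matches the requested mix
  shift_T <- matrix(c(0.9, 0.1, 0, 0,
                      0.1, 0.8, 0.1, 0,
                      0, 0.1, 0.8, 0.1,
                      0, 0, 0.1, 0.9), 4, 4, byrow = TRUE)
  base_mix <- as.vector(solve(t(shift_T), mix))
  base_mix <- pmax(0, base_mix); base_mix <- base_mix / sum(base_mix)
  with_seed(seed, {
    # stratified base-severity allocation (largest-remainder rounding), so
    # the cohort marginal tracks the requested mix despite subject clustering
    raw <- base_mix * n_subjects
    cnt <- floor(raw)
    rem <- n_subjects - sum(cnt)
    if (rem > 0) {
      extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
      cnt[extra] <- cnt[extra] + 1
    }
    bases <- sample(rep(seq_along(mix) - 1L, cnt))
    shifts <- matrix(sample(c(-1L, 0L, 1L), n_subjects * blocks_per_subject,
                            replace = TRUE, prob = c(0.1, 0.8, 0.1)),
                     nrow = n_subjects)
    rec_seeds <- sample.int(2147483646, n_subjects)
  })
  recordings <- vector("list", n_subjects)
  labels <- NULL
  for (s in seq_len(n_subjects)) {
    sev <- pmin(3L, pmax(0L, bases[s] + shifts[s, ]))
    sid <- sprintf("subj%02d", s)
    rec <- generate_recording(sev, rate = rate, quirks = quirks,
                              seed = rec_seeds[s],
                              source_id = sprintf("%s_rec", sid))
    recordings[[s]] <- rec
    labels <- rbind(labels, data.frame(
      source_id = sprintf("%s_rec", sid),
      block_index = seq_along(sev) - 1L,
      subject_id = sid,
      site = if (s %% 2 == 0) "siteA" else "siteB",
      condition = conditions[(seq_along(sev) - 1L) %% 4L + 1L],
      score = sev, stringsAsFactors = FALSE))
  }
  list(recordings = recordings, labels = labels)
}

#' Write a synthetic cohort to disk as CSV fixtures
#'
#' Materializes traces in the same delimited dialect [read_trace()] reads,
#' the label table, and the ground truth as JSON.
#'
#' @param dir output directory (created if needed)
#' @param n_subjects,blocks_per_subject,seed passed to [generate_cohort()]
#' @return `dir`, invisibly
#' @export
make_fixtures <- function(dir, n_subjects = 6, blocks_per_subject = 4,
                          seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  coh <- generate_cohort(n_subjects, blocks_per_subject, seed = seed)
  for (rec in coh$recordings) {
    tr <- rec$trace
    write.table(format(as.data.frame(tr$data), digits = 8, trim = TRUE),
                file.path(dir, paste0(tr$source_id, ".csv")),
                sep = ",", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(rec$truth$blocks,
                         file.path(dir, paste0(tr$source_id, "_truth.json")),
                         digits = NA)
  }
  write.table(coh$labels, file.path(dir, "labels.csv"), sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(dir)
}
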