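# small label table with controllable class structure, subject-exclusive
fake_labels <- function(n_subjects = 20, blocks_per = 8, seed = 1) {
  set.seed(seed)
  bases <- rep(0:3, length.out = n_subjects)
  rows <- NULL
  for (s in seq_len(n_subjects)) {
    sc <- pmin(3, pmax(0, bases[s] + sample(c(-1, 0, 1), blocks_per,
                                            replace = TRUE,
                                            prob = c(0.15, 0.7, 0.15))))
    rows <- rbind(rows, data.frame(
      source_id = sprintf("rec%02d", s), block_index = seq_len(blocks_per) - 1,
      subject_id = sprintf("subj%02d", s),
      site = ifelse(s %% 2 == 0, "siteA", "siteB"),
      condition = "medOn_stimOn", score = sc))
  }
  rows
}

test_that("the split is subject-exclusive, stratified and reproducible", {
  lab <- fake_labels()
  params <- modifyList(default_config()$classify,
                       list(split_tolerance = 0.05, split_seed = 7))
  sp <- split_dataset(lab, params)
  expect_length(intersect(sp$dev_subjects, sp$holdout_subjects), 0)
  expect_setequal(c(sp$dev_subjects, sp$holdout_subjects),
                  unique(lab$subject_id))
  # class proportions on both sides near the full-set proportions
  full <- prop.table(table(factor(lab$score, levels = 0:4)))
  for (side in list(sp$dev_subjects, sp$holdout_subjects)) {
    sub <- lab[lab$subject_id %in% side, ]
    gap <- max(abs(prop.table(table(factor(sub$score, levels = 0:4))) - full))
    expect_lte(gap, 0.05)
  }
  # block-count ratio near 75/25
  ndev <- sum(lab$subject_id %in% sp$dev_subjects)
  expect_lte(abs(ndev / nrow(lab) - 0.75), 0.07)
  # same seed, same split
  sp2 <- split_dataset(lab, params)
  expect_identical(sp[1:2], sp2[1:2])
  # impossible tolerance errors out with the best gap reported
  expect_error(split_dataset(lab, modifyList(params,
                 list(split_tolerance = 1e-6, split_max_iter = 50))),
               "no admissible split")
})

test_that("every rule path fires on fabricated feature vectors", {
  ctx <- list(rms10 = 0.5, vel_thr = 0.3)
  fv <- function(n_taps, rms, vel) {
    d <- as.data.frame(setNames(as.list(rep(1, length(feature_columns()))),
                                feature_columns()))
    d$n_taps <- n_taps; d$rms_norm_block <- rms; d$raise_vel_mean <- vel
    d
  }
  # few, small, weak taps -> 3
  r <- apply_rules(fv(5, 0.8, 0.1), ctx)
  expect_equal(r$rule, "few_taps_3"); expect_equal(r$score, 3L)
  # few taps with near-absent movement -> 4
  r <- apply_rules(fv(5, 0.2, 0.1), ctx)
  expect_equal(r$rule, "few_taps_4"); expect_equal(r$score, 4L)
  # few but vigorous taps -> deferred to the classifier
  r <- apply_rules(fv(5, 0.8, 0.9), ctx)
  expect_equal(r$rule, "velocity_override_deferred")
  expect_equal(r$action, "defer")
  # enough taps -> deferred, no rule
  r <- apply_rules(fv(12, 0.2, 0.1), ctx)
  expect_equal(r$rule, "none"); expect_equal(r$action, "defer")
  # RMS-4 wins over the velocity override among few-tap blocks
  r <- apply_rules(fv(5, 0.2, 0.9), ctx)
  expect_equal(r$rule, "few_taps_4")
  expect_error(apply_rules(fv(5, 1, 1), list()), "training context")
})

test_that("training learns a separable problem and is seed-deterministic", {
  set.seed(33)
  n <- 120
  lab <- data.frame(score = rep(0:3, each = n / 4))
  feats <- as.data.frame(matrix(1, n, length(feature_columns())))
  names(feats) <- feature_columns()
  feats$source_id <- "r"; feats$block_index <- seq_len(n)
  feats$n_taps <- 20
  # one feature separates the classes perfectly; all others constant
  feats$rms_norm_block <- lab$score * 2 + runif(n, 0, 0.5)
  m1 <- train_tap_model(feats, lab)
  p1 <- predict(m1, feats)
  expect_gte(mean(p1$predicted_score == lab$score), 0.95)
  expect_true(all(p1$predicted_score %in% 0:4))
  # determinism on a fixed probe
  m2 <- train_tap_model(feats, lab)
  expect_identical(predict(m2, feats)$predicted_score, p1$predicted_score)
  # the informative feature ranks first in MDI importance
  expect_equal(feature_importance(m1)$feature[1], "rms_norm_block")
  # an absent class is a hard error listing counts
  expect_error(train_tap_model(feats[lab$score > 0, ], lab[lab$score > 0, ,
                                                           drop = FALSE]),
               "all classes")
})

test_that("rule precedence is total: zero-tap blocks never reach the forest", {
  set.seed(34)
  n <- 80
  lab <- data.frame(score = rep(0:3, each = n / 4))
  feats <- as.data.frame(matrix(rnorm(n * length(feature_columns())), n))
  names(feats) <- feature_columns()
  feats$source_id <- "r"; feats$block_index <- seq_len(n)
  feats$n_taps <- 20
  feats$rms_norm_block <- lab$score + runif(n)
  m <- train_tap_model(feats, lab)
  probe <- feats[1, ]
  probe$n_taps <- 0
  probe[c("iti_mean", "raise_vel_mean")] <- NA
  pr <- predict(m, probe)
  expect_true(pr$predicted_score %in% c(3, 4))
  expect_true(pr$rule_applied %in% c("few_taps_3", "few_taps_4"))
  expect_true(is.na(pr$prob_0))
  # feature-order contract
  expect_error(predict(m, probe[, 1:5]), "order contract")
})

test_that("thresholds come from training data only", {
  set.seed(35)
  n <- 100
  lab <- data.frame(score = rep(0:3, each = n / 4))
  feats <- as.data.frame(matrix(1, n, length(feature_columns())))
  names(feats) <- feature_columns()
  feats$source_id <- "r"; feats$block_index <- seq_len(n)
  feats$n_taps <- sample(c(5, 20), n, replace = TRUE)
  feats$rms_norm_block <- runif(n, 0, 4)
  feats$raise_vel_mean <- runif(n, 0, 1)
  feats$iti_cv <- rnorm(n)
  m <- train_tap_model(feats, lab)
  # the rule context must not move when unseen (holdout) data changes
  probe <- feats; probe$rms_norm_block <- probe$rms_norm_block * 100
  m_ctx <- m$context
  pr <- predict(m, probe)
  expect_identical(m$context, m_ctx)
  # velocity override threshold equals the training median over scores 0-1
  good <- lab$score <= 1
  expect_equal(m$context$vel_thr, median(feats$raise_vel_mean[good]))
  few <- feats$n_taps < 9
  expect_equal(m$context$rms10,
               unname(quantile(feats$rms_norm_block[few], 0.10)))
})

test_that("models survive a save/load round trip", {
  set.seed(36)
  n <- 60
  lab <- data.frame(score = rep(0:3, each = n / 4))
  feats <- as.data.frame(matrix(1, n, length(feature_columns())))
  names(feats) <- feature_columns()
  feats$source_id <- "r"; feats$block_index <- seq_len(n)
  feats$n_taps <- 20
  feats$rms_norm_block <- lab$score + runif(n, 0, 0.3)
  m <- train_tap_model(feats, lab)
  path <- withr::local_tempfile(fileext = ".rds")
  save_tap_model(m, path)
  m2 <- load_tap_model(path)
  expect_identical(predict(m2, feats)$predicted_score,
                   predict(m, feats)$predicted_score)
})
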