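test_that("learning configuration enforces the protocol counts", {
  cfg <- learning_config("feedback_delta")
  expect_equal(cfg$n_trials, 432L)
  expect_equal(cfg$training_elevations, c(60, 40, 20, -10, -30, -50))
  expect_equal(cfg$training_stimulus, "BS35")
  expect_equal(learning_config("exposure_selfconsistency")$training_stimulus, "LP6")
  expect_error(learning_config(n_trials = 431), "multiple")
  expect_error(learning_config(learning_rate = -1), "learning_rate")
})

test_that("weight updates respect bounds, null steps and zero error", {
  bs35 <- stimulus_spectrum("BS35", fix_axis)
  w0 <- fix_obs$weights
  # null learning rate
  expect_equal(as.numeric(update_weights_feedback(fix_obs, bs35, 40, 0)), w0)
  # zero error: teach the estimator its own prediction (deterministic observer)
  obs_det <- observer(fix_hrtf, sensory_noise_sd = 0, internal_noise_sd = 0)
  est <- localize(obs_det, bs35, 40)$post_mean
  sens <- sensory_spectrum(bs35, fix_hrtf, 40, 0)
  w_zero <- update_weights_feedback(obs_det, bs35, est, 0.05, sensory = sens)
  expect_equal(as.numeric(w_zero), w0)
  # per-trial conservatism: step norm bounded by the learning rate, weights in [0,1]
  withr::with_seed(11, {
    obs <- fix_obs
    for (i in 1:20) {
      el <- sample(c(60, 40, 20, -10, -30, -50), 1)
      sens <- sensory_spectrum(bs35, fix_hrtf, el, noise_sd = 3)
      w_new <- update_weights_feedback(obs, bs35, el, 0.03, sensory = sens)
      expect_true(all(w_new >= 0 & w_new <= 1))
      expect_lte(sqrt(sum((w_new - obs$weights)^2)), 0.03 + 1e-12)
      obs$weights <- as.numeric(w_new)
    }
  })
  # uniform-likelihood (degenerate) exposure trial: no update
  trial <- list(lik_mode = 0, confidence = 1 / 29, degenerate = TRUE)
  w_skip <- update_weights_exposure(fix_obs, bs35, trial, 0.05)
  expect_equal(as.numeric(w_skip), w0)
  expect_true(attr(w_skip, "skipped"))
})

test_that("feedback training on BS35 raises the weak low-band weights", {
  f <- as.numeric(fix_axis)
  low <- f >= 3600 & f <= 6000
  gains <- vapply(1:5, function(s) {
    L <- simulate_listener(s, master_seed = 21)
    tr <- simulate_training_session(
      L$observer, learning_config("feedback_delta", seed = 100 + s))
    mean(tr$observer$weights[low]) - mean(L$observer$weights[low])
  }, numeric(1))
  expect_gt(mean(gains), 0)
  expect_gte(sum(gains > 0), 4)
})

test_that("training sessions are balanced, reproducible and resilient", {
  L <- simulate_listener(1, master_seed = 31)
  cfg <- learning_config("feedback_delta", n_trials = 72, seed = 5)
  tr <- simulate_training_session(L$observer, cfg)
  expect_equal(nrow(tr$trials), 72)
  expect_true(all(table(tr$trials$target_el_deg) == 12))
  # no elevation repeats more than twice in a row
  runs <- rle(tr$trials$target_el_deg)
  expect_lte(max(runs$lengths), 2)
  # bit-identical replay from the same config
  tr2 <- simulate_training_session(L$observer, cfg)
  expect_identical(tr$trials, tr2$trials)
  expect_identical(tr$observer$weights, tr2$observer$weights)
  # weight bookkeeping
  expect_equal(length(tr$weight_checksums), 72)
  expect_equal(unique(tr$weight_snapshots$trial), seq(10, 70, 10))
})

test_that("a zero learning rate leaves windowed performance flat", {
  L <- simulate_listener(2, master_seed = 31)
  tr <- simulate_training_session(
    L$observer, learning_config("feedback_delta", learning_rate = 0, seed = 9))
  expect_equal(range(tr$weight_checksums), rep(sum(L$observer$weights), 2))
  w <- windowed_regression(tr$trials)
  expect_lt(abs(mean(w$gain[w$start >= 330]) - mean(w$gain[w$start <= 50])), 0.3)
})

test_that("test sessions implement the published protocols", {
  L <- simulate_listener(1, master_seed = 41)
  pre1 <- simulate_test_session(L$observer, "pre", 1, seed = 2)
  expect_equal(nrow(pre1), 135)
  expect_equal(sort(unique(pre1$stim_kind)), c("BS25", "BS35", "LP6"))
  expect_true(all(table(pre1$stim_kind) == 45))
  expect_true(all(abs(pre1$target_az_deg) + abs(pre1$target_el_deg) <= 90))
  expect_true(all(pre1$target_el_deg >= -55 & pre1$target_el_deg <= 85))
  pre2 <- simulate_test_session(L$observer, "pre", 2, seed = 2)
  expect_equal(nrow(pre2), 116)
  expect_true(all(table(pre2$stim_kind) == 58))
  expect_true(all(abs(pre2$target_az_deg) <= 50))
  ctl <- simulate_test_session(L$observer, "control", seed = 2)
  expect_equal(nrow(ctl), 275)
  expect_true(all(table(ctl$stim_kind) == 55))
  expect_true(all(abs(ctl$target_az_deg) <= 20))
  expect_true(all(ctl$target_el_deg >= -50 & ctl$target_el_deg <= 60))
  # reproducible
  expect_identical(ctl, simulate_test_session(L$observer, "control", seed = 2))
})
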