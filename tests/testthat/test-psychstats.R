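test_that("stimulus-response regression recovers exact linear maps", {
  t1 <- c(-20, 0, 10, 30)
  f1 <- fit_stimulus_response(t1, t1)
  expect_equal(f1$gain, 1)
  expect_equal(f1$bias, 0)
  expect_equal(f1$r2, 1)
  expect_equal(f1$mare, 0)
  expect_equal(f1$mae, 0)
  f2 <- fit_stimulus_response(t1, 0.5 * t1 + 10)
  expect_equal(f2$gain, 0.5)
  expect_equal(f2$bias, 10)
  expect_equal(f2$r2, 1)
  # constant offset: unit gain, bias = MAE, zero residual error
  f3 <- fit_stimulus_response(c(0, 10, 20), c(5, 15, 25))
  expect_equal(f3$gain, 1)
  expect_equal(f3$bias, 5)
  expect_equal(f3$mae, 5)
  expect_equal(f3$mare, 0)
  expect_error(fit_stimulus_response(c(5, 5, 5), c(1, 2, 3)), "variance")
  expect_error(fit_stimulus_response(c(1, 2), c(1, 2)), "3 trials")
})

test_that("regression statistics are scale-equivariant", {
  withr::with_seed(7, {
    for (i in 1:5) {
      t <- runif(40, -50, 60)
      r <- 0.6 * t + 4 + rnorm(40, 0, 8)
      k <- runif(1, 0.5, 3)
      a <- glance(fit_stimulus_response(t, r))
      b <- glance(fit_stimulus_response(k * t, k * r))
      expect_equal(b$gain, a$gain)
      expect_equal(b$r2, a$r2)
      expect_equal(b$bias, k * a$bias)
      expect_equal(b$mare, k * a$mare)
      expect_equal(b$mae, k * a$mae)
    }
  })
})

test_that("tidy and glance expose the fit as tibbles", {
  f <- fit_stimulus_response(c(0, 10, 20), c(5, 15, 25))
  td <- tidy(f)
  expect_equal(td$estimate[td$term == "gain"], 1)
  gl <- glance(f)
  expect_equal(gl$r2, gl$r^2, tolerance = 1e-12)
  expect_equal(gl$n, 3L)
})

test_that("windowed regression has the declared window count", {
  withr::with_seed(1, {
    d <- tibble::tibble(trial = 1:432,
                        target_el_deg = rep(c(60, 40, 20, -10, -30, -50), 72),
                        resp_el_deg = rep(c(60, 40, 20, -10, -30, -50), 72) +
                          rnorm(432, 0, 5))
  })
  w <- windowed_regression(d, 50, 5)
  expect_equal(nrow(w), 77)
  expect_equal(w$start, seq(1, 381, by = 5))
  # degenerate window: one entry equal to the whole-session fit
  w1 <- windowed_regression(d, nrow(d), 5)
  expect_equal(nrow(w1), 1)
  expect_equal(w1$gain, fit_stimulus_response(d$target_el_deg, d$resp_el_deg)$gain)
  # entry-count invariant across window/step combinations
  for (cfg in list(c(100, 10), c(60, 7), c(50, 1))) {
    ww <- windowed_regression(d, cfg[1], cfg[2])
    expect_equal(nrow(ww), floor((432 - cfg[1]) / cfg[2]) + 1)
  }
  expect_error(windowed_regression(d, 5, 5), "at least 10")
  expect_error(windowed_regression(d[1:30, ], 50), "shorter")
})

test_that("a stationary responder shows no windowed trend", {
  withr::with_seed(42, {
    d <- tibble::tibble(trial = 1:432,
                        target_el_deg = rep(c(60, 40, 20, -10, -30, -50), 72),
                        resp_el_deg = 0.6 * rep(c(60, 40, 20, -10, -30, -50), 72) +
                          rnorm(432, 0, 10))
  })
  w <- windowed_regression(d)
  expect_lt(abs(mean(w$gain[w$start <= 50]) - mean(w$gain[w$start >= 330])), 0.1)
})

test_that("sign test equals the exact binomial tail", {
  expect_equal(sign_test_p(36, 36)$p_value, 2^-36)
  expect_equal(sign_test_p(0, 17)$p_value, 1)
  expect_equal(sign_test_p(29, 36)$p_value, 0.000156275578775, tolerance = 1e-10)
  # exhaustive enumeration oracle: all 2^n equally likely sign vectors
  for (n in c(5, 9, 12, 16)) {
    counts <- vapply(0:(2^n - 1),
                     function(x) sum(as.integer(intToBits(x))[1:n]), integer(1))
    for (s in 0:n) {
      expect_equal(sign_test_p(s, n)$p_value, mean(counts >= s))
    }
  }
  # closed-form cross-check at the study size
  for (s in c(18, 24, 26, 29, 33)) {
    expect_equal(sign_test_p(s, 36)$p_value,
                 pbinom(s - 1, 36, 0.5, lower.tail = FALSE), tolerance = 1e-12)
  }
  expect_error(sign_test_p(10, 5))
})

test_that("pre/post comparison counts strict improvements per stimulus", {
  fits <- tidyr::expand_grid(subject_id = paste0("S", 1:9),
                             stim_kind = c("LP6", "BS35")) |>
    dplyr::mutate(gain = 0.4, bias = 8, r2 = 0.4, mae = 20)
  same <- compare_pre_post(fits, fits)
  expect_equal(same$successes, c(0L, 0L))
  expect_equal(same$p_value, c(1, 1))
  better <- fits |> dplyr::mutate(gain = 0.7, bias = 2, r2 = 0.7, mae = 10)
  all_up <- compare_pre_post(fits, better)
  expect_equal(all_up$successes, c(36L, 36L))
  expect_equal(all_up$p_value, rep(2^-36, 2))
  expect_error(compare_pre_post(fits, fits[-1, ]), "different subject")
})

test_that("double-pole sampling respects the frontal hemifield", {
  s <- double_pole_sample(c(-90, 90), c(-55, 85), 2000, seed = 1)
  expect_equal(nrow(s), 2000)
  expect_true(all(abs(s$target_az_deg) + abs(s$target_el_deg) <= 90))
  line <- double_pole_sample(c(0, 0), c(-50, 60), 100, seed = 1)
  expect_true(all(line$target_az_deg == 0))
  expect_error(double_pole_sample(c(80, 90), c(70, 85), 10), "empty feasible")
  # uniformity over the feasible region: the fraction of upward targets
  # equals the analytic area ratio 8075/14950 for the [-90,90] x [-55,85] box
  big <- double_pole_sample(c(-90, 90), c(-55, 85), 10000, seed = 2)
  frac_up <- mean(big$target_el_deg > 0)
  p0 <- 8075 / 14950
  expect_lt(abs(frac_up - p0), 3 * sqrt(p0 * (1 - p0) / 10000))
})
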