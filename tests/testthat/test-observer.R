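test_that("sensory spectrum is HRTF plus stimulus plus noise", {
  gwn <- stimulus_spectrum("GWN", fix_axis)
  row20 <- fix_hrtf$gain_db[fix_hrtf$elevations == 20, ]
  s <- sensory_spectrum(gwn, fix_hrtf, 20, noise_sd = 0)
  expect_equal(s$gain_db, row20)
  bs <- stimulus_spectrum("BS35", fix_axis)
  s2 <- sensory_spectrum(bs, fix_hrtf, 20, noise_sd = 0)
  f <- as.numeric(fix_axis)
  expect_equal(s2$gain_db, row20 + ifelse(f >= 6000 & f <= 9000, -35, 0))
  # per-band Gaussian residuals with sample sd near the nominal level
  r1 <- sensory_spectrum(gwn, fix_hrtf, 20, noise_sd = 1, seed = 1)$gain_db - row20
  r2 <- sensory_spectrum(gwn, fix_hrtf, 20, noise_sd = 1, seed = 2)$gain_db - row20
  expect_false(identical(r1, r2))
  expect_lt(abs(sd(r1) - 1), 0.35)  # n = 64 bands
  # off-grid elevations are interpolated between neighbouring rows
  mid <- sensory_spectrum(gwn, fix_hrtf, 22.5, noise_sd = 0)$gain_db
  expect_equal(mid, 0.5 * row20 + 0.5 * fix_hrtf$gain_db[fix_hrtf$elevations == 25, ])
  other <- stimulus_spectrum("GWN", freq_axis(200, 20000, 32))
  expect_error(sensory_spectrum(other, fix_hrtf, 20), "axes")
})

test_that("weighting acts multiplicatively on the centred spectrum", {
  s <- sensory_spectrum(stimulus_spectrum("GWN", fix_axis), fix_hrtf, 0, 0)
  centred <- s$gain_db - mean(s$gain_db)
  expect_equal(apply_weights(rep(1, 64), s)$gain_db, centred)
  expect_equal(apply_weights(rep(0, 64), s)$gain_db, rep(0, 64))
  w <- rep(1, 64); w[10] <- 0.5
  expect_equal(apply_weights(w, s)$gain_db[10], centred[10] / 2)
  expect_equal(apply_weights(w, s)$gain_db[-10], centred[-10])
  expect_error(apply_weights(rep(1.5, 64), s), "\\[0, 1\\]")
})

test_that("template correlation is the band-restricted Pearson r", {
  # toy: weighted spectrum (1,2,3) against rows (1,2,3) and (3,2,1)
  tm <- toy_templates(rbind(c(1, 2, 3), c(3, 2, 1)))
  sp <- soundelev:::new_spectrum_profile(tm$axis, c(1, 2, 3))
  co <- correlation_function(sp, tm, band = c(3000, 10000))
  expect_equal(co$correlation, c(1, -1))
  expect_false(attr(co, "degenerate"))
  # self-correlation of an actual template row
  row <- soundelev:::new_spectrum_profile(fix_axis, fix_hrtf$gain_db[5, ])
  co2 <- correlation_function(row, fix_hrtf, band = c(3500, 14000))
  expect_equal(co2$correlation[5], 1)
  expect_true(all(co2$correlation <= 1 & co2$correlation >= -1))
  # negated row anti-correlates perfectly with itself
  neg <- soundelev:::new_spectrum_profile(fix_axis, -fix_hrtf$gain_db[5, ])
  expect_equal(correlation_function(neg, fix_hrtf)$correlation[5], -1)
  # a flat spectrum cannot be correlated: flagged, not NaN
  flat <- soundelev:::new_spectrum_profile(fix_axis, rep(2, 64))
  co3 <- correlation_function(flat, fix_hrtf)
  expect_true(attr(co3, "degenerate"))
  expect_true(all(is.finite(co3$correlation)))
  expect_error(correlation_function(sp, tm, band = c(3900, 4100)), "3 bands")
})

test_that("rectified likelihood normalises and falls back to uniform", {
  expect_equal(as.numeric(likelihood_from_correlation(c(-0.5, 0.5), beta = 1)),
               c(0, 1))
  l <- likelihood_from_correlation(c(-0.3, -0.9), beta = 2)
  expect_equal(as.numeric(l), c(0.5, 0.5))
  expect_true(attr(l, "uniform_fallback"))
  expect_equal(as.numeric(likelihood_from_correlation(c(0.2, 0.8), beta = 2)),
               c(0.04, 0.64) / 0.68)
  expect_error(likelihood_from_correlation(c(0.2, 0.8), beta = 0.5), "beta")
  expect_error(likelihood_from_correlation(c(1.5, 0)), "\\[-1, 1\\]")
})

test_that("posterior combines likelihood and Gaussian prior", {
  el <- seq(-50, 50, 10)
  lik <- rep(1 / length(el), length(el))
  pc <- posterior_curve(lik, sigma_prior = 20, elevations = el)
  expect_equal(sum(pc$posterior), 1, tolerance = 1e-9)
  prior <- dnorm(el, 0, 20)
  expect_equal(pc$posterior, prior / sum(prior))
  # flat-prior limit: posterior equals the likelihood
  lik2 <- likelihood_from_correlation(seq(-0.5, 0.5, length.out = length(el)), 2)
  pc2 <- posterior_curve(as.numeric(lik2), 1e6, el)
  expect_equal(pc2$posterior, as.numeric(lik2), tolerance = 1e-6)
  # point-mass likelihood survives the product
  delta <- as.numeric(el == 40)
  expect_equal(map_estimate(posterior_curve(delta, 20, el)), 40)
  expect_error(posterior_curve(rep(0.3, length(el)), 20, el), "normalised")
})

test_that("MAP estimate breaks ties toward the prior mean, then downward", {
  el <- seq(-50, 50, 10)
  uni <- posterior_curve(rep(1 / 11, 11), 1e6, el)
  expect_equal(map_estimate(uni), 0)
  bimodal <- c(-20, 30)
  lik <- as.numeric(el %in% bimodal) / 2
  expect_equal(map_estimate(posterior_curve(lik, 1e6, el)), -20)
})

test_that("estimation is veridical for flat spectra without noise", {
  gwn <- stimulus_spectrum("GWN", fix_axis)
  est <- vapply(fix_hrtf$elevations,
                function(e) localize(fix_obs_ideal, gwn, e)$estimate,
                numeric(1))
  expect_identical(est, fix_hrtf$elevations)
})

test_that("closed-form gain and variance follow the shrinkage algebra", {
  expect_equal(closed_form_gain_var(0, 30), tibble::tibble(gain = 1, variance = 0))
  cf <- closed_form_gain_var(12, 12)
  expect_equal(cf$gain, 0.5)
  expect_equal(cf$variance, 12^2 / 4)
  cf2 <- closed_form_gain_var(2, 1)
  expect_equal(cf2$gain, 0.2)
  expect_equal(cf2$variance, 0.16)
  expect_error(closed_form_gain_var(2, 0), "sigma_p")
  # shrinkage monotonicity on the closed form
  g_eps <- closed_form_gain_var(seq(0, 40, 5), 30)$gain
  expect_true(all(diff(g_eps) < 0))
  g_p <- closed_form_gain_var(15, seq(5, 60, 5))$gain
  expect_true(all(diff(g_p) > 0))
})

test_that("Gaussian MAP simulation reproduces the noiseless limit exactly", {
  sim <- simulate_map_trials(0, 30, n_trials = 500, seed = 3)
  expect_identical(sim$response, sim$target)
})

test_that("effective sensory sigma orders stimuli by spectral information", {
  gwn <- stimulus_spectrum("GWN", fix_axis)
  lp6 <- stimulus_spectrum("LP6", fix_axis)
  s_gwn <- effective_sensory_sigma(fix_obs, gwn, n_trials = 150, seed = 2)
  s_lp6 <- effective_sensory_sigma(fix_obs, lp6, n_trials = 150, seed = 2)
  expect_lt(s_gwn, s_lp6)
  # noiseless limit: the averaged likelihood collapses to within a grid step
  obs0 <- observer(fix_hrtf, sensory_noise_sd = 0, internal_noise_sd = 0)
  expect_lte(effective_sensory_sigma(obs0, gwn, n_trials = 100, seed = 1), 5)
  # more acoustic noise widens the likelihood
  obs2 <- observer(fix_hrtf, sensory_noise_sd = 6)
  expect_gt(effective_sensory_sigma(obs2, gwn, n_trials = 150, seed = 2), s_gwn)
  expect_error(effective_sensory_sigma(fix_obs, gwn, n_trials = 50), "n_trials")
})
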