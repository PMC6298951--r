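#' Default spectral weighting profile
#'
#' The weighting function w(f) expresses the observer's confidence in each
#' frequency band as a carrier of elevation information. The naive (untrained)
#' profile is non-monotonic with its maximum inside the 5-10 kHz notch band:
#' the prominent notch cues are trusted most, while the weak low-frequency
#' cues and the erratic high frequencies start out down-weighted. Perceptual
#' learning acts by raising the weights of informative but initially
#' under-trusted bands.
#'
#' The profile is an asymmetric Gaussian in log-frequency: it falls off
#' steeply below the peak (the weak low-frequency cues start heavily
#' discounted - these are the weights that perceptual training raises) and
#' more gradually above it (the high-frequency cues retain moderate naive
#' trust).
#'
#' @param axis A [freq_axis()].
#' @param base Baseline weight far from the peak (in `[0, 1)`).
#' @param peak_freq Frequency of maximal weight, Hz (default 7 kHz, the centre
#'   of the notch band).
#' @param width_low_oct Gaussian width below the peak, octaves.
#' @param width_high_oct Gaussian width above the peak, octaves.
#' @return Numeric weight vector in `[0, 1]`, one value per band.
#' @export
default_weight_profile <- function(axis = freq_axis(), base = 0.10,
                                   peak_freq = 7500, width_low_oct = 0.18,
                                   width_high_oct = 0.3) {
  f <- unclass(axis)
  d <- log2(f / peak_freq)
  wd <- ifelse(d < 0, width_low_oct, width_high_oct)
  w <- base + (1 - base) * exp(-0.5 * (d / wd)^2)
  pmin(pmax(w, 0), 1)
}

#' Construct a Bayesian spectral-cue observer
#'
#' Bundles everything the elevation estimator needs: the stored HRTF templates,
#' the spectral weighting profile, the Gaussian spatial prior (mean fixed at
#' 0 deg elevation, i.e. straight ahead), the per-band sensory noise level, the
#' analysis band over which spectra are compared, and the sharpness exponent
#' that maps rectified correlations to likelihoods.
#'
#' @param templates An `hrtf_set` of stored templates (by default the observer
#'   knows its own true filters).
#' @param weights Per-band weight vector in `[0, 1]`; defaults to
#'   [default_weight_profile()] on the template axis.
#' @param sigma_prior Standard deviation of the Gaussian prior on source
#'   elevation, degrees (> 0).
#' @param sensory_noise_sd Acoustic sensory noise: i.i.d. Gaussian dB noise
#'   added to each band of the sensory spectrum before weighting (>= 0); its
#'   per-band sd grows for attenuated bands, see [sensory_spectrum()].
#' @param internal_noise_sd Internal (post-weighting) noise: i.i.d. Gaussian
#'   dB noise of fixed sd added to the weighted spectrum at the template
#'   comparison stage (>= 0). Because this noise is not scaled by the
#'   weights, down-weighting a band genuinely discards its information -
#'   which is what makes the spectral weights behaviourally consequential
#'   and gives weight learning its leverage.
#' @param beta Likelihood sharpness exponent (>= 1): the rectified correlation
#'   is raised to this power before normalisation.
#' @param analysis_band Frequency interval over which the weighted sensory
#'   spectrum is cross-correlated with the templates, Hz.
#' @return An `observer_state` object.
#' @export
observer <- function(templates = synth_hrtf(),
                     weights = default_weight_profile(templates$axis),
                     sigma_prior = 30,
                     sensory_noise_sd = 3,
                     internal_noise_sd = 2,
                     beta = 10,
                     analysis_band = c(3500, 14000)) {
  stopifnot(inherits(templates, "hrtf_set"))
  check_weights(weights, templates$axis)
  if (!is.numeric(sigma_prior) || sigma_prior <= 0)
    stop("sigma_prior must be > 0", call. = FALSE)
  if (sensory_noise_sd < 0) stop("sensory_noise_sd must be >= 0", call. = FALSE)
  if (internal_noise_sd < 0) stop("internal_noise_sd must be >= 0", call. = FALSE)
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  f <- unclass(templates$axis)
  if (analysis_band[1] < min(f) || analysis_band[2] > max(f))
    stop("analysis_band outside the template frequency axis", call. = FALSE)
  if (sum(in_band(templates$axis, analysis_band)) < 3)
    stop("fewer than 3 bands inside the analysis band", call. = FALSE)
  structure(list(templates = templates, weights = as.numeric(weights),
                 prior_mean = 0, sigma_prior = sigma_prior,
                 sensory_noise_sd = sensory_noise_sd,
                 internal_noise_sd = internal_noise_sd, beta = beta,
                 analysis_band = as.numeric(analysis_band)),
            class = "observer_state")
}

check_weights <- function(weights, axis) {
  if (length(weights) != length(axis))
    stop("weight profile length must match the frequency axis", call. = FALSE)
  if (any(!is.finite(weights)) || any(weights < 0 | weights > 1))
    stop("all weights must lie in [0, 1]", call. = FALSE)
  invisible(weights)
}

#' @export
print.observer_state <- function(x, ...) {
  cat(sprintf(paste0("<observer_state> %d templates, sigma_prior=%g deg, ",
                     "noise=%g dB, beta=%g, band=[%g, %g] Hz\n"),
              length(x$templates$elevations), x$sigma_prior,
              x$sensory_noise_sd, x$beta, x$analysis_band[1], x$analysis_band[2]))
  invisible(x)
}

#' Sensory spectrum of one trial
#'
#' The proximal stimulus at the eardrum, in the log-magnitude band domain:
#' the stimulus spectrum X(f) plus the true HRTF row H(f; elevation) of the
#' source (linearly interpolated between grid elevations when needed), plus
#' zero-mean Gaussian noise per band. With `noise_sd = 0` the exact sum is
#' returned.
#'
#' The effective sensory noise per band grows as the band's level drops
#' towards threshold: the per-band noise sd is `noise_sd * 10^(-X(f)/40)` for
#' attenuated bands (`X(f) < 0`) and `noise_sd` at reference level. The
#' compressive exponent (half the physical inverse-level scaling) reflects
#' the near-miss-to-Weber growth of intensity discrimination thresholds at
#' low sensation levels: a 15-dB attenuation roughly doubles the dB-domain
#' noise, degrading but not destroying the band's spectral-shape cue.
#'
#' @param stimulus A `spectrum_profile`.
#' @param world The true `hrtf_set` of the simulated listener.
#' @param true_elev Source elevation, degrees (within the world grid).
#' @param noise_sd Per-band noise sd at reference (0 dB) band level, dB.
#' @param seed Optional integer seed; `NULL` uses the ambient RNG stream.
#' @return A `spectrum_profile` (kind `"sensory"`).
#' @export
sensory_spectrum <- function(stimulus, world, true_elev, noise_sd = 0,
                             seed = NULL) {
  stopifnot(inherits(stimulus, "spectrum_profile"), inherits(world, "hrtf_set"))
  if (!same_axis(stimulus$axis, world$axis))
    stop("stimulus and world are on different frequency axes", call. = FALSE)
  g <- hrtf_row(world, true_elev) + stimulus$gain_db
  if (noise_sd > 0) {
    sd_band <- noise_sd * 10^(-pmin(stimulus$gain_db, 0) / 40)
    noise <- if (is.null(seed)) stats::rnorm(length(g), 0, sd_band)
             else withr::with_seed(seed, stats::rnorm(length(g), 0, sd_band))
    g <- g + noise
  }
  out <- new_spectrum_profile(world$axis, g, "sensory")
  out$stim_kind <- stimulus$kind
  out$stim_gain_db <- stimulus$gain_db
  out
}

#' Apply the spectral weighting function
#'
#' Multiplies each band of the mean-centred sensory spectrum by its weight.
#' Centring (over the analysis band, or the full axis if `band` is `NULL`)
#' makes the operation independent of the arbitrary 0-dB reference: partial
#' weighting then attenuates a band's influence on the downstream correlation
#' rather than dragging its value toward the reference level.
#'
#' @param weights Per-band weights in `[0, 1]`.
#' @param sensory A `spectrum_profile`.
#' @param band Optional interval `c(lo, hi)` in Hz over which the centring
#'   mean is taken.
#' @return A `spectrum_profile` of the weighted, centred spectrum.
#' @export
apply_weights <- function(weights, sensory, band = NULL) {
  stopifnot(inherits(sensory, "spectrum_profile"))
  check_weights(weights, sensory$axis)
  g <- sensory$gain_db
  keep <- if (is.null(band)) rep(TRUE, length(g)) else in_band(sensory$axis, band)
  new_spectrum_profile(sensory$axis, weights * (g - mean(g[keep])), "weighted")
}

#' Correlation of a weighted spectrum with the stored templates
#'
#' Pearson correlation between the weighted sensory spectrum and each stored
#' HRTF row, both restricted to the bands inside `band`. This is the template
#' matching stage: elevations whose filters resemble the evidence score high.
#' A zero-variance (flat) input over the band cannot be correlated; the result
#' is then flagged degenerate (all correlations zero) rather than NaN.
#'
#' @param weighted A `spectrum_profile` (typically from [apply_weights()]).
#' @param templates An `hrtf_set`.
#' @param band Interval `c(lo, hi)` in Hz; needs at least 3 bands inside.
#' @return A tibble with columns `elevation` and `correlation`, with attribute
#'   `degenerate` (logical).
#' @export
correlation_function <- function(weighted, templates, band = c(3500, 14000)) {
  stopifnot(inherits(weighted, "spectrum_profile"), inherits(templates, "hrtf_set"))
  keep <- in_band(templates$axis, band)
  if (sum(keep) < 3) stop("fewer than 3 bands in the interval", call. = FALSE)
  x <- weighted$gain_db[keep]
  degenerate <- stats::sd(x) < 1e-12
  r <- if (degenerate) rep(0, length(templates$elevations))
       else as.numeric(stats::cor(x, t(templates$gain_db[, keep, drop = FALSE])))
  out <- tibble::tibble(elevation = templates$elevations, correlation = r)
  attr(out, "degenerate") <- degenerate
  out
}

#' Likelihood from a rectified correlation function
#'
#' Only positive correlations can indicate the true source elevation, so the
#' correlation function is rectified at zero, raised to the sharpness exponent
#' `beta`, and normalised to unit sum. If no correlation is positive the trial
#' carries no usable spectral evidence and the likelihood falls back to
#' uniform (the prior then decides); such trials are flagged.
#'
#' @param correlation Numeric vector of per-elevation correlations in `[-1, 1]`
#'   (or the tibble returned by [correlation_function()]).
#' @param beta Sharpness exponent, >= 1.
#' @return Numeric likelihood vector summing to 1, with attribute
#'   `uniform_fallback` (logical).
#' @export
likelihood_from_correlation <- function(correlation, beta = 4) {
  if (is.data.frame(correlation)) correlation <- correlation$correlation
  if (beta < 1) stop("beta must be >= 1", call. = FALSE)
  if (any(correlation < -1 - 1e-9 | correlation > 1 + 1e-9))
    stop("correlations must lie in [-1, 1]", call. = FALSE)
  l <- pmax(correlation, 0)^beta
  s <- sum(l)
  if (s <= 0) {
    l <- rep(1 / length(l), length(l))
    attr(l, "uniform_fallback") <- TRUE
  } else {
    l <- l / s
    attr(l, "uniform_fallback") <- FALSE
  }
  l
}

#' Posterior over source elevation
#'
#' Pointwise product of the (normalised) likelihood with the Gaussian prior
#' density evaluated on the elevation grid, renormalised to unit sum.
#'
#' @param likelihood Normalised likelihood vector over `elevations`.
#' @param sigma_prior Prior sd in degrees; values >= 1e6 behave as a flat prior.
#' @param elevations Elevation grid, degrees.
#' @param prior_mean Prior mean, degrees (fixed at 0 in the model; exposed for
#'   completeness).
#' @param correlation Optional correlation vector to carry along in the curve.
#' @return A `posterior_curve`: tibble with columns `elevation`,
#'   `correlation`, `likelihood`, `posterior` (posterior sums to 1).
#' @export
posterior_curve <- function(likelihood, sigma_prior, elevations,
                            prior_mean = 0, correlation = NA_real_) {
  stopifnot(length(likelihood) == length(elevations))
  if (abs(sum(likelihood) - 1) > 1e-6)
    stop("likelihood must be normalised to unit sum", call. = FALSE)
  prior <- stats::dnorm(elevations, prior_mean, sigma_prior)
  post <- as.numeric(likelihood) * prior
  s <- sum(post)
  if (s <= 0) stop("all-zero posterior product", call. = FALSE)
  out <- tibble::tibble(elevation = as.numeric(elevations),
                        correlation = correlation,
                        likelihood = as.numeric(likelihood),
                        posterior = post / s)
  attr(out, "prior_mean") <- prior_mean
  class(out) <- c("posterior_curve", class(out))
  out
}

#' Maximum a-posteriori elevation estimate
#'
#' The elevation of the posterior maximum. Ties (plateaus) are broken by the
#' smallest absolute distance to the prior mean, then by the lower elevation.
#'
#' @param curve A `posterior_curve`.
#' @return Elevation estimate in degrees (scalar).
#' @export
map_estimate <- function(curve) {
  stopifnot(inherits(curve, "posterior_curve"))
  prior_mean <- attr(curve, "prior_mean") %||% 0
  p <- curve$posterior
  el <- curve$elevation
  tied <- which(p >= max(p) - 1e-12)
  if (length(tied) > 1) {
    d <- abs(el[tied] - prior_mean)
    tied <- tied[d == min(d)]
  }
  el[min(tied)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Effective comparison band for a stimulus: the analysis band intersected
# with the bands where the input actually carries audible spectral shape -
# the template comparison runs only over bands defined by the input. Bands
# attenuated more than 20 dB below the stimulus peak (the out-of-band floor
# of LP6, the 6-9 kHz trough of BS25/BS35) are excluded; milder attenuation
# (BS15) keeps the band, at its degraded signal-to-noise ratio.
effective_band_idx <- function(obs, stimulus, audible_db = 20) {
  g <- stimulus$gain_db
  in_band(obs$templates$axis, obs$analysis_band) & (g > max(g) - audible_db)
}

# Fast numeric single-trial estimator used by the session simulators.
# sens_gain: raw sensory spectrum (dB per band). The weighted spectrum is
# perturbed by the fixed-magnitude internal comparison noise (unless
# internal = FALSE, used by the deterministic re-runs inside weight updates).
# Returns estimate, confidence (peak posterior mass), degenerate flag,
# likelihood mode, posterior mean.
trial_estimate <- function(obs, sens_gain, keep, internal = TRUE) {
  el <- obs$templates$elevations
  x <- sens_gain - mean(sens_gain[keep])
  xw <- (obs$weights * x)[keep]
  if (internal && obs$internal_noise_sd > 0)
    xw <- xw + stats::rnorm(length(xw), 0, obs$internal_noise_sd)
  degenerate <- stats::sd(xw) < 1e-12
  if (degenerate) {
    r <- rep(0, length(el))
  } else {
    r <- as.numeric(stats::cor(xw, t(obs$templates$gain_db[, keep, drop = FALSE])))
  }
  l <- pmax(r, 0)^obs$beta
  s <- sum(l)
  if (s <= 0) {
    l <- rep(1 / length(l), length(l))
    degenerate <- TRUE
  } else l <- l / s
  post <- l * stats::dnorm(el, obs$prior_mean, obs$sigma_prior)
  post <- post / sum(post)
  tied <- which(post >= max(post) - 1e-12)
  if (length(tied) > 1) {
    d <- abs(el[tied] - obs$prior_mean)
    tied <- tied[d == min(d)]
  }
  lmode <- which(l >= max(l) - 1e-12)
  if (length(lmode) > 1) {
    d <- abs(el[lmode] - obs$prior_mean)
    lmode <- lmode[d == min(d)]
  }
  list(estimate = el[min(tied)], confidence = max(post),
       degenerate = degenerate, lik_mode = el[min(lmode)],
       post_mean = sum(post * el), correlation = r, likelihood = l,
       posterior = post)
}

#' Localise a single sound
#'
#' Runs the full estimator pipeline for one trial: sensory spectrum (stimulus
#' plus true HRTF plus noise), spectral weighting, template correlation,
#' rectified likelihood, Bayesian combination with the prior, and the MAP
#' decision.
#'
#' @param obs An `observer_state`.
#' @param stimulus A `spectrum_profile`.
#' @param true_elev True source elevation, degrees.
#' @param world True `hrtf_set` (defaults to the observer's own templates).
#' @param seed Optional seed for the sensory noise.
#' @return A list of class `localization`: `estimate` (deg), `confidence`
#'   (peak posterior mass), `degenerate` (flag), `curve` (a `posterior_curve`).
#' @examples
#' obs <- observer(synth_hrtf(axis = freq_axis(n_bands = 32)))
#' localize(obs, stimulus_spectrum("GWN", obs$templates$axis), 20, seed = 1)$estimate
#' @export
localize <- function(obs, stimulus, true_elev, world = obs$templates,
                     seed = NULL) {
  stopifnot(inherits(obs, "observer_state"))
  sens <- sensory_spectrum(stimulus, world, true_elev,
                           noise_sd = obs$sensory_noise_sd, seed = seed)
  keep <- effective_band_idx(obs, stimulus)
  tr <- trial_estimate(obs, sens$gain_db, keep)
  curve <- posterior_curve(tr$likelihood, obs$sigma_prior,
                           obs$templates$elevations,
                           prior_mean = obs$prior_mean,
                           correlation = tr$correlation)
  structure(list(estimate = tr$estimate, confidence = tr$confidence,
                 degenerate = tr$degenerate, lik_mode = tr$lik_mode,
                 post_mean = tr$post_mean, curve = curve),
            class = "localization")
}

#' Closed-form response gain and variance of the Gaussian MAP estimator
#'
#' For a Gaussian likelihood of width `sigma_eps` centred on the (noisy)
#' sensory observation and a Gaussian prior of width `sigma_p`, the MAP
#' estimate shrinks toward the prior mean, giving
#' `gain = 1 / (1 + sigma_eps^2 / sigma_p^2)` and response variance
#' `sigma_eps^2 / (1 + sigma_eps^2 / sigma_p^2)^2`. Without sensory noise the
#' gain is 1 and the variance 0; when the sensory noise is comparable to the
#' prior uncertainty the gain drops well below 1 (the hallmark of responses to
#' spectrally poor stimuli).
#'
#' @param sigma_eps Sensory (likelihood) width, degrees, >= 0.
#' @param sigma_p Prior width, degrees, > 0.
#' @return A tibble with columns `gain` (dimensionless) and `variance` (deg^2).
#' @examples
#' closed_form_gain_var(2, 1) # gain 0.2, variance 0.16
#' @export
closed_form_gain_var <- function(sigma_eps, sigma_p) {
  if (any(sigma_p <= 0)) stop("sigma_p must be > 0", call. = FALSE)
  if (any(sigma_eps < 0)) stop("sigma_eps must be >= 0", call. = FALSE)
  g <- 1 / (1 + sigma_eps^2 / sigma_p^2)
  tibble::tibble(gain = g, variance = sigma_eps^2 * g^2)
}

#' Monte-Carlo simulation of the Gaussian MAP estimator
#'
#' Numerical counterpart of [closed_form_gain_var()]: on each trial a target
#' is drawn, the sensory observation is the target plus Gaussian noise of sd
#' `sigma_eps`, the Gaussian likelihood around the observation is multiplied
#' by the Gaussian prior on a fine elevation grid, and the grid argmax is the
#' response. The stimulus-response regression gain and residual variance of
#' the simulated responses can then be compared against the closed form.
#'
#' @param sigma_eps Likelihood width, degrees (0 gives a delta likelihood).
#' @param sigma_p Prior width, degrees.
#' @param n_trials Number of trials.
#' @param seed Integer seed.
#' @param target_range Targets are drawn uniformly from grid points in this
#'   range, degrees.
#' @param grid_step Elevation grid step, degrees.
#' @return A tibble with columns `target` and `response`.
#' @export
simulate_map_trials <- function(sigma_eps, sigma_p, n_trials = 10000,
                                seed = 1, target_range = c(-60, 60),
                                grid_step = 0.5) {
  grid <- seq(-150, 150, by = grid_step)
  withr::with_seed(seed, {
    pool <- grid[grid >= target_range[1] & grid <= target_range[2]]
    targets <- sample(pool, n_trials, replace = TRUE)
    obs <- targets + if (sigma_eps > 0) stats::rnorm(n_trials, 0, sigma_eps) else 0
    log_prior <- -grid^2 / (2 * sigma_p^2)
    resp <- if (sigma_eps == 0) {
      # delta likelihood: posterior mass only at the grid point nearest the
      # observation
      grid[vapply(obs, function(o) which.min(abs(grid - o)), integer(1))]
    } else {
      vapply(obs, function(o) {
        grid[which.max(-(grid - o)^2 / (2 * sigma_eps^2) + log_prior)]
      }, numeric(1))
    }
    tibble::tibble(target = targets, response = resp)
  })
}

#' Effective sensory noise of an observer-stimulus pairing
#'
#' Operationalises the likelihood width that enters the closed-form gain
#' expression: simulates `n_trials` likelihood curves for a source at 0 deg,
#' averages them, and returns the sd of a Gaussian fitted (least squares) to
#' the trial-averaged likelihood. Spectrally rich stimuli give narrow average
#' likelihoods (small effective sigma); impoverished stimuli like LP6 give
#' broad ones, comparable to the prior width.
#'
#' @param obs An `observer_state`.
#' @param stimulus A `spectrum_profile`.
#' @param n_trials Number of simulated trials (>= 100).
#' @param seed Integer seed.
#' @return Effective likelihood sd in degrees (scalar).
#' @export
effective_sensory_sigma <- function(obs, stimulus, n_trials = 200, seed = 1) {
  stopifnot(inherits(obs, "observer_state"), n_trials >= 100)
  keep <- effective_band_idx(obs, stimulus)
  el <- obs$templates$elevations
  withr::with_seed(seed, {
    acc <- numeric(length(el))
    n_deg <- 0
    for (i in seq_len(n_trials)) {
      sens <- sensory_spectrum(stimulus, obs$templates, 0,
                               noise_sd = obs$sensory_noise_sd)
      tr <- trial_estimate(obs, sens$gain_db, keep)
      if (tr$degenerate) n_deg <- n_deg + 1
      acc <- acc + tr$likelihood
    }
    if (n_deg > n_trials / 2)
      stop("degenerate uniform likelihoods in more than half of the trials",
           call. = FALSE)
    lbar <- acc / n_trials
    mu0 <- sum(el * lbar)
    sd0 <- sqrt(max(sum((el - mu0)^2 * lbar), 1e-6))
    fit <- tryCatch(
      stats::nls(y ~ a * exp(-(x - m)^2 / (2 * s^2)),
                 data = data.frame(x = el, y = lbar),
                 start = list(a = max(lbar), m = mu0, s = sd0),
                 control = stats::nls.control(warnOnly = TRUE)),
      error = function(e) NULL)
    if (is.null(fit)) sd0 else abs(stats::coef(fit)[["s"]])
  })
}
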