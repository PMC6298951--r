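#' Training-session configuration
#'
#' Configuration of a perceptual-learning session: 432 trials at six fixed
#' midsagittal elevations (72 presentations each, pseudo-random order), with
#' one of two weight-update rules:
#'
#' * `"feedback_delta"` - visual feedback: after each response the true
#'   location is revealed, and the squared elevation error with respect to the
#'   true target drives a gradient step on the spectral weights;
#' * `"exposure_selfconsistency"` - no feedback: the teaching signal is the
#'   mode of the trial's own sensory likelihood (the evidence peak), scaled by
#'   the trial's confidence (peak posterior mass), so that repeated exposure
#'   to consistent weak cues gradually boosts their weights.
#'
#' @param rule Update rule, see above.
#' @param learning_rate Per-trial weight-step norm, > 0 (the descent
#'   direction on each trial is normalised to this length). Defaults to 0.03
#'   for the feedback rule and 0.05 for the slower, confidence-scaled
#'   exposure rule.
#' @param n_trials Number of training trials; must be a multiple of the number
#'   of training elevations (default 432 = 72 x 6).
#' @param training_elevations Elevations of the training speakers, degrees,
#'   all at azimuth 0.
#' @param training_stimulus Stimulus kind used throughout the session
#'   (`"BS35"` for feedback training, `"LP6"` for feedback-free exposure).
#' @param seed Integer seed for the whole session (target order and noise).
#' @return A `learning_config` list.
#' @export
learning_config <- function(rule = c("feedback_delta", "exposure_selfconsistency"),
                            learning_rate = NULL,
                            n_trials = 432,
                            training_elevations = c(60, 40, 20, -10, -30, -50),
                            training_stimulus = NULL,
                            seed = 1L) {
  rule <- match.arg(rule)
  if (is.null(learning_rate))
    learning_rate <- if (rule == "feedback_delta") 0.03 else 0.05
  if (learning_rate < 0) stop("learning_rate must be >= 0", call. = FALSE)
  if (is.null(training_stimulus))
    training_stimulus <- if (rule == "feedback_delta") "BS35" else "LP6"
  n_el <- length(training_elevations)
  if (n_trials %% n_el != 0)
    stop("n_trials must be a multiple of the number of training elevations",
         call. = FALSE)
  structure(list(rule = rule, learning_rate = learning_rate,
                 n_trials = as.integer(n_trials),
                 training_elevations = as.numeric(training_elevations),
                 training_stimulus = training_stimulus,
                 seed = as.integer(seed)),
            class = "learning_config")
}

# Finite-difference gradient of the posterior-mean elevation estimate with
# respect to each band weight, on the trial's sensory spectrum. The recorded
# response is the MAP estimate, but the MAP argmax on a discrete template
# grid is piecewise constant in the weights, so its finite difference
# vanishes almost everywhere; the posterior mean is the smooth surrogate the
# gradient is taken on. One internal-noise draw is shared between the base
# and all perturbed re-runs (common random numbers), so that trial-averaged
# steps follow the gradient of the expected loss under the internal noise -
# this is what stops the rule from over-boosting bands whose marginal
# contribution is noise-dominated. Returns list(est0, d_est) where d_est[b]
# is the change in estimate per unit weight of band b (0 outside the band).
estimate_gradient <- function(obs, sens_gain, keep, dw = 0.01) {
  el <- obs$templates$elevations
  x <- sens_gain - mean(sens_gain[keep])
  bands <- which(keep)
  nb <- length(bands)
  w0 <- obs$weights
  # perturbation direction: forward unless the weight is at the upper bound
  dirs <- ifelse(w0[bands] <= 1 - dw, dw, -dw)
  # rows: base profile + one perturbed profile per band in the window
  W <- matrix(rep(w0[bands], nb + 1), nrow = nb + 1, byrow = TRUE)
  W[cbind(2:(nb + 1), seq_len(nb))] <- w0[bands] + dirs
  M <- W * matrix(rep(x[bands], nb + 1), nrow = nb + 1, byrow = TRUE)
  if (obs$internal_noise_sd > 0) {
    eta <- stats::rnorm(nb, 0, obs$internal_noise_sd)
    M <- M + matrix(rep(eta, nb + 1), nrow = nb + 1, byrow = TRUE)
  }
  # row-standardise and correlate with the (band-restricted) templates
  Tm <- obs$templates$gain_db[, bands, drop = FALSE]
  Ms <- M - rowMeans(M)
  msd <- sqrt(rowSums(Ms^2))
  Ts <- Tm - rowMeans(Tm)
  tsd <- sqrt(rowSums(Ts^2))
  if (any(msd < 1e-12) || any(tsd < 1e-12))
    return(list(est0 = NA_real_, d_est = rep(0, length(w0)), degenerate = TRUE))
  corr <- (Ms / msd) %*% t(Ts / tsd)
  L <- pmax(corr, 0)^obs$beta
  rs <- rowSums(L)
  if (any(rs <= 0))
    return(list(est0 = NA_real_, d_est = rep(0, length(w0)), degenerate = TRUE))
  prior <- stats::dnorm(el, obs$prior_mean, obs$sigma_prior)
  P <- L * matrix(rep(prior, nb + 1), nrow = nb + 1, byrow = TRUE)
  est <- as.numeric((P %*% el) / rowSums(P))
  d_est <- rep(0, length(w0))
  d_est[bands] <- (est[-1] - est[1]) / dirs
  list(est0 = est[1], d_est = d_est, degenerate = FALSE)
}

# Raw descent direction on (teacher - estimate)^2 for one trial:
# 2 * err * d_est over the stimulus' effective band, times `scale`.
# Returns list(dir, skipped).
update_direction <- function(obs, stimulus, teacher, sensory, scale = 1) {
  keep <- effective_band_idx(obs, stimulus)
  sens0 <- trial_sensory_gain(obs, stimulus, sensory, teacher)
  gr <- estimate_gradient(obs, sens0, keep)
  if (gr$degenerate || !is.finite(gr$est0))
    return(list(dir = NULL, skipped = TRUE))
  err <- teacher - gr$est0
  # a solved trial contributes no step (and must not be blown up by the
  # normalisation in descent_step)
  if (abs(err) < 1e-9)
    return(list(dir = rep(0, length(obs$weights)), skipped = FALSE))
  list(dir = scale * 2 * err * gr$d_est, skipped = FALSE)
}

#' Feedback-driven weight update
#'
#' One gradient-descent step on the squared elevation error with respect to
#' the visually revealed true target. The gradient of each band weight is a
#' finite difference (perturbation 0.01) of the estimator re-run on the
#' trial's sensory spectrum (held fixed; no fresh noise is drawn inside the
#' update); steps are clipped (at 0.05 per band) and the updated weights to
#' `[0, 1]`. A zero-error trial leaves the weights unchanged, as does
#' `learning_rate = 0`.
#'
#' @param obs An `observer_state`.
#' @param stimulus The trial's `spectrum_profile`.
#' @param true_elev True target elevation revealed by the feedback, degrees.
#' @param learning_rate Step size, >= 0.
#' @param sensory The trial's sensory spectrum (a `spectrum_profile`, or the
#'   numeric per-band gains); defaults to the exact (noise-free) spectrum of
#'   the trial's target.
#' @param response The trial's recorded MAP response (optional; it does not
#'   enter the gradient, which re-runs the estimator).
#' @return Updated weight vector in `[0, 1]`; attribute `skipped` is `TRUE`
#'   when a degenerate likelihood prevented the update.
#' @export
update_weights_feedback <- function(obs, stimulus, true_elev, learning_rate,
                                    sensory = NULL, response = NULL) {
  stopifnot(learning_rate >= 0)
  w <- obs$weights
  if (learning_rate == 0) return(structure(w, skipped = FALSE))
  d <- update_direction(obs, stimulus, true_elev, sensory)
  if (d$skipped) return(structure(w, skipped = TRUE))
  structure(descent_step(w, d$dir, learning_rate), skipped = FALSE)
}

# Normalised gradient-descent step: the descent direction is rescaled to a
# fixed step norm (learning_rate, in weight units per trial). Normalising
# makes each trial contribute a bounded weight change, so noise-driven
# directions cancel over the session while consistently informative bands
# accumulate.
descent_step <- function(w, dir, learning_rate, max_norm = 0.05) {
  nrm <- sqrt(sum(dir^2))
  if (nrm < 1e-12) return(w)
  step <- min(learning_rate, max_norm) * dir / nrm
  pmin(pmax(w + step, 0), 1)
}

#' Exposure-driven (feedback-free) weight update
#'
#' Same gradient step as [update_weights_feedback()], but the teaching signal
#' is internal: the mode of the trial's sensory likelihood (the evidence
#' peak), and the step is scaled by the trial's confidence (its peak posterior
#' mass). Trials whose likelihood fell back to uniform carry no evidence and
#' produce no update.
#'
#' @param obs An `observer_state`.
#' @param stimulus The trial's `spectrum_profile`.
#' @param trial A `localization` (from [localize()]) or a list with elements
#'   `lik_mode`, `confidence` and `degenerate` for the current trial.
#' @param learning_rate Step size, >= 0.
#' @param sensory The trial's sensory spectrum (a `spectrum_profile` or
#'   numeric gains); defaults to the exact spectrum at the trial's evidence
#'   peak.
#' @return Updated weight vector in `[0, 1]`; attribute `skipped` flags
#'   no-update trials.
#' @export
update_weights_exposure <- function(obs, stimulus, trial, learning_rate,
                                    sensory = NULL) {
  stopifnot(learning_rate >= 0)
  w <- obs$weights
  if (learning_rate == 0 || isTRUE(trial$degenerate))
    return(structure(w, skipped = isTRUE(trial$degenerate)))
  d <- update_direction(obs, stimulus, trial$lik_mode, sensory,
                        scale = trial$confidence)
  if (d$skipped) return(structure(w, skipped = TRUE))
  structure(descent_step(w, d$dir, learning_rate), skipped = FALSE)
}

# The spectrum the weight update differentiates on: the trial's realised
# sensory spectrum if given, otherwise the exact spectrum of `elev`.
trial_sensory_gain <- function(obs, stimulus, sensory, elev) {
  if (!is.null(sensory)) {
    if (inherits(sensory, "spectrum_profile")) sensory$gain_db
    else as.numeric(sensory)
  } else {
    el <- min(max(elev, min(obs$templates$elevations)),
              max(obs$templates$elevations))
    hrtf_row(obs$templates, el) + stimulus$gain_db
  }
}

# Balanced pseudo-random schedule: shuffled blocks of the training elevations,
# reshuffled per block. Each elevation appears exactly n_trials/n_el times and
# no elevation repeats more than twice in a row.
training_schedule <- function(elevations, n_trials) {
  n_blocks <- n_trials / length(elevations)
  unlist(lapply(seq_len(n_blocks), function(b) sample(elevations)))
}

#' Simulate a training session
#'
#' Runs a full training session: on each trial a target is drawn from the
#' balanced pseudo-random schedule, a noisy sensory spectrum is generated, the
#' observer localises it (MAP), the trial is recorded, and the weights are
#' updated according to the configured rule. Estimator failures are recorded
#' as flagged trials, never aborting the session.
#'
#' @param obs An `observer_state` (initial state).
#' @param config A [learning_config()].
#' @param world True `hrtf_set` (defaults to the observer's templates).
#' @param az_noise_sd Azimuth response noise sd, degrees. Azimuth is simulated
#'   as a near-noiseless independent channel (the binaural pathway), so
#'   responses are target azimuth plus small Gaussian noise.
#' @param snapshot_every Record a full weight-profile snapshot every this many
#'   trials.
#' @param momentum Consolidation factor in `[0, 1)`: the session integrates
#'   the per-trial descent directions with an exponential moving average
#'   (weight `1 - momentum` on the newest trial) before taking the
#'   normalised step. Averaging over recent trials lets inconsistent,
#'   noise-driven directions cancel while consistently informative bands
#'   accumulate - without it, weak-cue listeners random-walk instead of
#'   learning. `momentum = 0` recovers the memoryless per-trial rule of
#'   [update_weights_feedback()] and [update_weights_exposure()].
#' @return A list of class `training_result`: `trials` (tibble with one row
#'   per trial), `observer` (final state), `weight_snapshots` (tibble: trial,
#'   band `freq_hz`, `weight`), `weight_checksums` (per-trial sum of weights),
#'   `config`.
#' @export
simulate_training_session <- function(obs, config = learning_config(),
                                      world = obs$templates,
                                      az_noise_sd = 2, snapshot_every = 10,
                                      momentum = 0.95) {
  stopifnot(inherits(obs, "observer_state"), inherits(config, "learning_config"))
  stim <- stimulus_spectrum(config$training_stimulus, obs$templates$axis)
  keep <- effective_band_idx(obs, stim)
  f <- as.numeric(unclass(obs$templates$axis))
  withr::with_seed(config$seed, {
    targets <- training_schedule(config$training_elevations, config$n_trials)
    n <- config$n_trials
    resp_el <- conf <- numeric(n)
    degen <- logical(n)
    checksums <- numeric(n)
    dir_ema <- numeric(length(obs$weights))
    snaps <- vector("list", n %/% snapshot_every + 1)
    snap_i <- 0
    for (t in seq_len(n)) {
      sens <- sensory_spectrum(stim, world, targets[t],
                               noise_sd = obs$sensory_noise_sd)
      tr <- trial_estimate(obs, sens$gain_db, keep)
      resp_el[t] <- tr$estimate
      conf[t] <- tr$confidence
      degen[t] <- tr$degenerate
      d <- if (config$rule == "feedback_delta") {
        update_direction(obs, stim, targets[t], sens)
      } else if (tr$degenerate) {
        list(dir = NULL, skipped = TRUE)
      } else {
        update_direction(obs, stim, tr$lik_mode, sens, scale = tr$confidence)
      }
      if (d$skipped) {
        degen[t] <- TRUE
      } else if (config$learning_rate > 0) {
        dir_ema <- momentum * dir_ema + (1 - momentum) * d$dir
        obs$weights <- descent_step(obs$weights, dir_ema, config$learning_rate)
      }
      checksums[t] <- sum(obs$weights)
      if (t %% snapshot_every == 0) {
        snap_i <- snap_i + 1
        snaps[[snap_i]] <- tibble::tibble(trial = t, freq_hz = f,
                                          weight = obs$weights)
      }
    }
    trials <- tibble::tibble(
      trial = seq_len(n), phase = "train", stim_kind = config$training_stimulus,
      target_az_deg = 0, target_el_deg = targets,
      resp_az_deg = stats::rnorm(n, 0, az_noise_sd), resp_el_deg = resp_el,
      confidence = conf, degenerate_flag = degen)
    structure(list(trials = trials, observer = obs,
                   weight_snapshots = dplyr::bind_rows(snaps[seq_len(snap_i)]),
                   weight_checksums = checksums, config = config),
              class = "training_result")
  })
}

#' Simulate a test (or control) session
#'
#' Simulates one generalisation-test or control session with the observer's
#' weights frozen:
#'
#' * Experiment 1 pre/post: 135 trials, 45 each of LP6/BS35/BS25, at targets
#'   drawn uniformly from `[-90, 90]` deg azimuth x `[-55, 85]` deg elevation
#'   within the frontal hemifield;
#' * Experiment 2 pre/post: 116 trials, 58 each of GWN and LP6, over
#'   `[-50, 50]` x `[-50, 70]` deg;
#' * control: 275 trials, 55 each of all five stimuli, over `[-20, 20]` x
#'   `[-50, 60]` deg.
#'
#' @param obs An `observer_state`.
#' @param phase `"pre"`, `"post"` or `"control"`.
#' @param experiment 1 or 2 (ignored for the control session).
#' @param seed Integer seed.
#' @param world True `hrtf_set` (defaults to the observer's templates).
#' @param az_noise_sd Azimuth response noise sd, degrees.
#' @return Trial tibble with columns `trial`, `phase`, `stim_kind`,
#'   `target_az_deg`, `target_el_deg`, `resp_az_deg`, `resp_el_deg`,
#'   `confidence`, `degenerate_flag`.
#' @export
simulate_test_session <- function(obs, phase = c("pre", "post", "control"),
                                  experiment = 1, seed = 1,
                                  world = obs$templates, az_noise_sd = 2) {
  phase <- match.arg(phase)
  stopifnot(inherits(obs, "observer_state"), experiment %in% c(1, 2))
  proto <- if (phase == "control") {
    list(kinds = c("GWN", "BS15", "BS25", "BS35", "LP6"), per = 55,
         az = c(-20, 20), el = c(-50, 60))
  } else if (experiment == 1) {
    list(kinds = c("LP6", "BS35", "BS25"), per = 45,
         az = c(-90, 90), el = c(-55, 85))
  } else {
    list(kinds = c("GWN", "LP6"), per = 58, az = c(-50, 50), el = c(-50, 70))
  }
  stims <- lapply(proto$kinds, stimulus_spectrum, axis = obs$templates$axis)
  names(stims) <- proto$kinds
  keeps <- lapply(stims, effective_band_idx, obs = obs)
  withr::with_seed(seed, {
    n <- proto$per * length(proto$kinds)
    targets <- double_pole_sample(proto$az, proto$el, n)
    kind <- sample(rep(proto$kinds, proto$per))
    resp_el <- conf <- numeric(n)
    degen <- logical(n)
    for (t in seq_len(n)) {
      sens <- sensory_spectrum(stims[[kind[t]]], world, targets$target_el_deg[t],
                               noise_sd = obs$sensory_noise_sd)
      tr <- trial_estimate(obs, sens$gain_db, keeps[[kind[t]]])
      resp_el[t] <- tr$estimate
      conf[t] <- tr$confidence
      degen[t] <- tr$degenerate
    }
    tibble::tibble(
      trial = seq_len(n), phase = phase, stim_kind = kind,
      target_az_deg = targets$target_az_deg,
      target_el_deg = targets$target_el_deg,
      resp_az_deg = targets$target_az_deg + stats::rnorm(n, 0, az_noise_sd),
      resp_el_deg = resp_el, confidence = conf, degenerate_flag = degen)
  })
}
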