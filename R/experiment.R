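#' Experiment configuration
#'
#' Top-level configuration for a full simulated experiment: a cohort of
#' listeners, each running control (Experiment 1 only), pre-test, training and
#' post-test sessions, followed by the regression and sign-test analysis.
#' Experiment 1 trains with visual feedback on BS35 stimuli (9 listeners);
#' Experiment 2 uses feedback-free exposure to LP6 stimuli (3 listeners).
#'
#' All randomness flows from `master_seed`: per-subject, per-phase stream
#' seeds are derived deterministically with [derive_seed()]. Listener
#' heterogeneity is emulated by jittering the HRTF synthesis parameters, the
#' prior width and the sensory noise by up to +/-20% per subject.
#'
#' @param experiment 1 (feedback training) or 2 (feedback-free exposure).
#' @param n_subjects Cohort size (default 9 for Experiment 1, 3 for
#'   Experiment 2).
#' @param master_seed Integer master seed.
#' @param observer_opts Named list overriding [observer()] arguments
#'   (`sigma_prior`, `sensory_noise_sd`, `beta`, `analysis_band`).
#' @param learning_opts Named list overriding [learning_config()] arguments
#'   (`learning_rate`, `n_trials`, ...).
#' @param jitter Relative half-width of the per-listener parameter jitter.
#' @param include_control Whether to simulate the 275-trial control session
#'   (default `TRUE` for Experiment 1).
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(experiment = 1,
                              n_subjects = if (experiment == 1) 9 else 3,
                              master_seed = 1,
                              observer_opts = list(),
                              learning_opts = list(),
                              jitter = 0.2,
                              include_control = experiment == 1) {
  stopifnot(experiment %in% c(1, 2), n_subjects >= 1)
  structure(list(experiment = as.integer(experiment),
                 n_subjects = as.integer(n_subjects),
                 master_seed = as.integer(master_seed),
                 observer_opts = observer_opts,
                 learning_opts = learning_opts,
                 jitter = jitter,
                 include_control = include_control),
            class = "experiment_config")
}

#' Derive a stream seed
#'
#' Deterministically maps (master seed, subject index, phase label) to a
#' 31-bit stream seed, so every session of every simulated listener has its
#' own reproducible random stream.
#'
#' @param master_seed Integer master seed.
#' @param subject Subject index (>= 1), or 0 for cohort-level streams.
#' @param phase One of `"listener"`, `"control"`, `"pre"`, `"train"`,
#'   `"post"`.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(master_seed, subject, phase = "listener") {
  code <- match(phase, c("listener", "control", "pre", "train", "post"))
  if (is.na(code)) stop("unknown phase label: ", phase, call. = FALSE)
  as.integer(((master_seed %% 65011) * 31793 + subject * 7907 + code * 631) %%
               (2^31 - 1))
}

#' Build one simulated listener
#'
#' Synthesizes an idiosyncratic listener: HRTF parameters, prior width and
#' sensory noise jittered by up to +/-`jitter` (relative) around the
#' defaults, with the listener's own high-band seed. The observer's stored
#' templates equal the listener's true filters.
#'
#' A parameter draw whose filter set violates a structural invariant (for
#' example a jittered erratic field that leaves two elevations insufficiently
#' unique) is discarded and redrawn from the next candidate seed, mirroring
#' the screening of listeners against inclusion criteria; the retry is
#' deterministic given the master seed.
#'
#' @param subject Subject index.
#' @param master_seed Master seed.
#' @param observer_opts Named list overriding [observer()] defaults.
#' @param jitter Relative jitter half-width (0 disables heterogeneity).
#' @param axis Frequency axis.
#' @return A list with `world` (`hrtf_set`) and `observer` (`observer_state`).
#' @export
simulate_listener <- function(subject, master_seed = 1, observer_opts = list(),
                              jitter = 0.2, axis = freq_axis()) {
  base <- derive_seed(master_seed, subject, "listener")
  for (attempt in 0:19) {
    seed <- as.integer((base + attempt * 7919) %% (2^31 - 1))
    out <- withr::with_seed(seed, {
      j <- function(x, scale = jitter) x * stats::runif(1, 1 - scale, 1 + scale)
      params <- hrtf_params(
        resonance_gain = j(15), notch_depth = j(25),
        # the notch centre may drift only a little, or it leaves 5-10 kHz at
        # the extreme grid elevations
        notch_freq_at_zero = j(7600, min(jitter, 0.04)),
        lowband_slope = j(0.05), lowband_slope_down = j(0.12),
        lowband_roughness = j(6), highband_roughness = j(22), seed = seed)
      world <- tryCatch(synth_hrtf(params, axis = axis),
                        error = function(e) NULL)
      if (is.null(world)) NULL else {
        args <- utils::modifyList(
          list(templates = world,
               sigma_prior = j(30), sensory_noise_sd = j(3)),
          observer_opts)
        list(world = world, observer = do.call(observer, args))
      }
    })
    if (!is.null(out)) return(out)
  }
  stop("could not synthesize a valid listener after 20 attempts", call. = FALSE)
}

#' Run a full simulated experiment
#'
#' Simulates the complete protocol for every listener in the cohort -
#' control (Experiment 1), pre-test, training, post-test - then fits the
#' stimulus-response regressions and the pre/post sign tests, and writes all
#' artifacts to `out_dir`: per-subject trial CSVs, weight-trajectory CSVs,
#' a fits CSV, a sign-test JSON report, and a JSON run manifest (config and
#' derived seeds). Re-running with the same configuration reproduces
#' byte-identical CSVs.
#'
#' @param config An [experiment_config()].
#' @param out_dir Output directory (created if needed); `NULL` skips writing
#'   and returns the results only.
#' @return (Invisibly) a list: `trials` (all sessions, one tibble),
#'   `fits` (elevation fits per subject/phase/stimulus), `sign_tests`
#'   (pre vs post), `weights` (trajectory snapshots), `out_dir`.
#' @export
run_experiment <- function(config = experiment_config(), out_dir = NULL) {
  stopifnot(inherits(config, "experiment_config"))
  all_trials <- list()
  all_weights <- list()
  for (s in seq_len(config$n_subjects)) {
    listener <- simulate_listener(s, config$master_seed,
                                  config$observer_opts, config$jitter)
    obs <- listener$observer
    sid <- sprintf("S%02d", s)
    sessions <- list()
    if (config$include_control) {
      sessions$control <- simulate_test_session(
        obs, "control", config$experiment,
        seed = derive_seed(config$master_seed, s, "control"))
    }
    sessions$pre <- simulate_test_session(
      obs, "pre", config$experiment,
      seed = derive_seed(config$master_seed, s, "pre"))
    lcfg <- do.call(learning_config, utils::modifyList(
      list(rule = if (config$experiment == 1) "feedback_delta"
                  else "exposure_selfconsistency",
           seed = derive_seed(config$master_seed, s, "train")),
      config$learning_opts))
    trained <- simulate_training_session(obs, lcfg)
    sessions$train <- trained$trials
    sessions$post <- simulate_test_session(
      trained$observer, "post", config$experiment,
      seed = derive_seed(config$master_seed, s, "post"))
    all_trials[[s]] <- dplyr::bind_rows(sessions) |>
      dplyr::mutate(subject_id = sid, .before = 1)
    all_weights[[s]] <- trained$weight_snapshots |>
      dplyr::mutate(subject_id = sid, .before = 1)
  }
  trials <- dplyr::bind_rows(all_trials)
  weights <- dplyr::bind_rows(all_weights)
  fits <- fit_responses(trials, "elevation")
  sign_tests <- compare_pre_post(
    dplyr::filter(fits, .data$phase == "pre"),
    dplyr::filter(fits, .data$phase == "post"))
  result <- list(trials = trials, fits = fits, sign_tests = sign_tests,
                 weights = weights, out_dir = out_dir)
  if (!is.null(out_dir)) write_run(result, config, out_dir)
  invisible(result)
}

write_run <- function(result, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in unique(result$trials$subject_id)) {
    readr::write_csv(dplyr::filter(result$trials, .data$subject_id == sid),
                     file.path(out_dir, paste0("trials_", sid, ".csv")))
    readr::write_csv(dplyr::filter(result$weights, .data$subject_id == sid),
                     file.path(out_dir, paste0("weights_", sid, ".csv")))
  }
  readr::write_csv(result$fits, file.path(out_dir, "fits.csv"))
  jsonlite::write_json(
    lapply(split(result$sign_tests, result$sign_tests$stim_kind), function(d)
      list(successes = d$successes, n = d$n, p_value = d$p_value)),
    file.path(out_dir, "sign_tests.json"), auto_unbox = TRUE, digits = NA)
  manifest <- list(
    package_version = as.character(utils::packageVersion("soundelev")),
    config = unclass(config),
    subject_seeds = lapply(seq_len(config$n_subjects), function(s)
      list(subject = s,
           listener = derive_seed(config$master_seed, s, "listener"),
           control = derive_seed(config$master_seed, s, "control"),
           pre = derive_seed(config$master_seed, s, "pre"),
           train = derive_seed(config$master_seed, s, "train"),
           post = derive_seed(config$master_seed, s, "post"))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Re-analyse a written experiment run
#'
#' Regenerates all regression fits, windowed training series and sign-test
#' reports from the trial CSVs of a run directory alone, decoupling the
#' analysis from the simulation. The trial tables must carry the declared
#' schema; a missing column raises an error naming it.
#'
#' @param run_dir Directory written by [run_experiment()].
#' @return A list: `fits`, `sign_tests`, `windowed` (per-subject windowed
#'   regression of the training session), `trials`.
#' @export
analyze_run <- function(run_dir) {
  if (!file.exists(file.path(run_dir, "manifest.json")))
    stop("no manifest.json in ", run_dir, call. = FALSE)
  files <- list.files(run_dir, pattern = "^trials_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop("no trial CSVs in ", run_dir, call. = FALSE)
  trials <- dplyr::bind_rows(lapply(files, readr::read_csv,
                                    show_col_types = FALSE))
  need <- c("subject_id", "phase", "trial", "stim_kind", "target_az_deg",
            "target_el_deg", "resp_az_deg", "resp_el_deg")
  for (nm in need) {
    if (!nm %in% names(trials))
      stop("trial table is missing column: ", nm, call. = FALSE)
  }
  fits <- fit_responses(trials, "elevation")
  has_prepost <- all(c("pre", "post") %in% trials$phase)
  sign_tests <- if (has_prepost) {
    compare_pre_post(dplyr::filter(fits, .data$phase == "pre"),
                     dplyr::filter(fits, .data$phase == "post"))
  } else NULL
  train <- dplyr::filter(trials, .data$phase == "train")
  windowed <- if (nrow(train) > 0 && min(table(train$subject_id)) >= 50) {
    train |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::group_modify(function(d, key)
        windowed_regression(dplyr::arrange(d, .data$trial))) |>
      dplyr::ungroup()
  } else NULL
  list(fits = fits, sign_tests = sign_tests, windowed = windowed,
       trials = trials)
}
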