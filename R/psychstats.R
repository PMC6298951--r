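#' Stimulus-response regression for one response component
#'
#' Least-squares linear fit of responses on targets, `R = g * T + b`: the
#' slope g is the response gain (1 for veridical behaviour), the intercept b
#' the response bias in degrees (0 for veridical). Also returns Pearson's r,
#' the coefficient of determination r^2, the mean absolute residual error
#' around the fitted line (MARE) and the mean absolute localisation error
#' (MAE, responses vs. targets directly).
#'
#' @param targets,responses Numeric vectors of equal length (n >= 3), degrees.
#' @param component Which response component the fit describes,
#'   `"elevation"` or `"azimuth"` (label only).
#' @return A `regression_fit` object (see also [tidy()][generics::tidy] and
#'   [glance()][generics::glance] methods).
#' @examples
#' fit_stimulus_response(c(0, 10, 20), c(5, 15, 25))
#' @export
fit_stimulus_response <- function(targets, responses,
                                  component = c("elevation", "azimuth")) {
  component <- match.arg(component)
  stopifnot(length(targets) == length(responses))
  n <- length(targets)
  if (n < 3) stop("need at least 3 trials for a regression fit", call. = FALSE)
  if (stats::var(targets) <= 0)
    stop("zero target variance: gain is undefined", call. = FALSE)
  g <- stats::cov(targets, responses) / stats::var(targets)
  b <- mean(responses) - g * mean(targets)
  r <- if (stats::var(responses) > 0) stats::cor(targets, responses) else 0
  structure(list(component = component, gain = g, bias = b, r = r, r2 = r * r,
                 mare = mean(abs(responses - (g * targets + b))),
                 mae = mean(abs(responses - targets)), n = n),
            class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(paste0("<regression_fit> %s: gain=%.3f bias=%.2f deg ",
                     "r2=%.3f MARE=%.2f MAE=%.2f (n=%d)\n"),
              x$component, x$gain, x$bias, x$r2, x$mare, x$mae, x$n))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.regression_fit <- function(x, ...) {
  tibble::tibble(component = x$component,
                 term = c("gain", "bias"),
                 estimate = c(x$gain, x$bias))
}

#' @export
glance.regression_fit <- function(x, ...) {
  tibble::tibble(component = x$component, gain = x$gain, bias = x$bias,
                 r = x$r, r2 = x$r2, mare = x$mare, mae = x$mae, n = x$n)
}

#' Stimulus-response fits on a trial table
#'
#' Data-frame-first wrapper around [fit_stimulus_response()]: groups a trial
#' table (columns `target_el_deg`/`resp_el_deg` or `target_az_deg`/
#' `resp_az_deg`) by the given columns and returns one fit row per group.
#'
#' @param data Trial tibble (e.g. from [simulate_test_session()]).
#' @param component `"elevation"` or `"azimuth"`.
#' @param by Character vector of grouping columns present in `data`
#'   (default `"stim_kind"`, plus `subject_id` and `phase` when present).
#' @return Tibble with grouping columns plus `component`, `gain`, `bias`,
#'   `r`, `r2`, `mare`, `mae`, `n`.
#' @export
fit_responses <- function(data, component = c("elevation", "azimuth"),
                          by = NULL) {
  component <- match.arg(component)
  cols <- if (component == "elevation") c("target_el_deg", "resp_el_deg")
          else c("target_az_deg", "resp_az_deg")
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0)
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (is.null(by))
    by <- intersect(c("subject_id", "phase", "stim_kind"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::group_modify(function(d, key) {
      glance(fit_stimulus_response(d[[cols[1]]], d[[cols[2]]], component))
    }) |>
    dplyr::ungroup()
}

#' Windowed (rolling) stimulus-response regression
#'
#' Tracks learning within a session by fitting the stimulus-response
#' regression in a sliding window of consecutive trials (default 50 trials,
#' advanced in steps of 5), anchored at trial 1. A session of n trials yields
#' `floor((n - window) / step) + 1` fits.
#'
#' @param data Trial tibble ordered by trial number.
#' @param window Window length in trials (>= 10).
#' @param step Step between window starts, trials.
#' @param component `"elevation"` or `"azimuth"`.
#' @return Tibble with `start` (first trial of the window) plus the
#'   regression columns of [fit_responses()].
#' @export
windowed_regression <- function(data, window = 50, step = 5,
                                component = c("elevation", "azimuth")) {
  component <- match.arg(component)
  if (window < 10) stop("window must be at least 10 trials", call. = FALSE)
  n <- nrow(data)
  if (n < window) stop("session shorter than one window", call. = FALSE)
  cols <- if (component == "elevation") c("target_el_deg", "resp_el_deg")
          else c("target_az_deg", "resp_az_deg")
  starts <- seq(1, n - window + 1, by = step)
  purrr::map_dfr(starts, function(s) {
    d <- data[s:(s + window - 1), ]
    out <- glance(fit_stimulus_response(d[[cols[1]]], d[[cols[2]]], component))
    dplyr::bind_cols(tibble::tibble(start = s), out)
  })
}

#' Exact one-sided sign test
#'
#' Upper-tail exact binomial test with p = 0.5: the probability of observing
#' at least `successes` improvements out of `n` under the null hypothesis
#' that improvement and deterioration are equally likely. Tail counts are
#' accumulated from an exactly computed Pascal row (integer-valued doubles,
#' exact up to n = 52), then divided by 2^n.
#'
#' @param successes Number of improvements, `0 <= successes <= n`.
#' @param n Number of comparisons, >= 1.
#' @return A `sign_test` object: list with `successes`, `n`, `p_value`.
#' @examples
#' sign_test_p(29, 36) # p ~ 1.56e-4
#' @export
sign_test_p <- function(successes, n) {
  stopifnot(length(successes) == 1, length(n) == 1, n >= 1,
            successes >= 0, successes <= n, successes == round(successes),
            n == round(n))
  # Pascal row n: C(n, 0..n), built by the addition rule in exact doubles
  row <- 1
  for (i in seq_len(n)) row <- c(row, 0) + c(0, row)
  p <- sum(row[(successes + 1):(n + 1)]) / 2^n
  structure(list(successes = as.integer(successes), n = as.integer(n),
                 p_value = p),
            class = "sign_test")
}

#' @export
print.sign_test <- function(x, ...) {
  cat(sprintf("<sign_test> %d/%d improvements, one-sided exact p = %.3g\n",
              x$successes, x$n, x$p_value))
  invisible(x)
}

#' Pre/post sign tests per stimulus
#'
#' For each stimulus kind, counts strict improvements from pre- to
#' post-training over all subjects and the four regression measures (gain up,
#' r^2 up, |bias| down, MAE down; with 9 subjects this yields n = 36 values
#' per stimulus), and evaluates the exact one-sided sign test on the count.
#' Ties count as non-improvements (a conservative choice).
#'
#' @param pre_fits,post_fits Fit tibbles from [fit_responses()] with columns
#'   `subject_id`, `stim_kind`, `gain`, `bias`, `r2`, `mae`. Both phases must
#'   cover the same subjects and stimulus kinds.
#' @return Tibble with columns `stim_kind`, `successes`, `n`, `p_value`.
#' @export
compare_pre_post <- function(pre_fits, post_fits) {
  need <- c("subject_id", "stim_kind", "gain", "bias", "r2", "mae")
  for (nm in setdiff(need, names(pre_fits)))
    stop("pre_fits is missing column: ", nm, call. = FALSE)
  for (nm in setdiff(need, names(post_fits)))
    stop("post_fits is missing column: ", nm, call. = FALSE)
  key_pre <- with(pre_fits, paste(subject_id, stim_kind))
  key_post <- with(post_fits, paste(subject_id, stim_kind))
  if (!setequal(key_pre, key_post))
    stop("pre and post fits cover different subject/stimulus sets", call. = FALSE)
  joined <- dplyr::inner_join(pre_fits, post_fits,
                              by = c("subject_id", "stim_kind"),
                              suffix = c("_pre", "_post"))
  joined |>
    dplyr::group_by(.data$stim_kind) |>
    dplyr::summarise(
      successes = sum(.data$gain_post > .data$gain_pre) +
        sum(.data$r2_post > .data$r2_pre) +
        sum(abs(.data$bias_post) < abs(.data$bias_pre)) +
        sum(.data$mae_post < .data$mae_pre),
      n = 4L * dplyr::n(), .groups = "drop") |>
    dplyr::rowwise() |>
    dplyr::mutate(p_value = sign_test_p(.data$successes, .data$n)$p_value) |>
    dplyr::ungroup()
}

#' Sample targets in double-pole coordinates
#'
#' Draws pseudo-uniform target locations from an azimuth x elevation box
#' intersected with the frontal hemifield constraint |azimuth| + |elevation|
#' <= 90 deg of the double-pole coordinate system, by rejection sampling.
#'
#' @param az_range,el_range Intervals `c(lo, hi)` in degrees, within
#'   `[-90, 90]`.
#' @param n Number of targets.
#' @param seed Optional integer seed.
#' @return Tibble with columns `target_az_deg`, `target_el_deg`.
#' @export
double_pole_sample <- function(az_range, el_range, n, seed = NULL) {
  stopifnot(az_range[1] <= az_range[2], el_range[1] <= el_range[2],
            all(abs(az_range) <= 90), all(abs(el_range) <= 90))
  # feasibility: the box corner closest to the origin must satisfy the
  # hemifield constraint
  amin <- if (az_range[1] > 0) az_range[1] else if (az_range[2] < 0) -az_range[2] else 0
  emin <- if (el_range[1] > 0) el_range[1] else if (el_range[2] < 0) -el_range[2] else 0
  if (amin + emin > 90)
    stop("empty feasible region: box lies outside |az| + |el| <= 90", call. = FALSE)
  draw <- function() {
    az <- numeric(0); el <- numeric(0)
    while (length(az) < n) {
      m <- max(2 * (n - length(az)), 16)
      a <- stats::runif(m, az_range[1], az_range[2])
      e <- stats::runif(m, el_range[1], el_range[2])
      ok <- abs(a) + abs(e) <= 90
      az <- c(az, a[ok]); el <- c(el, e[ok])
    }
    tibble::tibble(target_az_deg = az[seq_len(n)], target_el_deg = el[seq_len(n)])
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
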