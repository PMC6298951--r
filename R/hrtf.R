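#' Synthesis parameters for an HRTF set
#'
#' Parameter block for [synth_hrtf()]. The synthetic head-related transfer
#' functions are built from four additive log-magnitude components that mirror
#' the canonical cue structure of measured human HRTFs:
#'
#' * a direction-independent **ear-canal resonance**: a Gaussian bump (in
#'   log-frequency) near 2.5 kHz, the quarter-wavelength resonance of the
#'   ear canal;
#' * an elevation-dependent **pinna notch**: a negative Gaussian whose centre
#'   frequency moves linearly with elevation inside 5-10 kHz, the strongest
#'   elevation cue;
#' * a **weak low-band cue**: an elevation-proportional gain offset that ramps
#'   in above `lowband_onset` (~3-3.5 kHz), with a larger slope magnitude for
#'   downward than for upward elevations, plus a weak random field (smooth in
#'   log-frequency and in elevation, with larger amplitude below the
#'   horizontal plane), so that the low-frequency curves diverge - weakly,
#'   idiosyncratically, but consistently - predominantly for downward
#'   directions;
#' * an **erratic high-band component** above 10 kHz: a seeded random field,
#'   smooth in frequency but non-monotonic across elevation, emulating the
#'   idiosyncratic fine structure to which listeners are poorly sensitive.
#'
#' @param resonance_freq Ear-canal resonance centre, Hz.
#' @param resonance_gain Resonance peak gain, dB.
#' @param resonance_width_oct Resonance width (Gaussian sd), octaves.
#' @param notch_freq_at_zero Notch centre frequency at 0 deg elevation, Hz.
#' @param notch_freq_slope Notch centre drift, Hz per degree of elevation.
#' @param notch_depth Notch depth, dB (positive number; applied as a dip).
#' @param notch_width_oct Notch width (Gaussian sd), octaves.
#' @param lowband_onset Frequency at which the weak low-band cue starts to
#'   ramp in for a source at 0 deg elevation, Hz.
#' @param lowband_onset_slope Drift of the divergence onset with elevation,
#'   Hz/deg; a small elevation dependence of the point where the curves start
#'   to diverge gives the low-band cues a graded shape (not just a scale)
#'   difference across elevations.
#' @param lowband_slope Low-band gain slope for upward elevations, dB/deg.
#' @param lowband_slope_down Low-band gain slope magnitude for downward
#'   elevations, dB/deg; larger than `lowband_slope` so the weak cues are
#'   predominantly informative for downward directions.
#' @param lowband_roughness Amplitude of the weak low-band random field
#'   (3.3-5.4 kHz), dB. The field varies smoothly across elevation
#'   (correlation length of a few tens of degrees) and is scaled down above
#'   the horizontal plane, mirroring the downward dominance of the weak cues.
#' @param highband_roughness Amplitude of the erratic component above 10 kHz, dB.
#' @param seed Integer seed for the high-band random field.
#'
#' @return A list of class `hrtf_params`.
#' @export
hrtf_params <- function(resonance_freq = 2500,
                        resonance_gain = 15,
                        resonance_width_oct = 0.30,
                        notch_freq_at_zero = 7600,
                        notch_freq_slope = 15,
                        notch_depth = 25,
                        notch_width_oct = 0.08,
                        lowband_onset = 3000,
                        lowband_onset_slope = 6,
                        lowband_slope = 0.05,
                        lowband_slope_down = 0.12,
                        lowband_roughness = 6,
                        highband_roughness = 22,
                        seed = 1L) {
  p <- list(resonance_freq = resonance_freq, resonance_gain = resonance_gain,
            resonance_width_oct = resonance_width_oct,
            notch_freq_at_zero = notch_freq_at_zero,
            notch_freq_slope = notch_freq_slope, notch_depth = notch_depth,
            notch_width_oct = notch_width_oct, lowband_onset = lowband_onset,
            lowband_onset_slope = lowband_onset_slope,
            lowband_slope = lowband_slope,
            lowband_slope_down = lowband_slope_down,
            lowband_roughness = lowband_roughness,
            highband_roughness = highband_roughness, seed = as.integer(seed))
  num <- p[setdiff(names(p), "seed")]
  if (!all(vapply(num, function(v) is.numeric(v) && is.finite(v), logical(1))))
    stop("all hrtf_params magnitudes must be finite numbers", call. = FALSE)
  structure(p, class = "hrtf_params")
}

# Smooth 0->1 ramp in log-frequency between f_lo and f_hi.
log_ramp <- function(f, f_lo, f_hi) {
  u <- (log(f) - log(f_lo)) / (log(f_hi) - log(f_lo))
  u <- pmin(pmax(u, 0), 1)
  u * u * (3 - 2 * u)
}

#' Synthesize an HRTF set
#'
#' Generates the log-magnitude HRTF matrix H(f; elevation) over a frequency
#' axis and an ascending elevation grid, from the component model described in
#' [hrtf_params()]. The constructor validates the structural invariants of the
#' set: a direction-independent resonance (across-elevation gain sd < 1 dB at
#' the band nearest 2.5 kHz), a notch centre that stays inside 5-10 kHz and is
#' strictly monotonic in elevation, and mutual uniqueness of the rows
#' (pairwise Pearson correlation over the analysis band < 0.99) so that
#' template matching has a well-defined maximum.
#'
#' @param params An [hrtf_params()] block.
#' @param elevations Ascending elevation grid in degrees, within `[-60, 90]`.
#'   The default covers the frontal-hemifield test range.
#' @param axis A [freq_axis()].
#'
#' @return An `hrtf_set` object: list with `elevations`, `axis`, `gain_db`
#'   (matrix, one row per elevation) and `params`.
#' @examples
#' h <- synth_hrtf()
#' validate_uniqueness(h)
#' @export
synth_hrtf <- function(params = hrtf_params(),
                       elevations = seq(-55, 85, by = 5),
                       axis = freq_axis()) {
  stopifnot(inherits(params, "hrtf_params"))
  elevations <- as.numeric(elevations)
  if (is.unsorted(elevations, strictly = TRUE))
    stop("elevation grid must be strictly ascending", call. = FALSE)
  if (min(elevations) < -60 || max(elevations) > 90)
    stop("elevation grid must lie within [-60, 90] deg", call. = FALSE)

  f <- as.numeric(unclass(axis))
  lf2 <- log2(f)
  n_el <- length(elevations)

  notch_centers <- params$notch_freq_at_zero + params$notch_freq_slope * elevations
  if (any(notch_centers < 5000 | notch_centers > 10000))
    stop("notch centres leave [5000, 10000] Hz for the requested elevations; ",
         "invalid notch_freq_at_zero/notch_freq_slope", call. = FALSE)

  resonance <- params$resonance_gain *
    exp(-0.5 * ((lf2 - log2(params$resonance_freq)) / params$resonance_width_oct)^2)

  ramp_high <- log_ramp(f, 10000, 11500)
  u_high <- (lf2 - log2(10000)) / (log2(14500) - log2(10000))

  gain <- matrix(0, n_el, length(f))
  fields <- withr::with_seed(params$seed, {
    # high band: per-elevation smooth random Fourier series in log-frequency,
    # independent across elevations (erratic, non-monotonic)
    hi <- t(vapply(seq_len(n_el), function(i) {
      a <- stats::rnorm(4, sd = params$highband_roughness / sqrt(4))
      ph <- stats::runif(4, 0, 2 * pi)
      colSums(a * sin(outer(1:4, 2 * pi * u_high) + ph))
    }, numeric(length(f))))
    # low band: weak field, smooth in log-frequency (3 Fourier orders over
    # 3.3-6.5 kHz) and in elevation (spline through knots every 25 deg)
    u_low <- (lf2 - log2(3300)) / (log2(5600) - log2(3300))
    # field kept clear of the 5-10 kHz notch region, so the notch centre
    # stays the argmin of the deterministic components
    taper <- log_ramp(f, 3200, 3900) * (1 - log_ramp(f, 4600, 5400))
    knots <- seq(-65, 95, by = 25)
    lo <- matrix(0, n_el, length(f))
    for (j in 1:3) {
      cj <- stats::spline(knots, stats::rnorm(length(knots)), xout = elevations)$y
      dj <- stats::spline(knots, stats::rnorm(length(knots)), xout = elevations)$y
      lo <- lo + outer(cj, sin(2 * pi * j * u_low)) + outer(dj, cos(2 * pi * j * u_low))
    }
    amp <- params$lowband_roughness / sqrt(3) *
      ifelse(elevations < 0, 1, 0.6) # downward-dominant weak cues
    lo <- (amp * lo) * matrix(rep(taper, n_el), n_el, byrow = TRUE)
    list(hi = hi, lo = lo)
  })
  rough <- fields$hi

  for (i in seq_len(n_el)) {
    el <- elevations[i]
    notch <- -params$notch_depth *
      exp(-0.5 * ((lf2 - log2(notch_centers[i])) / params$notch_width_oct)^2)
    slope <- if (el >= 0) params$lowband_slope else params$lowband_slope_down
    knee <- params$lowband_onset + params$lowband_onset_slope * el
    lowband <- slope * el * log_ramp(f, knee, knee * 1.6)
    gain[i, ] <- resonance + notch + lowband + fields$lo[i, ] +
      ramp_high * rough[i, ]
  }

  set <- structure(list(elevations = elevations, axis = axis, gain_db = gain,
                        params = params),
                   class = "hrtf_set")
  validate_hrtf_set(set)
  set
}

validate_hrtf_set <- function(set) {
  if (!(min(set$elevations) <= -50 && max(set$elevations) >= 60))
    stop("elevation grid must span at least [-50, +60] deg", call. = FALSE)
  i25 <- which.min(abs(unclass(set$axis) - 2500))
  if (stats::sd(set$gain_db[, i25]) >= 1)
    stop("ear-canal resonance is not direction-independent: gain sd at 2.5 kHz >= 1 dB",
         call. = FALSE)
  nc <- notch_centers(set)
  increasing <- !is.unsorted(nc, strictly = TRUE)
  decreasing <- !is.unsorted(rev(nc), strictly = TRUE)
  if (any(!is.finite(nc)) || !(increasing || decreasing))
    stop("notch-centre frequency is not strictly monotonic in elevation",
         call. = FALSE)
  r <- validate_uniqueness(set)
  if (r >= 0.99)
    stop(sprintf("HRTF rows are not unique: max pairwise correlation %.3f >= 0.99", r),
         call. = FALSE)
  invisible(set)
}

#' Notch-centre frequencies of an HRTF set
#'
#' Locates the spectral-notch centre per elevation as the minimum of the gain
#' within 5-10 kHz, refined by quadratic (parabolic) interpolation of the gain
#' over log-frequency around the discrete minimum. Sub-band interpolation is
#' needed because the notch drift per elevation step is smaller than the band
#' spacing of a typical axis.
#'
#' @param set An `hrtf_set`.
#' @return Numeric vector of notch-centre frequencies (Hz), one per elevation.
#' @export
notch_centers <- function(set) {
  stopifnot(inherits(set, "hrtf_set"))
  f <- unclass(set$axis)
  idx <- which(in_band(set$axis, c(5000, 10000)))
  if (length(idx) < 3) stop("fewer than 3 bands in 5-10 kHz", call. = FALSE)
  lf <- log(f)
  vapply(seq_along(set$elevations), function(i) {
    g <- set$gain_db[i, idx]
    j <- which.min(g)
    jj <- idx[j]
    if (jj <= 1 || jj >= length(f)) return(f[jj])
    # parabola through the three log-f points around the minimum
    x <- lf[(jj - 1):(jj + 1)]
    y <- set$gain_db[i, (jj - 1):(jj + 1)]
    denom <- (y[1] - 2 * y[2] + y[3])
    if (abs(denom) < 1e-12) return(f[jj])
    xv <- x[2] - 0.5 * (x[3] - x[1]) * (y[3] - y[1]) / (2 * denom)
    exp(xv)
  }, numeric(1))
}

#' Maximum pairwise correlation between HRTF rows
#'
#' The template-matching model has a unique maximum only if no two stored
#' HRTFs positively correlate too strongly with each other. This computes the
#' maximum Pearson correlation over all pairs of distinct elevations, with the
#' gain rows restricted to the analysis band.
#'
#' @param set An `hrtf_set`.
#' @param band Frequency interval `c(lo, hi)` in Hz (default the 3.5-14 kHz
#'   analysis band).
#' @return The maximum off-diagonal correlation (scalar).
#' @export
validate_uniqueness <- function(set, band = c(3500, 14000)) {
  stopifnot(inherits(set, "hrtf_set"))
  keep <- in_band(set$axis, band)
  if (sum(keep) < 3) stop("fewer than 3 bands in the interval", call. = FALSE)
  cm <- stats::cor(t(set$gain_db[, keep, drop = FALSE]))
  max(cm[upper.tri(cm)])
}

# Linear interpolation of the HRTF row at an off-grid elevation.
hrtf_row <- function(set, elevation) {
  el <- set$elevations
  if (elevation < min(el) || elevation > max(el))
    stop("elevation outside the HRTF grid", call. = FALSE)
  i <- findInterval(elevation, el, all.inside = TRUE)
  w <- (elevation - el[i]) / (el[i + 1] - el[i])
  (1 - w) * set$gain_db[i, ] + w * set$gain_db[i + 1, ]
}

#' @export
print.hrtf_set <- function(x, ...) {
  cat(sprintf("<hrtf_set> %d elevations [%g, %g] deg x %d bands [%.0f, %.0f] Hz\n",
              length(x$elevations), min(x$elevations), max(x$elevations),
              length(x$axis), min(unclass(x$axis)), max(unclass(x$axis))))
  invisible(x)
}

#' @rdname synth_hrtf
#' @param x An `hrtf_set`.
#' @param ... Unused.
#' @export
as_tibble.hrtf_set <- function(x, ...) {
  tibble::tibble(
    elevation_deg = rep(x$elevations, each = length(x$axis)),
    freq_hz = rep(as.numeric(unclass(x$axis)), length(x$elevations)),
    gain_db = as.numeric(t(x$gain_db))
  )
}

#' Read and write HRTF sets as CSV
#'
#' The on-disk format is a plain CSV with a first column `elevation_deg` and
#' one `gain_db` column per band, whose header declares the band centre (e.g.
#' `gain_db_2500.0`). A JSON sidecar (`<path>.json`) stores the synthesis
#' parameters and seed so a written set can be regenerated.
#'
#' @param set An `hrtf_set`.
#' @param path CSV file path.
#' @return `write_hrtf_csv` returns `path` invisibly; `read_hrtf_csv` returns
#'   an `hrtf_set`.
#' @export
write_hrtf_csv <- function(set, path) {
  stopifnot(inherits(set, "hrtf_set"))
  df <- as.data.frame(set$gain_db)
  names(df) <- sprintf("gain_db_%.1f", unclass(set$axis))
  df <- cbind(elevation_deg = set$elevations, df)
  readr::write_csv(tibble::as_tibble(df), path)
  if (!is.null(set$params)) {
    jsonlite::write_json(unclass(set$params), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_hrtf_csv
#' @export
read_hrtf_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "elevation_deg")
    stop("first column must be elevation_deg", call. = FALSE)
  centers <- as.numeric(sub("gain_db_", "", names(df)[-1]))
  params <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    pj <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    params <- do.call(hrtf_params, pj)
  }
  set <- structure(list(elevations = df$elevation_deg,
                        axis = structure(centers, class = "freq_axis"),
                        gain_db = as.matrix(df[, -1]),
                        params = params),
                   class = "hrtf_set")
  dimnames(set$gain_db) <- NULL
  validate_hrtf_set(set)
  set
}
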