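#' Log-spaced frequency axis
#'
#' Builds the band-centre grid on which all spectra, HRTFs and weight profiles
#' live. Band centres are log-spaced (constant ratio between neighbours), which
#' mirrors the roughly logarithmic frequency resolution of the cochlea and the
#' log-frequency axis on which HRTF magnitude spectra are conventionally drawn.
#'
#' @param f_min,f_max Band-centre limits in Hz. Must satisfy
#'   `200 <= f_min < f_max <= 20000` (the audible band used throughout).
#' @param n_bands Number of bands (>= 8, except that 2 or 3 bands are permitted
#'   for toy grids in examples and tests).
#'
#' @return A `freq_axis` object: a numeric vector of strictly ascending band
#'   centres in Hz with class `"freq_axis"`.
#' @examples
#' freq_axis(200, 20000, 3) # middle band at 2000 Hz, the geometric mean
#' @export
freq_axis <- function(f_min = 200, f_max = 20000, n_bands = 64) {
  stopifnot(is.numeric(f_min), is.numeric(f_max), length(f_min) == 1,
            length(f_max) == 1, length(n_bands) == 1)
  if (!(f_min >= 200 && f_min < f_max && f_max <= 20000)) {
    stop("frequency limits must satisfy 200 <= f_min < f_max <= 20000 Hz",
         call. = FALSE)
  }
  n_bands <- as.integer(n_bands)
  if (n_bands < 2) stop("n_bands must be at least 2", call. = FALSE)
  centers <- exp(seq(log(f_min), log(f_max), length.out = n_bands))
  # pin the endpoints exactly (guards band-membership tests at the limits)
  centers[1] <- f_min
  centers[n_bands] <- f_max
  structure(centers, class = "freq_axis")
}

#' @export
print.freq_axis <- function(x, ...) {
  cat(sprintf("<freq_axis> %d log-spaced bands, %.0f-%.0f Hz\n",
              length(x), min(x), max(x)))
  invisible(x)
}

# A band belongs to an interval iff its centre lies in the closed interval.
in_band <- function(axis, band) {
  stopifnot(length(band) == 2, band[1] <= band[2])
  unclass(axis) >= band[1] & unclass(axis) <= band[2]
}

same_axis <- function(a, b, tol = 1e-9) {
  length(a) == length(b) && all(abs(log(unclass(a)) - log(unclass(b))) < tol)
}
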