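#' Stimulus spectra
#'
#' Builds the log-amplitude spectrum profile of one of the five standard
#' stimuli, expressed in dB relative to the flat broadband reference:
#'
#' * `GWN` - Gaussian white noise, flat (0 dB) across 0.2-20 kHz;
#' * `BS15`/`BS25`/`BS35` - band-stop noises with the 6-9 kHz notch band
#'   attenuated by 15/25/35 dB, flat elsewhere;
#' * `LP6` - low-pass noise, flat within 0.5-6 kHz and at the attenuation
#'   floor outside that band.
#'
#' A band belongs to an interval iff its centre lies in the closed interval.
#'
#' @param kind One of `"GWN"`, `"BS15"`, `"BS25"`, `"BS35"`, `"LP6"`.
#' @param axis A [freq_axis()].
#' @param floor_db Attenuation floor in dB for out-of-band energy of band
#'   limited stimuli (default -60; kept finite so downstream arithmetic is).
#'
#' @return A `spectrum_profile` object: list with `axis`, `gain_db` (numeric
#'   per band) and `kind`.
#' @examples
#' stimulus_spectrum("BS35", freq_axis())
#' @export
stimulus_spectrum <- function(kind, axis = freq_axis(), floor_db = -60) {
  kinds <- c("GWN", "BS15", "BS25", "BS35", "LP6")
  if (!is.character(kind) || length(kind) != 1 || !(kind %in% kinds)) {
    stop("unknown stimulus kind; expected one of ",
         paste(kinds, collapse = ", "), call. = FALSE)
  }
  f <- unclass(axis)
  gain <- numeric(length(f))
  if (kind %in% c("BS15", "BS25", "BS35")) {
    atten <- as.numeric(sub("BS", "", kind))
    gain[in_band(axis, c(6000, 9000))] <- -atten
  } else if (kind == "LP6") {
    gain[!in_band(axis, c(500, 6000))] <- floor_db
  }
  new_spectrum_profile(axis, gain, kind)
}

new_spectrum_profile <- function(axis, gain_db, kind = "custom") {
  stopifnot(length(gain_db) == length(axis), all(is.finite(gain_db)))
  structure(list(axis = axis, gain_db = as.numeric(gain_db), kind = kind),
            class = "spectrum_profile")
}

#' @export
print.spectrum_profile <- function(x, ...) {
  cat(sprintf("<spectrum_profile> kind=%s, %d bands, range [%.1f, %.1f] dB\n",
              x$kind, length(x$gain_db), min(x$gain_db), max(x$gain_db)))
  invisible(x)
}

#' @rdname stimulus_spectrum
#' @param x A `spectrum_profile`.
#' @param ... Unused.
#' @export
as_tibble.spectrum_profile <- function(x, ...) {
  tibble::tibble(freq_hz = as.numeric(unclass(x$axis)),
                 gain_db = x$gain_db, kind = x$kind)
}
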