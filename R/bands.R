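#' Define a frequency band
#'
#' @param name band label (e.g. "alpha1").
#' @param low lower edge in Hz (inclusive).
#' @param high upper edge in Hz (exclusive for bin aggregation).
#' @return an object of class `band`.
#' @examples
#' band("alpha1", 8, 10.5)
#' @export
band <- function(name, low, high) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(low) || !is.numeric(high) || length(low) != 1L ||
      length(high) != 1L || is.na(low) || is.na(high)) {
    stop("band edges must be single numbers", call. = FALSE)
  }
  if (low <= 0 || low >= high) {
    stop(sprintf("invalid band '%s': need 0 < low < high (got %g, %g)",
                 name, low, high), call. = FALSE)
  }
  structure(list(name = name, low = low, high = high), class = "band")
}

#' @export
print.band <- function(x, ...) {
  cat(sprintf("<band> %s: %g-%g Hz\n", x$name, x$low, x$high))
  invisible(x)
}

#' Standard resting-state EEG analysis bands
#'
#' Theta, alpha-1, alpha-2, beta-1 and beta-2. The theta band is commonly
#' stated either as 4-8 Hz or as 5-8 Hz; 4-8 Hz is the default and the
#' narrower variant is available via `theta_low = 5`. Delta and gamma are
#' deliberately absent: on real scalp data they are dominated by ocular and
#' muscular artifact.
#'
#' @param theta_low lower edge of the theta band in Hz (4 or 5).
#' @return a named list of [band()] objects.
#' @examples
#' names(default_bands())
#' @export
default_bands <- function(theta_low = 4) {
  stopifnot(theta_low %in% c(4, 5))
  list(
    theta  = band("theta", theta_low, 8),
    alpha1 = band("alpha1", 8, 10.5),
    alpha2 = band("alpha2", 10.5, 13),
    beta1  = band("beta1", 13, 20),
    beta2  = band("beta2", 20, 30)
  )
}

# validate a band against a sampling rate (Nyquist)
check_band_nyquist <- function(band, sampling_rate) {
  nyq <- sampling_rate / 2
  if (band$high > nyq) {
    stop(sprintf("band '%s' upper edge %g Hz exceeds Nyquist %g Hz",
                 band$name, band$high, nyq), call. = FALSE)
  }
  invisible(TRUE)
}
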