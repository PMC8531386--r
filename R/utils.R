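#' Run code under a temporary RNG seed
#'
#' Evaluates `code` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so that seeded package functions do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  code
}

#' Derive a bounded child seed from a base seed and stream indices
#'
#' Mixes a base seed with up to three small indices into a deterministic
#' integer below 2^31, so every recording / bootstrap stream gets its own
#' reproducible substream.
#'
#' @param seed base integer seed.
#' @param ... small non-negative integer indices.
#' @return a single integer in [0, 2^31 - 1].
#' @keywords internal
child_seed <- function(seed, ...) {
  idx <- c(...)
  x <- as.double(seed) %% 2147483647
  for (i in idx) {
    x <- (x * 48271 + as.double(i) + 1) %% 2147483647
  }
  as.integer(x)
}

#' Data-to-channel sufficiency factor for ICA decomposition
#'
#' Ratio of the number of time samples to the squared channel count,
#' conventionally used to judge whether a recording is long enough for a
#' stable independent component decomposition (values well above 1 are
#' considered sufficient). A 5-minute recording at 256 Hz over a 65-channel
#' montage gives 76800 / 65^2 = 18.18.
#'
#' @param n_samples number of time samples.
#' @param n_channels number of channels.
#' @return `n_samples / n_channels^2`.
#' @examples
#' amica_sufficiency(5 * 60 * 256, 65)
#' @export
amica_sufficiency <- function(n_samples, n_channels) {
  stopifnot(n_samples > 0, n_channels > 0)
  n_samples / n_channels^2
}

`%||%` <- function(a, b) if (is.null(a)) b else a
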