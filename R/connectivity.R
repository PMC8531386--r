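# Band-resolved functional connectivity from Welch-style segment
# cross-spectra. Both estimators are computed from the same tapered
# segment spectra:
#
#   wPLI(f) = |sum_s Im S_xy,s(f)| / sum_s |Im S_xy,s(f)|
#   Coh(f)  = |<S_xy(f)>_s| / sqrt(<S_xx(f)>_s <S_yy(f)>_s)
#
# with S_xy,s(f) = X_s(f) * Conj(Y_s(f)), averaged over frequency bins whose
# center lies in [low, high). wPLI is defined as 0 when its denominator is 0
# (pure zero-lag coupling); coherence here is magnitude (not squared)
# coherence so both estimators share the [0, 1] scale.

#' Tapered segment spectra of one epoch
#'
#' Splits an epoch into overlapping tapered segments and returns the
#' discrete Fourier coefficients per segment and channel, from which all
#' pairwise cross-spectra `S_xy(f) = X(f) Conj(Y(f))` derive. Frequency
#' resolution is `sampling_rate / segment_length`.
#'
#' @param x channels x samples numeric matrix (one epoch).
#' @param sampling_rate sampling rate in Hz.
#' @param segment_length segment length in samples (default: one second).
#' @param segment_overlap fractional overlap between segments in `[0, 1)`.
#' @param window taper: `"hann"` or `"rectangular"`.
#' @return a list of class `cross_spectra` with `coef` (segments x
#'   frequencies x channels complex array) and `freq` (Hz).
#' @export
cross_spectra <- function(x, sampling_rate,
                          segment_length = round(sampling_rate),
                          segment_overlap = 0.5,
                          window = c("hann", "rectangular")) {
  window <- match.arg(window)
  x <- as.matrix(x)
  nch <- nrow(x)
  n <- ncol(x)
  L <- as.integer(segment_length)
  if (L > n) stop("segment_length exceeds epoch length", call. = FALSE)
  if (segment_overlap < 0 || segment_overlap >= 1) {
    stop("segment_overlap must lie in [0, 1)", call. = FALSE)
  }
  step <- max(1L, as.integer(round(L * (1 - segment_overlap))))
  starts <- seq(0L, n - L, by = step)
  if (length(starts) < 2L) {
    stop("need at least 2 segments per epoch for cross-spectral estimation",
         call. = FALSE)
  }
  win <- if (window == "hann") as.numeric(signal::hanning(L)) else rep(1, L)
  nfreq <- L %/% 2L + 1L
  coef <- array(0i, dim = c(length(starts), nfreq, nch))
  for (s in seq_along(starts)) {
    seg <- x[, (starts[s] + 1L):(starts[s] + L), drop = FALSE]
    seg <- sweep(seg, 2L, win, "*")
    F <- stats::mvfft(t(seg))            # L x nch, series in columns
    coef[s, , ] <- F[seq_len(nfreq), , drop = FALSE]
  }
  structure(list(coef = coef,
                 freq = (seq_len(nfreq) - 1) * sampling_rate / L,
                 n_segments = length(starts),
                 window = window),
            class = "cross_spectra")
}

#' Materialize per-segment cross-spectral matrices
#'
#' @param cs a [cross_spectra()] object.
#' @param freq_idx indices into `cs$freq` to materialize (default: all).
#' @return complex array segments x frequencies x channels x channels with
#'   `S[s, f, i, j] = X_i Conj(X_j)`.
#' @export
cross_spectral_tensor <- function(cs, freq_idx = seq_along(cs$freq)) {
  stopifnot(inherits(cs, "cross_spectra"))
  d <- dim(cs$coef)
  S <- array(0i, dim = c(d[1], length(freq_idx), d[3], d[3]))
  for (fi in seq_along(freq_idx)) {
    for (s in seq_len(d[1])) {
      z <- cs$coef[s, freq_idx[fi], ]
      S[s, fi, , ] <- outer(z, Conj(z))
    }
  }
  S
}

# indices of frequency bins whose center lies in [low, high)
band_bins <- function(freq, band) {
  idx <- which(freq >= band$low & freq < band$high)
  if (length(idx) == 0L) {
    stop(sprintf("no frequency bins inside band '%s' (%g-%g Hz) at resolution %g Hz",
                 band$name, band$low, band$high, freq[2] - freq[1]),
         call. = FALSE)
  }
  idx
}

# per-epoch connectivity for one set of segment spectra; returns a named
# list of channel x channel matrices, one per requested estimator x band
epoch_connectivity <- function(cs, bands, estimators) {
  d <- dim(cs$coef)
  nch <- d[3]
  pair <- which(upper.tri(matrix(0, nch, nch)), arr.ind = TRUE)
  pi_ <- pair[, 1]; pj <- pair[, 2]
  out <- list()
  for (b in names(bands)) {
    bins <- band_bins(cs$freq, bands[[b]])
    acc <- list()
    for (est in estimators) acc[[est]] <- numeric(nrow(pair))
    for (f in bins) {
      Z <- cs$coef[, f, , drop = TRUE]
      if (is.null(dim(Z))) Z <- matrix(Z, nrow = d[1])
      M <- Z[, pi_, drop = FALSE] * Conj(Z[, pj, drop = FALSE])
      if ("wpli" %in% estimators) {
        im <- Im(M)
        num <- abs(colSums(im))
        den <- colSums(abs(im))
        acc$wpli <- acc$wpli + ifelse(den > 0, num / den, 0)
      }
      if ("coh" %in% estimators) {
        sxx <- colMeans(abs(Z)^2)
        if (any(sxx <= 0)) {
          stop(sprintf(
            "zero auto-spectrum in band '%s' (constant channel?)", b),
            call. = FALSE)
        }
        acc$coh <- acc$coh +
          abs(colMeans(M)) / sqrt(sxx[pi_] * sxx[pj])
      }
    }
    for (est in estimators) {
      v <- pmin(pmax(acc[[est]] / length(bins), 0), 1)
      W <- matrix(0, nch, nch)
      W[upper.tri(W)] <- v
      W <- W + t(W)
      out[[paste(est, b, sep = ".")]] <- W
    }
  }
  out
}

# shared driver: per-epoch connectivity stacks for several bands/estimators
connectivity_stacks <- function(epochs, bands, estimators,
                                segment_length = NULL,
                                segment_overlap = 0.5,
                                window = "hann") {
  stopifnot(inherits(epochs, "epoch_set"))
  fs <- attr(epochs, "sampling_rate")
  if (inherits(bands, "band")) bands <- stats::setNames(list(bands), bands$name)
  for (b in bands) check_band_nyquist(b, fs)
  segment_length <- segment_length %||% round(fs)
  d <- dim(epochs)
  stacks <- list()
  for (key in as.vector(outer(estimators, names(bands), paste, sep = "."))) {
    stacks[[key]] <- array(0, dim = c(d[1], d[2], d[2]))
  }
  for (e in seq_len(d[1])) {
    cs <- cross_spectra(epochs[e, , , drop = TRUE], fs,
                        segment_length = segment_length,
                        segment_overlap = segment_overlap,
                        window = window)
    mats <- epoch_connectivity(cs, bands, estimators)
    for (key in names(mats)) stacks[[key]][e, , ] <- mats[[key]]
  }
  prov <- attributes(epochs)[c("participant_id", "session_id", "condition",
                               "channel_labels")]
  lapply(stats::setNames(names(stacks), names(stacks)), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    structure(stacks[[key]],
              class = "connectivity_stack",
              estimator = parts[1],
              band = bands[[parts[2]]],
              participant_id = prov$participant_id,
              session_id = prov$session_id,
              condition = prov$condition,
              channel_labels = prov$channel_labels)
  })
}

#' Weighted phase lag index per epoch
#'
#' @param epochs an [epoch_signal()] result.
#' @param band a [band()].
#' @param segment_length Welch segment length in samples (default one
#'   second).
#' @param segment_overlap fractional overlap between segments.
#' @param window taper label.
#' @return a `connectivity_stack`: epochs x channels x channels array of
#'   symmetric wPLI matrices with zero diagonal, values in `[0, 1]`.
#' @export
wpli <- function(epochs, band, segment_length = NULL,
                 segment_overlap = 0.5, window = "hann") {
  connectivity_stacks(epochs, band, "wpli", segment_length,
                      segment_overlap, window)[[1]]
}

#' Spectral (magnitude) coherence per epoch
#'
#' @inheritParams wpli
#' @param squared if `TRUE`, return squared coherence instead of magnitude
#'   coherence.
#' @return a `connectivity_stack` of coherence matrices in `[0, 1]`.
#' @export
coherence <- function(epochs, band, segment_length = NULL,
                      segment_overlap = 0.5, window = "hann",
                      squared = FALSE) {
  st <- connectivity_stacks(epochs, band, "coh", segment_length,
                            segment_overlap, window)[[1]]
  if (squared) {
    at <- attributes(st)
    st <- st^2
    attributes(st) <- at
  }
  st
}

#' @export
print.connectivity_stack <- function(x, ...) {
  d <- dim(x)
  b <- attr(x, "band")
  cat(sprintf("<connectivity_stack> %s, band %s (%g-%g Hz): %d epochs x %d x %d\n",
              attr(x, "estimator"), b$name, b$low, b$high, d[1], d[2], d[3]))
  invisible(x)
}
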