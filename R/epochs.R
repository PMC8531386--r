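#' Cut a recording into fixed-length overlapping epochs
#'
#' Epochs start at multiples of `epoch_length - overlap` seconds from time
#' zero and the set is truncated to the first `max_epochs` epochs. The
#' default 8 s epochs with 4 s overlap capped at 50 epochs span
#' `(50 - 1) * 4 + 8 = 204` s, i.e. 3.4 min of consecutive data from a
#' 5-minute recording.
#'
#' @param rec an [recording()].
#' @param epoch_length epoch length in seconds.
#' @param overlap overlap between consecutive epochs in seconds
#'   (`0 <= overlap < epoch_length`).
#' @param max_epochs keep at most this many epochs (`Inf` for all).
#' @return an object of class `epoch_set`: an epochs x channels x samples
#'   array with sampling and provenance attributes.
#' @examples
#' rec <- recording(matrix(rnorm(2 * 256 * 16), 2), 256)
#' dim(epoch_signal(rec, 8, 4))
#' @export
epoch_signal <- function(rec, epoch_length = 8, overlap = 4,
                         max_epochs = 50) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (overlap < 0 || overlap >= epoch_length) {
    stop("need 0 <= overlap < epoch_length", call. = FALSE)
  }
  fs <- rec$sampling_rate
  len <- as.integer(round(epoch_length * fs))
  step <- as.integer(round((epoch_length - overlap) * fs))
  n <- ncol(rec$samples)
  if (n < len) {
    stop(sprintf("recording (%g s) is shorter than one epoch (%g s)",
                 n / fs, epoch_length), call. = FALSE)
  }
  starts <- seq(0L, n - len, by = step)
  if (is.finite(max_epochs) && length(starts) > max_epochs) {
    starts <- starts[seq_len(max_epochs)]
  }
  ep <- array(0, dim = c(length(starts), nrow(rec$samples), len))
  for (e in seq_along(starts)) {
    ep[e, , ] <- rec$samples[, (starts[e] + 1L):(starts[e] + len)]
  }
  structure(ep,
            class = "epoch_set",
            sampling_rate = fs,
            epoch_length = epoch_length,
            overlap = overlap,
            channel_labels = rec$channel_labels,
            participant_id = rec$participant_id,
            session_id = rec$session_id,
            condition = rec$condition)
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf(
    "<epoch_set> %d epochs x %d channels x %d samples (%g s, %g s overlap)\n",
    d[1], d[2], d[3], attr(x, "epoch_length"), attr(x, "overlap")))
  invisible(x)
}

#' Total time spanned by an epoch set
#'
#' @param n_epochs number of epochs.
#' @param epoch_length,overlap epoch geometry in seconds.
#' @return span in seconds: `(n_epochs - 1) * (epoch_length - overlap) +
#'   epoch_length`.
#' @examples
#' epoch_span(50, 8, 4) / 60   # minutes of consecutive data
#' @export
epoch_span <- function(n_epochs, epoch_length = 8, overlap = 4) {
  stopifnot(n_epochs >= 1)
  (n_epochs - 1) * (epoch_length - overlap) + epoch_length
}
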