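# Minimal European Data Format (EDF) I/O.
#
# EDF stores a fixed-width ASCII header (256 bytes + 256 per signal) followed
# by little-endian 16-bit samples, linearly mapped between per-channel
# physical and digital ranges. This writer emits continuous recordings with
# 1-second data records; study identifiers travel in the patient / recording
# identification fields. Quantization error per sample is bounded by half a
# step of (phys_max - phys_min) / (dig_max - dig_min).

edf_field <- function(x, width) {
  s <- formatC(as.character(x), width = -width)
  substr(s, 1L, width)
}

edf_num <- function(x, width) {
  s <- formatC(format(x, digits = 7, trim = TRUE, scientific = FALSE),
               width = -width)
  if (nchar(s) > width) s <- substr(s, 1L, width)
  s
}

#' Write a recording as EDF
#'
#' @param rec an [recording()]; the duration must be a whole number of
#'   seconds and the sampling rate an integer (one EDF data record per
#'   second).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$sampling_rate
  if (fs != round(fs)) stop("EDF export needs an integer sampling rate",
                            call. = FALSE)
  x <- rec$samples
  nch <- nrow(x)
  n <- ncol(x)
  if (n %% fs != 0) {
    stop("EDF export needs a whole number of seconds of data", call. = FALSE)
  }
  n_rec <- n %/% fs
  dmin <- -32768; dmax <- 32767
  pmin <- apply(x, 1, min)
  pmax <- apply(x, 1, max)
  flat <- pmax - pmin <= 0
  pmax[flat] <- pmax[flat] + 1

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_field("0", 8),
    edf_field(rec$participant_id, 80),
    edf_field(sprintf("session=%d condition=%s", rec$session_id,
                      rec$condition), 80),
    "01.01.00", "00.00.00",
    edf_field(256 * (nch + 1), 8),
    edf_field("", 44),
    edf_field(n_rec, 8),
    edf_num(1, 8),
    edf_field(nch, 4),
    paste(vapply(rec$channel_labels, edf_field, "", width = 16),
          collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field("uV", 8), nch), collapse = ""),
    paste(vapply(pmin, edf_num, "", width = 8), collapse = ""),
    paste(vapply(pmax, edf_num, "", width = 8), collapse = ""),
    paste(rep(edf_field(dmin, 8), nch), collapse = ""),
    paste(rep(edf_field(dmax, 8), nch), collapse = ""),
    paste(rep(edf_field("", 80), nch), collapse = ""),
    paste(rep(edf_field(fs, 8), nch), collapse = ""),
    paste(rep(edf_field("", 32), nch), collapse = "")
  )
  writeChar(hdr, con, eos = NULL)
  # read the physical limits back from their ASCII form so the scaling the
  # reader will apply is exactly the scaling used to digitize
  pmin_h <- as.numeric(vapply(pmin, edf_num, "", width = 8))
  pmax_h <- as.numeric(vapply(pmax, edf_num, "", width = 8))
  scale <- (dmax - dmin) / (pmax_h - pmin_h)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (ch in seq_len(nch)) {
      d <- round((x[ch, idx] - pmin_h[ch]) * scale[ch]) + dmin
      d <- pmin(pmax(d, dmin), dmax)
      writeBin(as.integer(d), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path path to an EDF file with equal sampling rates across signals.
#' @return an [recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  invisible(rd(8))                      # version
  patient <- rd(80)
  recid <- rd(80)
  invisible(rd(8)); invisible(rd(8))    # date, time
  invisible(rd(8))                      # header bytes
  invisible(rd(44))
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nch <- as.integer(rd(4))
  labels <- vapply(seq_len(nch), function(i) rd(16), "")
  invisible(replicate(nch, rd(80)))     # transducer
  invisible(replicate(nch, rd(8)))      # phys dim
  pmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  pmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rd(8), ""))
  invisible(replicate(nch, rd(80)))     # prefiltering
  nsamp <- as.integer(vapply(seq_len(nch), function(i) rd(8), ""))
  invisible(replicate(nch, rd(32)))
  if (anyNA(c(n_rec, rec_dur, nch, nsamp)) || rec_dur <= 0) {
    stop("malformed EDF header in ", path, call. = FALSE)
  }
  if (length(unique(nsamp)) != 1L) {
    stop("EDF signals with differing sampling rates are not supported",
         call. = FALSE)
  }
  fs <- nsamp[1] / rec_dur
  x <- matrix(0, nch, n_rec * nsamp[1])
  scale <- (pmax - pmin) / (dmax - dmin)
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nch)) {
      d <- readBin(con, "integer", n = nsamp[ch], size = 2, signed = TRUE,
                   endian = "little")
      x[ch, ((r - 1) * nsamp[ch] + 1):(r * nsamp[ch])] <-
        (d - dmin[ch]) * scale[ch] + pmin[ch]
    }
  }
  sess <- sub(".*session=([0-9]+).*", "\\1", recid)
  cond <- sub(".*condition=([A-Za-z0-9]+).*", "\\1", recid)
  recording(x, fs, channel_labels = labels,
            participant_id = if (nzchar(patient)) patient else "P01",
            session_id = if (grepl("session=", recid)) as.integer(sess) else 1L,
            condition = if (grepl("condition=", recid)) cond else "PRE")
}
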