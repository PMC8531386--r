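#' Construct a multichannel recording
#'
#' A recording is a channels x samples numeric matrix with sampling metadata
#' and study identifiers (participant, session, condition).
#'
#' @param samples channels x samples numeric matrix.
#' @param sampling_rate sampling rate in Hz.
#' @param channel_labels character vector, one label per channel.
#' @param participant_id,session_id,condition study identifiers.
#' @return an object of class `eeg_recording`.
#' @export
recording <- function(samples, sampling_rate,
                      channel_labels = NULL,
                      participant_id = "P01",
                      session_id = 1L,
                      condition = "PRE") {
  samples <- as.matrix(samples)
  if (!is.numeric(samples) || anyNA(samples)) {
    stop("`samples` must be a numeric matrix without missing values",
         call. = FALSE)
  }
  if (!is.numeric(sampling_rate) || sampling_rate <= 0) {
    stop("`sampling_rate` must be a positive number", call. = FALSE)
  }
  nch <- nrow(samples)
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("Ch%02d", seq_len(nch))
  }
  if (length(channel_labels) != nch) {
    stop("channel label count must equal channel count", call. = FALSE)
  }
  rownames(samples) <- channel_labels
  structure(
    list(
      samples = samples,
      sampling_rate = sampling_rate,
      channel_labels = channel_labels,
      participant_id = as.character(participant_id),
      session_id = as.integer(session_id),
      condition = as.character(condition)
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s session %d %s: %d channels x %d samples @ %g Hz (%.1f s)\n",
    x$participant_id, x$session_id, x$condition,
    nrow(x$samples), ncol(x$samples), x$sampling_rate,
    ncol(x$samples) / x$sampling_rate))
  invisible(x)
}

#' Write a recording to disk
#'
#' Two on-disk forms are supported: a tab-delimited samples x channels text
#' matrix with a JSON metadata sidecar (`<path>.tsv` + `<path>.json`), or
#' 16-bit EDF (`<path>.edf`, see [write_edf()]). The format is chosen from
#' the `format` argument or the file extension of `path`.
#'
#' @param rec an [recording()].
#' @param path output path; extension `.edf` selects EDF, `.tsv` (or no
#'   extension) selects the delimited form.
#' @param format `"matrix"` or `"edf"`; default inferred from `path`.
#' @return the paths written, invisibly.
#' @export
write_recording <- function(rec, path, format = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  ext <- tolower(tools::file_ext(path))
  format <- format %||% (if (ext == "edf") "edf" else "matrix")
  if (format == "edf") {
    if (ext != "edf") path <- paste0(path, ".edf")
    write_edf(rec, path)
    return(invisible(path))
  }
  base <- if (ext == "tsv") tools::file_path_sans_ext(path) else path
  tsv <- paste0(base, ".tsv")
  side <- paste0(base, ".json")
  m <- t(rec$samples)
  colnames(m) <- rec$channel_labels
  utils::write.table(m, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      sampling_rate = rec$sampling_rate,
      channel_labels = rec$channel_labels,
      participant_id = rec$participant_id,
      session_id = rec$session_id,
      condition = rec$condition
    ),
    side, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, side))
}

#' Read a recording from disk
#'
#' Counterpart of [write_recording()]: reads either an EDF file or a
#' delimited matrix plus JSON sidecar.
#'
#' @param path path to a `.edf` or `.tsv` file (the sidecar is found by
#'   swapping the extension).
#' @return an [recording()].
#' @export
read_recording <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "edf") return(read_edf(path))
  base <- tools::file_path_sans_ext(path)
  side <- paste0(base, ".json")
  if (!file.exists(side)) {
    stop("missing JSON sidecar for ", path, call. = FALSE)
  }
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    stop("sidecar ", side, " lacks a sampling_rate field", call. = FALSE)
  }
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  recording(t(m), meta$sampling_rate,
            channel_labels = meta$channel_labels %||% colnames(m),
            participant_id = meta$participant_id %||% "P01",
            session_id = meta$session_id %||% 1L,
            condition = meta$condition %||% "PRE")
}
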