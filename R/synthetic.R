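# Synthetic study generator: band-limited coupled oscillators with
# participant-specific coupling strengths, controllable between-session
# consistency, and an additive condition (exercise) effect; plus scalar
# two-way tables with known variance components as an analytic oracle for
# the reliability statistics.

#' Describe a two-session, two-condition study design
#'
#' @param n_participants number of participants (>= 2).
#' @param sessions number of repeated sessions (>= 2 for reliability).
#' @param conditions ordered condition labels; default `c("PRE", "POST")`.
#' @param duration recording length in seconds.
#' @param n_channels montage size; 19 by default, 65 mirrors a 64-channel
#'   cap with restored reference.
#' @param sampling_rate sampling rate in Hz (256 by default).
#' @param seed default base seed carried by the design.
#' @return an object of class `study_design`.
#' @examples
#' study_design(n_participants = 4, duration = 30)
#' @export
study_design <- function(n_participants = 15, sessions = 2,
                         conditions = c("PRE", "POST"),
                         duration = 300, n_channels = 19,
                         sampling_rate = 256, seed = 1L) {
  stopifnot(n_participants >= 2, sessions >= 2, length(conditions) >= 1,
            duration > 0, n_channels >= 2, sampling_rate > 0)
  n_samples <- duration * sampling_rate
  if (abs(n_samples - round(n_samples)) > 1e-9) {
    stop("duration x sampling_rate must be an integer sample count",
         call. = FALSE)
  }
  structure(
    list(n_participants = as.integer(n_participants),
         sessions = as.integer(sessions),
         conditions = as.character(conditions),
         duration = duration,
         n_channels = as.integer(n_channels),
         sampling_rate = sampling_rate,
         seed = as.integer(seed)),
    class = "study_design")
}

#' Specify lagged inter-channel coupling for one frequency band
#'
#' Each edge injects a shared band-limited latent oscillation into its two
#' channels, delayed at the second channel so the pair carries a non-zero
#' phase lag, and scaled by edge strength times participant strength.
#'
#' @param band a [band()] the latent oscillations live in.
#' @param edges data frame with columns `from`, `to` (channel indices),
#'   `strength` (in `[0, 1]`) and `lag` (radians at the band center,
#'   in `(-pi, pi]`).
#' @param noise_sd standard deviation of the independent Gaussian sensor
#'   noise added to every channel.
#' @param session_consistency correlation `rho` in `[-1, 1]` between a
#'   participant's session-1 and session-2 latent coupling strengths.
#'   `rho = 1` is the exact-replication limit: repeated sessions reuse the
#'   same generative stream and are bit-identical.
#' @param condition_shift additive change of coupling strength for the
#'   second (POST) condition.
#' @param waveform `"noise"` for band-pass-filtered Gaussian noise latents
#'   (realistic spectral spread) or `"sine"` for pure tones at the band
#'   center (analytic test cases).
#' @return an object of class `coupling_spec`.
#' @export
coupling_spec <- function(band, edges, noise_sd = 2,
                          session_consistency = 0.8,
                          condition_shift = 0,
                          waveform = c("noise", "sine")) {
  waveform <- match.arg(waveform)
  stopifnot(inherits(band, "band"), is.data.frame(edges))
  need <- c("from", "to", "strength", "lag")
  if (!all(need %in% names(edges))) {
    stop("`edges` needs columns from, to, strength, lag", call. = FALSE)
  }
  if (any(edges$strength < 0 | edges$strength > 1)) {
    stop("edge strengths must lie in [0, 1]", call. = FALSE)
  }
  if (any(edges$lag <= -pi | edges$lag > pi)) {
    stop("phase lags must lie in (-pi, pi]", call. = FALSE)
  }
  if (abs(session_consistency) > 1) {
    stop("session_consistency must lie in [-1, 1]", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(
    list(band = band, edges = edges, noise_sd = noise_sd,
         session_consistency = session_consistency,
         condition_shift = condition_shift, waveform = waveform),
    class = "coupling_spec")
}

#' Default multi-band coupling layout
#'
#' A ring of lagged couplings (channel i to i+1) in every analysis band, so
#' each channel carries oscillatory power in each band and every band has a
#' coupled network for the connectivity estimators to recover.
#'
#' @param n_channels montage size.
#' @param bands list of [band()] objects; defaults to [default_bands()].
#' @param strength edge coupling strength.
#' @param lag phase lag in radians at each band's center frequency.
#' @param ... passed on to [coupling_spec()] (noise_sd,
#'   session_consistency, condition_shift, waveform).
#' @return a list of [coupling_spec()] objects, one per band.
#' @export
default_coupling <- function(n_channels, bands = default_bands(),
                             strength = 1, lag = pi / 4, ...) {
  stopifnot(n_channels >= 2)
  from <- seq_len(n_channels)
  to <- c(seq_len(n_channels)[-1], 1L)
  if (n_channels == 2) { from <- 1L; to <- 2L }
  edges <- data.frame(from = from, to = to, strength = strength, lag = lag)
  lapply(bands, function(b) coupling_spec(b, edges, ...))
}

#' Known variance components for a two-way outcome table
#'
#' The generative model is `y_ij = mu + r_i + c_j + e_ij` with independent
#' zero-mean Gaussian subject, session and residual effects. Its analytic
#' intraclass correlation is
#' `var_subject / (var_subject + var_session + var_error)`.
#'
#' @param mu grand mean.
#' @param var_subject,var_session,var_error variances (>= 0).
#' @return an object of class `variance_components`.
#' @export
variance_components <- function(mu = 0, var_subject = 1, var_session = 0,
                                var_error = 1) {
  if (var_subject < 0 || var_session < 0 || var_error < 0) {
    stop("variance components must be >= 0", call. = FALSE)
  }
  structure(list(mu = mu, var_subject = var_subject,
                 var_session = var_session, var_error = var_error),
            class = "variance_components")
}

#' Analytic intraclass correlation of a variance-components model
#'
#' @param vc a [variance_components()].
#' @return `var_subject / (var_subject + var_session + var_error)`.
#' @export
analytic_icc <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  denom <- vc$var_subject + vc$var_session + vc$var_error
  if (denom <= 0) stop("total variance must be > 0", call. = FALSE)
  vc$var_subject / denom
}

# band-limited unit-variance latent of length n (+ lead samples for lags)
make_latent <- function(n, band, sampling_rate, waveform) {
  if (waveform == "sine") {
    f <- (band$low + band$high) / 2
    phase <- stats::runif(1, 0, 2 * pi)
    s <- sin(2 * pi * f * (seq_len(n) - 1) / sampling_rate + phase)
    return(s * sqrt(2))
  }
  # generate on a highly composite length (fast FFT) and slice to n
  m <- stats::nextn(n)
  w <- stats::rnorm(m)
  W <- stats::fft(w)
  freq <- (seq_len(m) - 1) / m * sampling_rate
  freq <- pmin(freq, sampling_rate - freq)   # fold to [0, fs/2]
  keep <- freq >= band$low & freq <= band$high
  W[!keep] <- 0
  s <- Re(stats::fft(W, inverse = TRUE))[seq_len(n)] / m
  sd_s <- stats::sd(s)
  if (sd_s == 0) stop("degenerate latent (band too narrow for length)",
                      call. = FALSE)
  s / sd_s
}

#' Generate one multichannel surrogate recording
#'
#' Each coupled channel pair shares a band-limited latent oscillation,
#' injected into the lagging channel with a fixed sample delay matched to
#' the requested phase lag at the band's center frequency, scaled by edge
#' strength times the participant's coupling strength. Independent Gaussian
#' sensor noise is added to every channel. Deterministic given `seed`.
#'
#' @param design a [study_design()].
#' @param spec a [coupling_spec()] or a list of them (one per band).
#' @param participant_strength scalar coupling strength in `[0, 1]`.
#' @param seed integer seed.
#' @param participant_id,session_id,condition identifiers stored on the
#'   returned recording.
#' @return an [recording()].
#' @export
generate_recording <- function(design, spec, participant_strength = 0.6,
                               seed = design$seed,
                               participant_id = "P01", session_id = 1L,
                               condition = design$conditions[1]) {
  stopifnot(inherits(design, "study_design"))
  if (inherits(spec, "coupling_spec")) spec <- list(spec)
  stopifnot(all(vapply(spec, inherits, TRUE, "coupling_spec")))
  if (participant_strength < 0 || participant_strength > 1) {
    stop("participant_strength must lie in [0, 1]", call. = FALSE)
  }
  fs <- design$sampling_rate
  n <- as.integer(round(design$duration * fs))
  nch <- design$n_channels
  for (sp in spec) check_band_nyquist(sp$band, fs)

  with_seed(seed, {
    x <- matrix(0, nch, n)
    for (sp in spec) {
      fc <- (sp$band$low + sp$band$high) / 2
      for (e in seq_len(nrow(sp$edges))) {
        i <- sp$edges$from[e]; j <- sp$edges$to[e]
        if (i < 1 || j < 1 || i > nch || j > nch || i == j) {
          stop("coupling edge references an invalid channel", call. = FALSE)
        }
        delay <- as.integer(round(sp$edges$lag[e] / (2 * pi * fc) * fs))
        amp <- sp$edges$strength[e] * participant_strength
        lat <- make_latent(n + abs(delay), sp$band, fs, sp$waveform)
        if (delay >= 0) {
          lead <- lat[(delay + 1):(delay + n)]   # leading channel
          lagg <- lat[1:n]                       # lagging channel
        } else {
          lead <- lat[1:n]
          lagg <- lat[(-delay + 1):(-delay + n)]
        }
        x[i, ] <- x[i, ] + amp * lead
        x[j, ] <- x[j, ] + amp * lagg
      }
    }
    noise_sd <- spec[[1]]$noise_sd
    if (noise_sd > 0) {
      x <- x + matrix(stats::rnorm(nch * n, sd = noise_sd), nch, n)
    }
    recording(x, fs, participant_id = participant_id,
              session_id = session_id, condition = condition)
  })
}

#' Generate a full two-session, two-condition study
#'
#' Participant coupling strengths are drawn once per participant on a latent
#' normal scale (`strength_mean`, `strength_sd`, clipped to `[0, 1]`);
#' session-2 latents correlate with session-1 latents at
#' `session_consistency` (Gaussian copula); strengths for the second
#' condition are shifted by `condition_shift` and re-clipped. When
#' `session_consistency == 1` repeated sessions reuse the same per-recording
#' generative stream and are exact replicates.
#'
#' @param design a [study_design()].
#' @param spec a [coupling_spec()] or list of them; defaults to
#'   [default_coupling()] across [default_bands()].
#' @param seed integer base seed; every recording derives its own substream.
#' @param strength_mean,strength_sd location and spread of participant
#'   coupling strengths before clipping.
#' @return a list of [recording()] objects (participant x session x
#'   condition), with the drawn strength matrix in the `"strengths"`
#'   attribute.
#' @export
generate_study <- function(design, spec = default_coupling(design$n_channels),
                           seed = design$seed,
                           strength_mean = 0.6, strength_sd = 0.2) {
  stopifnot(inherits(design, "study_design"))
  if (inherits(spec, "coupling_spec")) spec <- list(spec)
  rho <- spec[[1]]$session_consistency
  shift <- spec[[1]]$condition_shift
  np <- design$n_participants
  ns <- design$sessions
  z <- with_seed(seed, {
    z1 <- stats::rnorm(np)
    zs <- matrix(0, np, ns)
    zs[, 1] <- z1
    for (s in seq_len(ns)[-1]) {
      eps <- stats::rnorm(np)
      zs[, s] <- rho * z1 + sqrt(max(0, 1 - rho^2)) * eps
    }
    zs
  })
  strengths <- pmin(pmax(strength_mean + strength_sd * z, 0), 1)
  dimnames(strengths) <- list(sprintf("P%02d", seq_len(np)),
                              sprintf("S%d", seq_len(ns)))
  recs <- list()
  for (p in seq_len(np)) {
    for (s in seq_len(ns)) {
      for (ci in seq_along(design$conditions)) {
        s_eff <- if (rho == 1) 1L else s
        st <- pmin(pmax(strengths[p, s] + (ci - 1) * shift, 0), 1)
        rec <- generate_recording(
          design, spec, participant_strength = st,
          seed = child_seed(seed, p, ci, s_eff),
          participant_id = sprintf("P%02d", p),
          session_id = s, condition = design$conditions[ci])
        recs[[length(recs) + 1L]] <- rec
      }
    }
  }
  attr(recs, "strengths") <- strengths
  attr(recs, "design") <- design
  recs
}

#' Generate a subjects x sessions table with known variance components
#'
#' `y_ij = mu + r_i + c_j + e_ij` with independent zero-mean Gaussian draws
#' at the specified variances; deterministic given `seed`.
#'
#' @param n number of subjects (>= 2).
#' @param k number of sessions (>= 2).
#' @param vc a [variance_components()].
#' @param seed integer seed.
#' @return an n x k numeric matrix.
#' @export
generate_two_way_table <- function(n, k, vc, seed = 1L) {
  stopifnot(inherits(vc, "variance_components"), n >= 2, k >= 2)
  with_seed(seed, {
    r <- stats::rnorm(n, sd = sqrt(vc$var_subject))
    c_ <- stats::rnorm(k, sd = sqrt(vc$var_session))
    e <- matrix(stats::rnorm(n * k, sd = sqrt(vc$var_error)), n, k)
    vc$mu + outer(r, rep(1, k)) + outer(rep(1, n), c_) + e
  })
}
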