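# End-to-end orchestration: simulate (or read) recordings -> band-resolved
# connectivity -> weighted graph metrics -> reliability tables, ANOVA and
# paired bootstrap effect sizes, with a resolved-config snapshot and run
# manifest for reproducibility.

#' Assemble a pipeline configuration
#'
#' All stage parameters with their defaults: the two-session PRE/POST
#' design (15 participants, 5-minute recordings at 256 Hz), 8 s epochs
#' overlapping by 4 s capped at 50, 1 s Hann segments with 50% overlap,
#' both estimators over the five standard bands, and 1000 bootstrap
#' cycles.
#'
#' @param out_dir output directory for result files.
#' @param input_dir optional directory of existing recordings (`.tsv` +
#'   sidecar or `.edf`); when `NULL`, recordings are simulated.
#' @param n_participants,sessions,conditions,duration,n_channels,sampling_rate
#'   study design, see [study_design()].
#' @param noise_sd,session_consistency,condition_shift,waveform,strength_mean,strength_sd
#'   synthetic coupling parameters, see [coupling_spec()] and
#'   [generate_study()].
#' @param bands named list of [band()] objects.
#' @param estimators subset of `c("wpli", "coh")`.
#' @param epoch_length,overlap,max_epochs epoching parameters.
#' @param segment_length,segment_overlap,window spectral parameters.
#' @param aggregate_matrices average normalized matrices before graph
#'   computation instead of per-epoch graphs.
#' @param k_cycles bootstrap cycles for the condition comparison.
#' @param n_boot_cov bootstrap resamples for the CoV interval.
#' @param seed base seed for every stochastic stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            input_dir = NULL,
                            n_participants = 15, sessions = 2,
                            conditions = c("PRE", "POST"),
                            duration = 300, n_channels = 19,
                            sampling_rate = 256,
                            noise_sd = 2, session_consistency = 0.8,
                            condition_shift = 0.1, waveform = "noise",
                            strength_mean = 0.6, strength_sd = 0.2,
                            bands = default_bands(),
                            estimators = c("wpli", "coh"),
                            epoch_length = 8, overlap = 4, max_epochs = 50,
                            segment_length = NULL, segment_overlap = 0.5,
                            window = "hann",
                            aggregate_matrices = FALSE,
                            k_cycles = 1000, n_boot_cov = 2000,
                            seed = 1L) {
  estimators <- match.arg(estimators, c("wpli", "coh"), several.ok = TRUE)
  stopifnot(length(bands) >= 1, length(estimators) >= 1)
  cfg <- list(out_dir = out_dir, input_dir = input_dir,
              n_participants = n_participants, sessions = sessions,
              conditions = conditions, duration = duration,
              n_channels = n_channels, sampling_rate = sampling_rate,
              noise_sd = noise_sd, session_consistency = session_consistency,
              condition_shift = condition_shift, waveform = waveform,
              strength_mean = strength_mean, strength_sd = strength_sd,
              bands = bands, estimators = estimators,
              epoch_length = epoch_length, overlap = overlap,
              max_epochs = max_epochs, segment_length = segment_length,
              segment_overlap = segment_overlap, window = window,
              aggregate_matrices = aggregate_matrices,
              k_cycles = k_cycles, n_boot_cov = n_boot_cov,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

config_as_json <- function(cfg) {
  c2 <- unclass(cfg)
  c2$bands <- lapply(cfg$bands, function(b) list(name = b$name, low = b$low,
                                                 high = b$high))
  c2
}

#' Reliability analysis of a tidy outcome table
#'
#' Takes the long outcome table produced by [graph_outcomes()] /
#' [run_pipeline()] (columns participant, session, condition, estimator,
#' band, CC, PL, SWI) and computes, per estimator x band x outcome x
#' condition: per-session means and SDs, ICC with 95% CI and category, SEM
#' and CoV with bootstrap CI, the session paired t test, and (when two
#' conditions are present) bootstrap effect sizes of the condition
#' difference in ICC and in CoV, plus the 2 x 2 repeated-measures ANOVA.
#'
#' @param outcomes tidy outcome data frame.
#' @param k_cycles bootstrap cycles for the condition comparison.
#' @param n_boot_cov bootstrap resamples for the CoV interval.
#' @param seed integer base seed.
#' @return list with data frames `reliability` and `anova`.
#' @export
reliability_analysis <- function(outcomes, k_cycles = 1000,
                                 n_boot_cov = 2000, seed = 1L) {
  metrics <- c("CC", "PL", "SWI")
  ests <- unique(outcomes$estimator)
  bands <- unique(outcomes$band)
  conds <- unique(outcomes$condition)
  sessions <- sort(unique(outcomes$session))
  rel_rows <- list()
  anova_rows <- list()
  comp_i <- 0L
  for (est in ests) for (b in bands) for (m in metrics) {
    comp_i <- comp_i + 1L
    tabs <- list()
    for (cond in conds) {
      sub <- outcomes[outcomes$estimator == est & outcomes$band == b &
                        outcomes$condition == cond, ]
      tab <- stats::reshape(
        sub[, c("participant", "session", m)],
        idvar = "participant", timevar = "session", direction = "wide")
      rownames(tab) <- tab$participant
      tab <- as.matrix(tab[order(tab$participant), -1, drop = FALSE])
      tabs[[cond]] <- tab
    }
    es <- list()
    if (length(conds) == 2L) {
      for (statistic in c("icc", "cov")) {
        cmp <- bootstrap_reliability_compare(
          tabs[[conds[1]]], tabs[[conds[2]]], statistic = statistic,
          k_cycles = k_cycles, seed = child_seed(seed, comp_i))
        es[[statistic]] <- cmp$effect_size_d
      }
    }
    for (cond in conds) {
      tab <- tabs[[cond]]
      ir <- icc_absolute_single(tab)
      cv <- sem_and_cov(tab, icc = ir$icc, n_boot = n_boot_cov,
                        seed = child_seed(seed, comp_i, match(cond, conds)))
      tt <- paired_t(tab[, 1], tab[, 2])
      row <- data.frame(estimator = est, band = b, outcome = m,
                        condition = cond, stringsAsFactors = FALSE)
      for (s in seq_along(sessions)) {
        row[[sprintf("mean_s%d", s)]] <- mean(tab[, s])
        row[[sprintf("sd_s%d", s)]] <- stats::sd(tab[, s])
      }
      row$icc <- ir$icc
      row$icc_lb <- ir$ci_low
      row$icc_ub <- ir$ci_high
      row$icc_category <- ir$category
      row$icc_es <- if (cond == conds[1] || length(conds) != 2L)
        NA_real_ else es$icc
      row$sem <- cv$sem
      row$cov_percent <- cv$cov_percent
      row$cov_lb <- cv$ci_low
      row$cov_ub <- cv$ci_high
      row$cov_es <- if (cond == conds[1] || length(conds) != 2L)
        NA_real_ else es$cov
      row$t_session <- tt$t
      row$p_session <- tt$p
      rel_rows[[length(rel_rows) + 1L]] <- row
    }
    if (length(conds) == 2L && length(sessions) == 2L) {
      sub <- outcomes[outcomes$estimator == est & outcomes$band == b, ]
      adf <- data.frame(participant = sub$participant,
                        exercise = sub$condition,
                        session = sub$session,
                        value = sub[[m]])
      an <- rm_anova_2x2(adf)
      an$estimator <- est; an$band <- b; an$outcome <- m
      anova_rows[[length(anova_rows) + 1L]] <- an
    }
  }
  rel <- do.call(rbind, rel_rows)
  rownames(rel) <- NULL
  anova <- if (length(anova_rows)) do.call(rbind, anova_rows) else NULL
  if (!is.null(anova)) {
    anova <- anova[, c("estimator", "band", "outcome", "effect",
                       "df1", "df2", "F", "p")]
    rownames(anova) <- NULL
  }
  list(reliability = rel, anova = anova)
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> epoch -> connectivity -> graph metrics ->
#' reliability. Writes `outcomes.csv`, `reliability.csv`, `anova.csv`,
#' `config.json`, `manifest.json` and `run.log` into `config$out_dir`.
#' Fully deterministic given `config$seed`.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return list with `outcomes`, `reliability`, `anova` data frames and
#'   `paths` of the files written, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  log_con <- file(log_path, "w")
  on.exit(close(log_con), add = TRUE)
  logmsg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    writeLines(line, log_con)
    if (!quiet) message(line)
  }
  jsonlite::write_json(config_as_json(config),
                       file.path(config$out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  timing <- list()

  # stage 1: recordings
  t0 <- Sys.time()
  if (!is.null(config$input_dir)) {
    files <- list.files(config$input_dir, pattern = "\\.(tsv|edf)$",
                        full.names = TRUE)
    if (length(files) == 0L) {
      stop("input stage: no .tsv/.edf recordings in ", config$input_dir,
           call. = FALSE)
    }
    recs <- lapply(sort(files), read_recording)
    rates <- unique(vapply(recs, function(r) r$sampling_rate, numeric(1)))
    if (length(rates) != 1L) {
      stop("input stage: sampling rate mismatch across recordings",
           call. = FALSE)
    }
    logmsg("loaded %d recordings from %s", length(recs), config$input_dir)
  } else {
    design <- study_design(config$n_participants, config$sessions,
                           config$conditions, config$duration,
                           config$n_channels, config$sampling_rate,
                           seed = config$seed)
    spec <- default_coupling(config$n_channels, config$bands,
                             noise_sd = config$noise_sd,
                             session_consistency = config$session_consistency,
                             condition_shift = config$condition_shift,
                             waveform = config$waveform)
    recs <- generate_study(design, spec, seed = config$seed,
                           strength_mean = config$strength_mean,
                           strength_sd = config$strength_sd)
    logmsg("simulated %d recordings (%d participants x %d sessions x %d conditions)",
           length(recs), config$n_participants, config$sessions,
           length(config$conditions))
  }
  timing$recordings <- as.numeric(Sys.time() - t0, units = "secs")

  # stage 2+3: connectivity and graph metrics
  t0 <- Sys.time()
  rows <- vector("list", length(recs))
  for (i in seq_along(recs)) {
    rows[[i]] <- graph_outcomes(
      recs[[i]], bands = config$bands, estimators = config$estimators,
      epoch_length = config$epoch_length, overlap = config$overlap,
      max_epochs = config$max_epochs,
      segment_length = config$segment_length,
      segment_overlap = config$segment_overlap, window = config$window,
      aggregate_matrices = config$aggregate_matrices)
    if (i %% 10 == 0) logmsg("graph metrics: %d/%d recordings", i,
                             length(recs))
  }
  outcomes <- do.call(rbind, rows)
  rownames(outcomes) <- NULL
  timing$graph_metrics <- as.numeric(Sys.time() - t0, units = "secs")
  out_csv <- file.path(config$out_dir, "outcomes.csv")
  utils::write.csv(outcomes, out_csv, row.names = FALSE)
  logmsg("wrote %s (%d rows)", out_csv, nrow(outcomes))

  # stage 4: reliability
  t0 <- Sys.time()
  rel <- reliability_analysis(outcomes, k_cycles = config$k_cycles,
                              n_boot_cov = config$n_boot_cov,
                              seed = config$seed)
  timing$reliability <- as.numeric(Sys.time() - t0, units = "secs")
  rel_csv <- file.path(config$out_dir, "reliability.csv")
  utils::write.csv(rel$reliability, rel_csv, row.names = FALSE)
  logmsg("wrote %s (%d rows)", rel_csv, nrow(rel$reliability))
  anova_csv <- NULL
  if (!is.null(rel$anova)) {
    anova_csv <- file.path(config$out_dir, "anova.csv")
    utils::write.csv(rel$anova, anova_csv, row.names = FALSE)
    logmsg("wrote %s (%d rows)", anova_csv, nrow(rel$anova))
  }

  version <- tryCatch(as.character(utils::packageVersion("graphrely")),
                      error = function(e) NA_character_)
  manifest <- list(
    package_version = version,
    seed = config$seed,
    n_recordings = length(recs),
    n_outcome_rows = nrow(outcomes),
    n_reliability_rows = nrow(rel$reliability),
    stage_seconds = timing,
    total_seconds = as.numeric(Sys.time() - t_start, units = "secs"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  paths <- c(outcomes = out_csv, reliability = rel_csv,
             anova = anova_csv %||% NA_character_,
             config = file.path(config$out_dir, "config.json"),
             manifest = file.path(config$out_dir, "manifest.json"),
             log = log_path)
  invisible(list(outcomes = outcomes, reliability = rel$reliability,
                 anova = rel$anova, paths = paths))
}
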