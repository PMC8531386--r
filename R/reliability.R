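# Relative and absolute test-retest reliability on subjects x sessions
# tables: single-rating absolute-agreement two-way ICC with F-based 95%
# confidence intervals, SEM and CoV with bootstrap intervals, a paired
# bootstrap comparison of reliability across conditions (Cohen's d on
# Fisher-z ICC distributions), and the 2x2 repeated-measures ANOVA.

check_two_way <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) {
    stop("two-way table must be numeric with no missing cells", call. = FALSE)
  }
  if (nrow(x) < 2L || ncol(x) < 2L) {
    stop("two-way table needs >= 2 subjects and >= 2 sessions", call. = FALSE)
  }
  x
}

# two-way mean squares: rows = subjects, columns = sessions
two_way_ms <- function(x) {
  n <- nrow(x); k <- ncol(x)
  g <- mean(x)
  rm_ <- rowMeans(x); cm <- colMeans(x)
  ssr <- k * sum((rm_ - g)^2)
  ssc <- n * sum((cm - g)^2)
  sst <- sum((x - g)^2)
  sse <- sst - ssr - ssc
  list(msr = ssr / (n - 1), msc = ssc / (k - 1),
       mse = sse / ((n - 1) * (k - 1)), n = n, k = k)
}

#' Single-rating absolute-agreement two-way ICC
#'
#' Implements `ICC = (MSR - MSE) / (MSR + (k - 1) MSE + (k / n)(MSC - MSE))`
#' with MSR, MSC, MSE the two-way mean squares for rows (subjects), columns
#' (sessions) and error. Estimates below 0 are reported as 0; the raw
#' (unclamped) value is retained in `icc_raw` for interval construction and
#' bootstrap work.
#'
#' @param x n subjects x k sessions numeric matrix.
#' @param ci if `TRUE` (default) attach the 95% F-based confidence
#'   interval, see [icc_confidence_interval()].
#' @param alpha interval level (default 0.05 for a 95% CI).
#' @return an object of class `icc_result`: `icc`, `icc_raw`, `ci_low`,
#'   `ci_high`, `msr`, `msc`, `mse`, `n`, `k`, `category`.
#' @examples
#' icc_absolute_single(matrix(c(1, 3, 2, 4), 2))   # icc = 0.8
#' @export
icc_absolute_single <- function(x, ci = TRUE, alpha = 0.05) {
  x <- check_two_way(x)
  ms <- two_way_ms(x)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (denom <= 0 || (ms$msr == 0 && ms$mse == 0 && ms$msc == 0)) {
    stop("ICC undefined: table has no variance", call. = FALSE)
  }
  raw <- (ms$msr - ms$mse) / denom
  icc <- max(0, raw)
  bounds <- if (ci) icc_ci_from_ms(ms, raw, alpha) else c(NA_real_, NA_real_)
  structure(
    list(icc = icc, icc_raw = raw,
         ci_low = bounds[1], ci_high = bounds[2],
         msr = ms$msr, msc = ms$msc, mse = ms$mse,
         n = ms$n, k = ms$k,
         category = categorize_icc(icc)),
    class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(A,1) = %.3f [%.3f %.3f] (%s), n = %d, k = %d\n",
              x$icc, x$ci_low, x$ci_high, x$category, x$n, x$k))
  invisible(x)
}

# F-distribution interval for the single-rating absolute-agreement ICC
# (McGraw-Wong construction), clamped to [0, 1] for reporting
icc_ci_from_ms <- function(ms, raw, alpha = 0.05) {
  n <- ms$n; k <- ms$k
  if (ms$mse == 0 && ms$msc == 0) return(c(1, 1))  # perfect agreement
  r <- min(raw, 1 - 1e-12)
  a <- k * r / (n * (1 - r))
  b <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (a * ms$msc + b * ms$mse)^2 /
    ((a * ms$msc)^2 / (k - 1) + (b * ms$mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, v)
  f2 <- stats::qf(1 - alpha / 2, v, n - 1)
  lo <- n * (ms$msr - f1 * ms$mse) /
    (f1 * (k * ms$msc + (k * n - k - n) * ms$mse) + n * ms$msr)
  hi <- n * (f2 * ms$msr - ms$mse) /
    (k * ms$msc + (k * n - k - n) * ms$mse + n * f2 * ms$msr)
  c(max(0, min(1, lo)), max(0, min(1, hi)))
}

#' Confidence interval for the two-way absolute-agreement ICC
#'
#' F-distribution-based interval for the single-rating absolute-agreement
#' two-way ICC; bounds are clamped to `[0, 1]` for reporting.
#'
#' @param x n x k numeric matrix.
#' @param alpha interval level (0.05 gives a 95% CI).
#' @return length-2 vector `c(ci_low, ci_high)`.
#' @export
icc_confidence_interval <- function(x, alpha = 0.05) {
  x <- check_two_way(x)
  ms <- two_way_ms(x)
  denom <- ms$msr + (ms$k - 1) * ms$mse + (ms$k / ms$n) * (ms$msc - ms$mse)
  if (denom <= 0 || (ms$msr == 0 && ms$mse == 0 && ms$msc == 0)) {
    stop("ICC undefined: table has no variance", call. = FALSE)
  }
  raw <- (ms$msr - ms$mse) / denom
  icc_ci_from_ms(ms, raw, alpha)
}

#' Qualitative ICC category
#'
#' poor (< 0.4), fair (0.4 to < 0.6), good (0.6 to < 0.75), excellent
#' (>= 0.75). Boundary points are assigned to the higher category.
#'
#' @param icc ICC value in `[0, 1]`.
#' @return one of `"poor"`, `"fair"`, `"good"`, `"excellent"`.
#' @examples
#' categorize_icc(0.65)
#' @export
categorize_icc <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1L, icc >= 0, icc <= 1)
  if (icc < 0.4) "poor"
  else if (icc < 0.6) "fair"
  else if (icc < 0.75) "good"
  else "excellent"
}

#' Standard error of measurement and coefficient of variation
#'
#' `SEM = SD_pooled * sqrt(1 - ICC)` with the between-subject SD pooled
#' across sessions, and `CoV = 100 * SEM / |grand mean|` (in percent). The
#' 95% interval comes from a seeded participant-level percentile bootstrap
#' in which the ICC is re-estimated inside every resample.
#'
#' @param x n x k numeric matrix.
#' @param icc ICC to plug into the SEM formula; defaults to the table's own
#'   [icc_absolute_single()] estimate.
#' @param n_boot bootstrap resamples for the interval (0 to skip).
#' @param seed integer seed for the bootstrap.
#' @param alpha interval level.
#' @return an object of class `cov_result`: `sem`, `cov_percent`,
#'   `ci_low`, `ci_high` (percent scale).
#' @examples
#' tab <- generate_two_way_table(12, 2, variance_components(100, 75, 0, 25),
#'                               seed = 7)
#' sem_and_cov(tab, n_boot = 200)
#' @export
sem_and_cov <- function(x, icc = NULL, n_boot = 2000, seed = 1L,
                        alpha = 0.05) {
  x <- check_two_way(x)
  g <- mean(x)
  if (abs(g) < .Machine$double.eps) {
    stop("CoV undefined: table grand mean is zero", call. = FALSE)
  }
  if (is.null(icc)) icc <- icc_absolute_single(x, ci = FALSE)$icc
  stopifnot(icc >= 0, icc <= 1)
  point <- sem_cov_point(x, icc)
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    n <- nrow(x)
    covs <- with_seed(seed, {
      idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), n, n_boot)
      vapply(seq_len(n_boot), function(b) {
        xb <- x[idx[, b], , drop = FALSE]
        if (abs(mean(xb)) < .Machine$double.eps) return(NA_real_)
        iccb <- tryCatch(icc_absolute_single(xb, ci = FALSE)$icc,
                         error = function(e) 0)
        sem_cov_point(xb, iccb)["cov"]
      }, numeric(1))
    })
    ci <- unname(stats::quantile(covs, c(alpha / 2, 1 - alpha / 2),
                                 na.rm = TRUE))
  }
  structure(list(sem = unname(point["sem"]),
                 cov_percent = unname(point["cov"]),
                 ci_low = ci[1], ci_high = ci[2]),
            class = "cov_result")
}

sem_cov_point <- function(x, icc) {
  sd_pooled <- sqrt(mean(apply(x, 2, stats::var)))
  sem <- sd_pooled * sqrt(max(0, 1 - icc))
  c(sem = sem, cov = 100 * sem / abs(mean(x)))
}

#' @export
print.cov_result <- function(x, ...) {
  cat(sprintf("SEM = %.4g, CoV = %.2f%% [%.2f %.2f]\n",
              x$sem, x$cov_percent, x$ci_low, x$ci_high))
  invisible(x)
}

#' Paired bootstrap comparison of reliability across two conditions
#'
#' Resamples participants with replacement `k_cycles` times and recomputes
#' the chosen reliability statistic per resample for both conditions. The
#' same resample indices are used for both tables (a paired bootstrap:
#' conditions share participants), so identical inputs give an effect size
#' of exactly 0. ICC distributions are Fisher-z transformed
#' (`atanh` of the raw, unclamped estimate clamped into
#' `[-(1 - 1e-6), 1 - 1e-6]`); CoV distributions stay on their raw percent
#' scale. The effect size is `|mean_a - mean_b|` over the pooled SD of the
#' two distributions (Cohen's d, reported sign-free).
#'
#' @param table_a,table_b n x k matrices for the two conditions (same n
#'   and k).
#' @param statistic `"icc"` or `"cov"`.
#' @param k_cycles number of bootstrap cycles (>= 100).
#' @param seed integer seed.
#' @return an object of class `bootstrap_comparison`: `k_cycles`,
#'   `dist_a`, `dist_b` (z scale for ICC, percent for CoV),
#'   `effect_size_d`, `n_degenerate`, `statistic`, `seed`.
#' @export
bootstrap_reliability_compare <- function(table_a, table_b,
                                          statistic = c("icc", "cov"),
                                          k_cycles = 1000, seed = 1L) {
  statistic <- match.arg(statistic)
  a <- check_two_way(table_a); b <- check_two_way(table_b)
  if (!all(dim(a) == dim(b))) {
    stop("both tables must share n and k", call. = FALSE)
  }
  if (k_cycles < 100) stop("k_cycles must be >= 100", call. = FALSE)
  n <- nrow(a)
  clamp <- 1 - 1e-6
  n_degenerate <- 0L
  stat_one <- function(x) {
    if (statistic == "icc") {
      raw <- tryCatch(icc_absolute_single(x, ci = FALSE)$icc_raw,
                      error = function(e) NA_real_)
      if (is.na(raw)) {
        n_degenerate <<- n_degenerate + 1L
        raw <- -clamp
      }
      atanh(min(max(raw, -clamp), clamp))
    } else {
      val <- tryCatch({
        iccb <- tryCatch(icc_absolute_single(x, ci = FALSE)$icc,
                         error = function(e) 0)
        sem_cov_point(x, iccb)["cov"]
      }, error = function(e) NA_real_)
      if (is.na(val)) {
        n_degenerate <<- n_degenerate + 1L
        val <- 0
      }
      unname(val)
    }
  }
  idx <- with_seed(seed,
                   matrix(sample.int(n, n * k_cycles, replace = TRUE),
                          n, k_cycles))
  dist_a <- vapply(seq_len(k_cycles),
                   function(c_) stat_one(a[idx[, c_], , drop = FALSE]),
                   numeric(1))
  dist_b <- vapply(seq_len(k_cycles),
                   function(c_) stat_one(b[idx[, c_], , drop = FALSE]),
                   numeric(1))
  pooled <- sqrt((stats::var(dist_a) + stats::var(dist_b)) / 2)
  d <- if (pooled == 0) 0 else abs(mean(dist_a) - mean(dist_b)) / pooled
  if (n_degenerate > 0) {
    message(sprintf("bootstrap_reliability_compare: %d degenerate cycles",
                    n_degenerate))
  }
  structure(list(k_cycles = as.integer(k_cycles),
                 dist_a = dist_a, dist_b = dist_b,
                 effect_size_d = d, n_degenerate = n_degenerate,
                 statistic = statistic, seed = as.integer(seed)),
            class = "bootstrap_comparison")
}

#' @export
print.bootstrap_comparison <- function(x, ...) {
  cat(sprintf("<bootstrap_comparison> %s, k = %d: Cohen's d = %.3f\n",
              x$statistic, x$k_cycles, x$effect_size_d))
  invisible(x)
}

#' Two-by-two repeated-measures ANOVA
#'
#' Fully within-subject 2 x 2 design (exercise: PRE vs POST; session: I vs
#' II). Each effect is tested against its own subject-by-effect error
#' stratum via `stats::aov` with an `Error(participant/...)` term, giving F
#' at (1, n - 1) degrees of freedom.
#'
#' @param df data frame with columns `participant`, `exercise`, `session`
#'   and `value`; every participant must have all four cells.
#' @return data frame with one row per effect (`exercise`, `session`,
#'   `exercise:session`): `df1`, `df2`, `F`, `p`.
#' @export
rm_anova_2x2 <- function(df) {
  need <- c("participant", "exercise", "session", "value")
  if (!all(need %in% names(df))) {
    stop("need columns participant, exercise, session, value", call. = FALSE)
  }
  df$participant <- factor(df$participant)
  df$exercise <- factor(df$exercise)
  df$session <- factor(df$session)
  n <- nlevels(df$participant)
  if (n < 3) stop("need at least 3 participants", call. = FALSE)
  if (nlevels(df$exercise) != 2L || nlevels(df$session) != 2L) {
    stop("exercise and session must each have exactly 2 levels", call. = FALSE)
  }
  counts <- table(df$participant, df$exercise, df$session)
  if (any(counts != 1L)) {
    stop("incomplete or duplicated cells in the 2x2 within-subject design",
         call. = FALSE)
  }
  fit <- stats::aov(value ~ exercise * session +
                      Error(participant / (exercise * session)), data = df)
  sm <- summary(fit)
  out <- data.frame(effect = c("exercise", "session", "exercise:session"),
                    df1 = NA_real_, df2 = NA_real_,
                    F = NA_real_, p = NA_real_,
                    stringsAsFactors = FALSE)
  ss_scale <- sum((df$value - mean(df$value))^2)
  for (stratum in sm) {
    tab <- stratum[[1]]
    terms <- trimws(rownames(tab))
    for (i in seq_along(terms)) {
      j <- match(terms[i], out$effect)
      if (!is.na(j)) {
        out$df1[j] <- tab[i, "Df"]
        out$df2[j] <- tab[nrow(tab), "Df"]
        # an effect whose sum of squares is numerically zero is a true null
        # (its F would otherwise be rounding dust over a zero error term)
        if (ss_scale > 0 && tab[i, "Sum Sq"] < 1e-10 * ss_scale) {
          out$F[j] <- 0
          out$p[j] <- 1
        } else {
          out$F[j] <- tab[i, "F value"]
          out$p[j] <- tab[i, "Pr(>F)"]
        }
      }
    }
  }
  out
}

#' Paired t test on matched outcome vectors
#'
#' Standard two-sided paired t test. Identical vectors (all differences
#' exactly zero) return `t = 0, p = 1`; a constant nonzero difference has
#' zero variance and raises an error.
#'
#' @param a,b matched numeric vectors of equal length >= 3.
#' @return list with `t`, `p`, `df`, `mean_diff`.
#' @export
paired_t <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3L) {
    stop("need matched vectors of equal length >= 3", call. = FALSE)
  }
  d <- a - b
  scale <- max(abs(d), 1)
  if (stats::sd(d) <= 1e-12 * scale) {
    if (max(abs(d)) <= 1e-12 * max(abs(c(a, b, 1)))) {
      return(list(t = 0, p = 1, df = length(d) - 1L, mean_diff = 0))
    }
    stop("t undefined: differences have zero variance but nonzero mean",
         call. = FALSE)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate))
}
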