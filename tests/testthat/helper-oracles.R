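# Independent oracles and fixture builders shared across test files.
# These deliberately re-derive quantities from first principles (brute-force
# enumeration, base-R model fits, hand-unrolled definitions) so they stay
# independent of the package's implementation paths.

# random symmetric weight matrix with zero diagonal, weights in (0, 1]
random_weight_matrix <- function(n, density = 1, rng_max = 1) {
  w <- matrix(0, n, n)
  up <- which(upper.tri(w))
  vals <- runif(length(up), 0.05, rng_max)
  if (density < 1) {
    drop <- runif(length(up)) > density
    vals[drop] <- 0
  }
  w[up] <- vals
  w <- w + t(w)
  diag(w) <- 0
  w
}

# brute-force geometric-mean weighted clustering: explicit triangle loops
oracle_clustering <- function(w) {
  n <- nrow(w)
  ci <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(w[i, ] > 0)
    if (k < 2) next
    acc <- 0
    for (j in seq_len(n)) for (h in seq_len(n)) {
      if (j < h && j != i && h != i) {
        acc <- acc + (w[i, j] * w[i, h] * w[j, h])^(1 / 3)
      }
    }
    ci[i] <- 2 * acc / (k * (k - 1))
  }
  mean(ci)
}

# brute-force characteristic path length: Floyd-Warshall on 1/w lengths
oracle_path_length <- function(w) {
  n <- nrow(w)
  d <- ifelse(w > 0, 1 / w, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  off <- !diag(TRUE, n)
  mean(d[off])
}

# independent ICC(A,1) via base-R anova mean squares on the long table
oracle_icc_a1 <- function(tab) {
  n <- nrow(tab); k <- ncol(tab)
  df <- data.frame(y = as.vector(tab),
                   subj = factor(rep(seq_len(n), k)),
                   sess = factor(rep(seq_len(k), each = n)))
  an <- anova(lm(y ~ subj + sess, data = df))
  msr <- an["subj", "Mean Sq"]
  msc <- an["sess", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

# brute-force within-subject 2x2 ANOVA by explicit sums of squares
oracle_rm_anova <- function(y) {
  # y: n x 2 x 2 array [participant, exercise, session]
  n <- dim(y)[1]
  res <- list()
  contrasts <- list(
    exercise = apply(y, 1, function(m) mean(m[2, ]) - mean(m[1, ])),
    session = apply(y, 1, function(m) mean(m[, 2]) - mean(m[, 1])),
    `exercise:session` = apply(y, 1, function(m)
      (m[2, 2] - m[2, 1]) - (m[1, 2] - m[1, 1])))
  for (eff in names(contrasts)) {
    d <- contrasts[[eff]]
    # F for a within-subject 2-level effect equals the squared one-sample t
    tstat <- mean(d) / (sd(d) / sqrt(n))
    res[[eff]] <- list(F = tstat^2,
                       p = pf(tstat^2, 1, n - 1, lower.tail = FALSE))
  }
  res
}

# hand-unrolled wPLI and magnitude coherence from the defining ratios,
# starting from raw segment time series (its own FFT and taper)
oracle_connectivity <- function(segments_x, segments_y, bins, win) {
  ns <- length(segments_x)
  imxy <- matrix(0, ns, length(bins))
  sxy <- matrix(0i, ns, length(bins))
  sxx <- syy <- matrix(0, ns, length(bins))
  for (s in seq_len(ns)) {
    X <- fft(segments_x[[s]] * win)
    Y <- fft(segments_y[[s]] * win)
    cross <- X[bins] * Conj(Y[bins])
    imxy[s, ] <- Im(cross)
    sxy[s, ] <- cross
    sxx[s, ] <- abs(X[bins])^2
    syy[s, ] <- abs(Y[bins])^2
  }
  wpli_f <- vapply(seq_along(bins), function(f) {
    den <- sum(abs(imxy[, f]))
    if (den == 0) 0 else abs(sum(imxy[, f])) / den
  }, numeric(1))
  coh_f <- vapply(seq_along(bins), function(f) {
    abs(mean(sxy[, f])) / sqrt(mean(sxx[, f]) * mean(syy[, f]))
  }, numeric(1))
  list(wpli = mean(wpli_f), coh = mean(coh_f))
}

# two-channel recording whose second channel is the first delayed
delayed_pair_recording <- function(freq, fs = 256, dur = 8,
                                   lag_frac = 0.25, noise = 0) {
  t <- (0:(fs * dur - 1)) / fs
  x <- sin(2 * pi * freq * t)
  y <- sin(2 * pi * freq * t - 2 * pi * lag_frac)
  if (noise > 0) {
    x <- x + rnorm(length(t), sd = noise)
    y <- y + rnorm(length(t), sd = noise)
  }
  recording(rbind(x, y), fs)
}
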