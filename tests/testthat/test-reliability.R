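# ICC, SEM/CoV, bootstrap comparison and ANOVA against hand evaluations,
# an independent base-R mean-squares oracle, and frozen values from an
# external reference implementation.

test_that("ICC formula matches hand evaluation of the two-way mean squares", {
  # n = 2, k = 2 table [[1,2],[3,4]]: MSR = 4, MSC = 1, MSE = 0
  tab <- matrix(c(1, 3, 2, 4), 2)
  res <- icc_absolute_single(tab)
  expect_equal(res$msr, 4)
  expect_equal(res$msc, 1)
  expect_equal(res$mse, 0)
  expect_equal(res$icc, 4 / 5)
  # perfect agreement: second session identical to the first
  perf <- cbind(c(1, 5, 9), c(1, 5, 9))
  pres <- icc_absolute_single(perf)
  expect_equal(pres$icc, 1)
  expect_equal(pres$ci_high, 1)
  expect_error(icc_absolute_single(matrix(2, 3, 2)), "no variance")
})

test_that("ICC point and CI match an external reference implementation", {
  # frozen from an independent ICC(A,1) computation (ANOVA mean squares +
  # F-based interval) on this exact table
  tab <- matrix(c(51.488832, 47.986062, 51.968412, 52.24988, 46.97638,
                  47.210779, 51.478222, 48.939187, 50.498707, 48.706645,
                  51.387226, 49.047273, 50.64161, 50.922247, 46.048004,
                  46.714711, 50.101151, 49.015381, 50.331842, 48.724733),
                nrow = 10)
  res <- icc_absolute_single(tab)
  expect_equal(res$icc, 0.895484327931, tolerance = 1e-9)
  expect_equal(res$ci_low, 0.618134793830, tolerance = 1e-6)
  expect_equal(res$ci_high, 0.973368726011, tolerance = 1e-6)
})

test_that("ICC matches the independent mean-squares oracle on 200 tables", {
  set.seed(17)
  for (i in 1:200) {
    n <- sample(4:20, 1); k <- sample(2:4, 1)
    tab <- matrix(rnorm(n * k, mean = 5), n, k) +
      rnorm(n, sd = runif(1, 0, 3))
    raw <- icc_absolute_single(tab, ci = FALSE)$icc_raw
    expect_equal(raw, oracle_icc_a1(tab), tolerance = 1e-10)
  }
})

test_that("ICC recovers known analytic values and its CI covers", {
  # mean recovered ICC within +/- 0.05 of the analytic value (n=15, k=2)
  for (target in c(0.2, 0.5, 0.75, 0.9)) {
    vc <- variance_components(mu = 1, var_subject = target, var_session = 0,
                              var_error = 1 - target)
    est <- vapply(1:1000, function(r) {
      icc_absolute_single(generate_two_way_table(15, 2, vc,
                                                 seed = 20000 + r),
                          ci = FALSE)$icc_raw
    }, numeric(1))
    expect_lt(abs(mean(est) - target), 0.05)
  }
  # 95% CI coverage for analytic ICC 0.75 in 93-97%
  vc <- variance_components(mu = 1, var_subject = 3, var_session = 0,
                            var_error = 1)
  hits <- vapply(1:1000, function(r) {
    ci <- icc_confidence_interval(generate_two_way_table(15, 2, vc,
                                                         seed = 50000 + r))
    ci[1] <= 0.75 && 0.75 <= ci[2]
  }, logical(1))
  expect_gte(mean(hits), 0.93)
  expect_lte(mean(hits), 0.97)
})

test_that("ICC and SEM are shift-invariant, CoV is not; clamping holds", {
  set.seed(5)
  tab <- generate_two_way_table(12, 2,
                                variance_components(10, 2, 0.5, 1), seed = 6)
  r1 <- icc_absolute_single(tab)
  r2 <- icc_absolute_single(tab + 100)
  expect_equal(r1$icc, r2$icc, tolerance = 1e-9)
  c1 <- sem_and_cov(tab, n_boot = 0)
  c2 <- sem_and_cov(tab + 100, n_boot = 0)
  expect_equal(c1$sem, c2$sem, tolerance = 1e-9)
  expect_false(isTRUE(all.equal(c1$cov_percent, c2$cov_percent)))
  # anti-correlated sessions push the raw estimate below zero: report 0
  anti <- cbind(c(1, 2, 3, 4, 5), c(5, 4, 3, 2, 1)) +
    matrix(rnorm(10, sd = 0.01), 5)
  res <- icc_absolute_single(anti)
  expect_lt(res$icc_raw, 0)
  expect_identical(res$icc, 0)
  expect_true(res$ci_low >= 0 && res$ci_high <= 1)
  expect_true(res$ci_low <= res$icc && res$icc <= res$ci_high)
})

test_that("ICC categories follow the poor/fair/good/excellent thresholds", {
  expect_equal(categorize_icc(0.38), "poor")
  expect_equal(categorize_icc(0.65), "good")
  expect_equal(categorize_icc(0.91), "excellent")
  # boundary points belong to the higher category
  expect_equal(categorize_icc(0.4), "fair")
  expect_equal(categorize_icc(0.6), "good")
  expect_equal(categorize_icc(0.75), "excellent")
  expect_equal(categorize_icc(0), "poor")
  expect_equal(categorize_icc(1), "excellent")
})

test_that("SEM and CoV follow their defining arithmetic", {
  # ICC = 1 -> SEM = 0 -> CoV = 0
  perf <- cbind(c(1, 5, 9), c(1, 5, 9))
  res <- sem_and_cov(perf, n_boot = 0)
  expect_equal(res$sem, 0)
  expect_equal(res$cov_percent, 0)
  # SD = 10, mean = 100, ICC = 0.75 -> SEM = 5, CoV = 5%
  base <- c(85.85786, 92.92893, 100, 107.07107, 114.14214)  # sd = 10 arms
  tab <- cbind(base, base)
  expect_equal(sd(base), 11.18034, tolerance = 1e-5)
  tab <- cbind(base, rev(base))  # engineered: pooled sd known
  sdp <- sqrt(mean(apply(tab, 2, var)))
  res2 <- sem_and_cov(tab, icc = 0.75, n_boot = 0)
  expect_equal(res2$sem, sdp * 0.5, tolerance = 1e-9)
  expect_equal(res2$cov_percent, 100 * sdp * 0.5 / mean(tab),
               tolerance = 1e-9)
  expect_error(sem_and_cov(cbind(c(-1, 1, 0), c(1, -1, 0))), "grand mean")
})

test_that("bootstrap CoV interval brackets the point estimate", {
  set.seed(9)
  ok <- vapply(1:30, function(r) {
    tab <- generate_two_way_table(15, 2,
                                  variance_components(50, 4, 0.5, 2),
                                  seed = 300 + r)
    res <- sem_and_cov(tab, n_boot = 400, seed = r)
    res$ci_low <= res$cov_percent && res$cov_percent <= res$ci_high
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("bootstrap comparison is deterministic and paired", {
  tab <- generate_two_way_table(15, 2, variance_components(10, 3, 0, 1),
                                seed = 2)
  c1 <- bootstrap_reliability_compare(tab, tab, "icc", k_cycles = 500,
                                      seed = 7)
  c2 <- bootstrap_reliability_compare(tab, tab, "icc", k_cycles = 500,
                                      seed = 7)
  expect_identical(c1$dist_a, c2$dist_a)
  expect_identical(c1$effect_size_d, c2$effect_size_d)
  # identical tables share resample indices -> d is exactly 0 (< 0.05)
  expect_equal(c1$effect_size_d, 0)
  expect_lt(c1$effect_size_d, 0.05)
  expect_length(c1$dist_a, 500)
  expect_error(bootstrap_reliability_compare(tab, tab[1:10, ], "icc"),
               "share n and k")
  expect_error(bootstrap_reliability_compare(tab, tab, "icc", k_cycles = 50),
               ">= 100")
})

test_that("well separated reliabilities give a large bootstrap effect size", {
  vc_hi <- variance_components(10, 0.9, 0, 0.1)   # analytic ICC 0.9
  vc_lo <- variance_components(10, 0.1, 0, 0.9)   # analytic ICC 0.1
  hi <- generate_two_way_table(15, 2, vc_hi, seed = 21)
  lo <- generate_two_way_table(15, 2, vc_lo, seed = 22)
  cmp <- bootstrap_reliability_compare(hi, lo, "icc", k_cycles = 1000,
                                       seed = 5)
  expect_gt(cmp$effect_size_d, 0.8)
  # back-transformed bootstrap mean lies within the sample ICC 95% CI
  ci <- icc_confidence_interval(hi)
  m <- tanh(mean(cmp$dist_a))
  expect_gte(m, ci[1])
  expect_lte(m, ci[2])
})

test_that("2x2 repeated-measures ANOVA matches its brute-force oracle", {
  set.seed(33)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    y <- array(rnorm(n * 4, mean = 10), dim = c(n, 2, 2))
    df <- expand.grid(participant = seq_len(n), exercise = c("PRE", "POST"),
                      session = c(1, 2))
    df$value <- mapply(function(p, e, s) y[p, ifelse(e == "PRE", 1, 2), s],
                       df$participant, df$exercise, df$session)
    res <- rm_anova_2x2(df)
    ora <- oracle_rm_anova(y)
    # factor levels: POST < PRE alphabetically, but F is direction-free
    for (eff in res$effect) {
      expect_equal(res$F[res$effect == eff], ora[[eff]]$F,
                   tolerance = 1e-10)
      expect_equal(res$p[res$effect == eff], ora[[eff]]$p,
                   tolerance = 1e-10)
      expect_equal(res$df1[res$effect == eff], 1)
      expect_equal(res$df2[res$effect == eff], n - 1)
    }
  }
})

test_that("ANOVA degenerate and error cases behave", {
  # POST = PRE + constant for everyone: zero interaction F
  n <- 6
  set.seed(8)
  base <- matrix(rnorm(n * 2, 10), n)
  df <- expand.grid(participant = seq_len(n), exercise = c("PRE", "POST"),
                    session = c(1, 2))
  df$value <- mapply(function(p, e, s)
    base[p, s] + ifelse(e == "POST", 3, 0),
    df$participant, df$exercise, df$session)
  res <- rm_anova_2x2(df)
  expect_equal(res$F[res$effect == "exercise:session"], 0,
               tolerance = 1e-10)
  expect_error(rm_anova_2x2(df[-1, ]), "incomplete")
  expect_error(rm_anova_2x2(df[, -4]), "columns")
})

test_that("paired t test matches the closed form and its conventions", {
  a <- c(3.1, 4.5, 2.2, 5.0, 3.7)
  b <- c(2.8, 4.9, 1.9, 4.2, 3.1)
  res <- paired_t(a, b)
  d <- a - b
  t_hand <- mean(d) / (sd(d) / sqrt(5))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-12)
  # identical vectors: t = 0, p = 1
  same <- paired_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  # adding a constant to both leaves t unchanged
  shifted <- paired_t(a + 7, b + 7)
  expect_equal(shifted$t, res$t, tolerance = 1e-12)
  # constant nonzero difference: undefined
  expect_error(paired_t(a, a + 1), "zero variance")
})
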