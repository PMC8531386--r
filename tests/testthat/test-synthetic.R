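test_that("generated recordings are deterministic given a seed", {
  des <- study_design(n_participants = 3, duration = 4, n_channels = 4,
                      seed = 9)
  sp <- default_coupling(4, default_bands()["alpha1"], noise_sd = 0.3)
  r1 <- generate_recording(des, sp, 0.7, seed = 42)
  r2 <- generate_recording(des, sp, 0.7, seed = 42)
  r3 <- generate_recording(des, sp, 0.7, seed = 43)
  expect_identical(r1$samples, r2$samples)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("zero coupling strength gives mutually independent channels", {
  des <- study_design(n_participants = 2, duration = 8, n_channels = 3,
                      seed = 1)
  sp <- default_coupling(3, default_bands()["alpha1"], noise_sd = 1)
  rec <- generate_recording(des, sp, participant_strength = 0, seed = 5)
  # with strength 0 every channel is pure iid noise: near-zero correlations
  cc <- cor(t(rec$samples))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.05)
})

test_that("latent oscillatory power concentrates inside the requested band", {
  des <- study_design(n_participants = 2, duration = 8, n_channels = 2,
                      seed = 1)
  for (bn in c("theta", "alpha1", "beta2")) {
    b <- default_bands()[[bn]]
    sp <- coupling_spec(b, data.frame(from = 1, to = 2, strength = 1,
                                      lag = pi / 4), noise_sd = 0)
    rec <- generate_recording(des, sp, 1, seed = 7)
    sp_est <- spec.pgram(rec$samples[1, ], plot = FALSE, taper = 0,
                         detrend = FALSE)
    freq_hz <- sp_est$freq * rec$sampling_rate
    inband <- freq_hz >= b$low & freq_hz <= b$high
    frac <- sum(sp_est$spec[inband]) / sum(sp_est$spec)
    expect_gt(frac, 0.8)
  }
})

test_that("invalid bands are rejected at generation time", {
  des <- study_design(n_participants = 2, duration = 2, n_channels = 2,
                      sampling_rate = 64, seed = 1)
  expect_error(band("bad", 10, 8), "invalid band")
  sp <- coupling_spec(band("hi", 30, 40),
                      data.frame(from = 1, to = 2, strength = 1,
                                 lag = pi / 4))
  expect_error(generate_recording(des, sp, 0.5, seed = 1), "Nyquist")
})

test_that("downstream wPLI increases with coupling strength", {
  des <- study_design(n_participants = 2, duration = 16, n_channels = 2,
                      seed = 1)
  b <- default_bands()$alpha1
  sp <- coupling_spec(b, data.frame(from = 1, to = 2, strength = 1,
                                    lag = pi / 2), noise_sd = 1)
  mean_wpli <- function(strength) {
    vals <- vapply(1:20, function(s) {
      rec <- generate_recording(des, sp, strength, seed = 100 + s)
      st <- wpli(epoch_signal(rec, 8, 4), b)
      mean(st[, 1, 2])
    }, numeric(1))
    mean(vals)
  }
  expect_gt(mean_wpli(0.8), mean_wpli(0.2))
})

test_that("generate_study yields the full participant x session x condition grid", {
  des <- study_design(n_participants = 15, sessions = 2, duration = 2,
                      n_channels = 2, sampling_rate = 64, seed = 3)
  sp <- default_coupling(2, default_bands()["alpha1"], noise_sd = 0.5)
  recs <- generate_study(des, sp, seed = 3)
  expect_length(recs, 15 * 2 * 2)
  ids <- vapply(recs, function(r)
    paste(r$participant_id, r$session_id, r$condition), "")
  expect_equal(length(unique(ids)), 60)
  strengths <- attr(recs, "strengths")
  expect_equal(dim(strengths), c(15, 2))
  expect_true(all(strengths >= 0 & strengths <= 1))
})

test_that("perfect session consistency replicates sessions exactly", {
  des <- study_design(n_participants = 3, sessions = 2, duration = 4,
                      n_channels = 4, seed = 11)
  sp <- default_coupling(4, default_bands()["alpha1"], noise_sd = 0.4,
                         session_consistency = 1, condition_shift = 0)
  recs <- generate_study(des, sp, seed = 11)
  for (p in c("P01", "P02", "P03")) {
    pair <- Filter(function(r) r$participant_id == p &&
                     r$condition == "PRE", recs)
    expect_identical(pair[[1]]$samples, pair[[2]]$samples)
  }
})

test_that("uncorrelated sessions give near-zero downstream ICC on average", {
  des <- study_design(n_participants = 8, sessions = 2, conditions = "PRE",
                      duration = 16, n_channels = 2, seed = 2)
  b <- default_bands()$alpha1
  sp <- coupling_spec(b, data.frame(from = 1, to = 2, strength = 1,
                                    lag = pi / 2),
                      noise_sd = 1.5, session_consistency = 0)
  raw_iccs <- vapply(1:50, function(rep) {
    recs <- generate_study(des, sp, seed = 1000 + rep,
                           strength_mean = 0.5, strength_sd = 0.25)
    tab <- matrix(0, 8, 2)
    for (r in recs) {
      st <- wpli(epoch_signal(r, 8, 4), b)
      p <- as.integer(sub("P", "", r$participant_id))
      tab[p, r$session_id] <- mean(st[, 1, 2])
    }
    icc_absolute_single(tab, ci = FALSE)$icc_raw
  }, numeric(1))
  expect_lt(abs(mean(raw_iccs)), 0.2)
})

test_that("two-way tables recover their variance components", {
  vc <- variance_components(mu = 10, var_subject = 4, var_session = 1,
                            var_error = 2)
  expect_equal(analytic_icc(vc), 4 / 7)
  tab <- generate_two_way_table(400, 50, vc, seed = 8)
  expect_equal(mean(tab), 10, tolerance = 0.05)
  # empirical decomposition: between-subject and residual variances
  subj_var <- var(rowMeans(tab)) - var(as.vector(tab - rowMeans(tab))) / 50
  expect_equal(var(rowMeans(tab)), 4 + (1 + 2) / 50, tolerance = 0.6)
  expect_equal(mean(apply(sweep(tab, 2, colMeans(tab)), 2, var)),
               4 + 2, tolerance = 0.6)
  expect_error(variance_components(var_subject = -1), ">= 0")
  expect_identical(generate_two_way_table(5, 2, vc, seed = 3),
                   generate_two_way_table(5, 2, vc, seed = 3))
})

test_that("noiseless error-free tables give ICC exactly 1", {
  vc <- variance_components(mu = 5, var_subject = 2, var_session = 0,
                            var_error = 0)
  tab <- generate_two_way_table(10, 2, vc, seed = 4)
  expect_equal(icc_absolute_single(tab)$icc, 1)
})
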