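test_that("subject parameters are deterministic and dispersion-controlled", {
  cfg <- cohort_config(n_subjects = 5, seed = 0)
  a <- draw_subject_params(cfg, 3)
  b <- draw_subject_params(cfg, 3)
  expect_identical(a, b)
  expect_true(all(a$psi >= -pi & a$psi < pi))
  expect_true(all(is.finite(a$A)))

  cfg0 <- cohort_config(n_subjects = 4, amp_dispersion = 0,
                        phase_dispersion = 0, cadence_dispersion = 0, seed = 0)
  ps <- lapply(1:4, function(i) draw_subject_params(cfg0, i))
  for (i in 2:4) {
    expect_equal(ps[[i]]$A, ps[[1]]$A)
    expect_equal(ps[[i]]$psi, ps[[1]]$psi)
    expect_equal(ps[[i]]$c0, ps[[1]]$c0)
    expect_equal(ps[[i]]$c1, ps[[1]]$c1)
  }
  expect_error(draw_subject_params(cfg, 9), "subject_index")
})

test_that("self-selected speed and balance are correlated as configured", {
  cfg <- cohort_config(n_subjects = 1000, ss_balance_r = 0.5, seed = 42)
  ps <- lapply(seq_len(1000), function(i) draw_subject_params(cfg, i))
  ss <- vapply(ps, `[[`, numeric(1), "ss_speed")
  bal <- vapply(ps, `[[`, numeric(1), "balance_score")
  expect_lt(abs(cor(ss, bal) - 0.5), 0.1)
})

test_that("clean single-harmonic trials are exact cosines of the stride frequency", {
  cfg <- cohort_config(n_subjects = 1, speeds_per_subject = 1,
                       speed_min = 1, speed_max = 1, duration_s = 20,
                       n_harmonics = 1, noise_sd = 0, jitter_sd = 0,
                       gamma = 0, data_type = "kin2d", seed = 5)
  p <- draw_subject_params(cfg, 1)
  tr <- generate_trial(p, 1, cfg)
  cadence <- p$c0 + p$c1 * 1
  f_true <- cadence / 120
  # FFT oracle: spectral peak within one frequency bin of cadence/120
  n <- nrow(tr$trial$samples)
  freqs <- (0:(n - 1)) * cfg$fs / n
  for (ci in 1:3) {
    sp <- Mod(fft(tr$trial$samples[, ci]))[2:(n / 2)]
    expect_lt(abs(freqs[1 + which.max(sp)] - f_true), cfg$fs / n + 1e-12)
  }
  # no jitter: heel-strike intervals equal, cadence exact
  dhs <- diff(tr$truth$true_heel_strikes_right)
  expect_true(all(dhs %in% c(min(dhs), min(dhs) + 1)))  # sample rounding only
  expect_equal(tr$truth$true_cadence, cadence, tolerance = 1e-12)
})

test_that("amplitude speed-gain follows its closed form", {
  cfg <- cohort_config(n_subjects = 1, speeds_per_subject = 2,
                       speed_min = 0.6, speed_max = 1.2, duration_s = 10,
                       n_harmonics = 1, noise_sd = 0, jitter_sd = 0,
                       gamma = 0.2, data_type = "kin2d", seed = 6)
  p <- draw_subject_params(cfg, 1)
  s_mid <- (0.6 + 1.2) / 2
  t1 <- generate_trial(p, 0.6, cfg)$trial
  t2 <- generate_trial(p, 1.2, cfg)$trial
  expected <- (1 + 0.2 * (1.2 - s_mid) / s_mid) / (1 + 0.2 * (0.6 - s_mid) / s_mid)
  for (ci in seq_len(ncol(t1$samples))) {
    ratio <- sd(t2$samples[, ci]) / sd(t1$samples[, ci])
    expect_equal(ratio, expected, tolerance = 0.02)
  }
  # monotone RMS in speed when gamma > 0
  cfgm <- cohort_config(n_subjects = 1, speeds_per_subject = 4,
                        duration_s = 10, noise_sd = 0, jitter_sd = 0,
                        gamma = 0.3, data_type = "kin2d", seed = 6)
  pm <- draw_subject_params(cfgm, 1)
  speeds <- seq(cfgm$speed_min, cfgm$speed_max, length.out = 4)
  rms <- sapply(speeds, function(s)
    sqrt(mean(generate_trial(pm, s, cfgm)$trial$samples[, 1]^2)))
  expect_true(all(diff(rms) > 0))
})

test_that("trial generation rejects invalid requests", {
  cfg <- cohort_config(n_subjects = 1, seed = 1)
  p <- draw_subject_params(cfg, 1)
  expect_error(generate_trial(p, 5, cfg), "speed outside")
  p2 <- p
  p2$c0 <- -200
  expect_error(generate_trial(p2, 0.5, cfg), "non-positive cadence")
})

test_that("cohort layout and exclusions reproduce the study arithmetic", {
  cfg <- cohort_config(n_subjects = 17, speeds_per_subject = 9,
                       duration_s = 2, data_type = "kin2d", seed = 2)
  co <- generate_cohort(cfg)
  expect_length(co$trials, 153)
  excl <- data.frame(subject_id = c("S04", "S04", "S06"),
                     speed_index = c(8L, 9L, 8L))
  co2 <- generate_cohort(cfg, exclude = excl)
  expect_length(co2$trials, 150)

  co3 <- generate_cohort(cohort_config(n_subjects = 2, speeds_per_subject = 1,
                                       duration_s = 2, data_type = "kin2d",
                                       seed = 2))
  expect_length(co3$trials, 2)
  expect_length(unique(co3$metadata$subject_id), 2)
})

test_that("identical configs generate bit-identical cohorts", {
  cfg <- cohort_config(n_subjects = 2, speeds_per_subject = 2,
                       duration_s = 4, noise_sd = 0.5, jitter_sd = 0.02,
                       seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$metadata, b$metadata)
})

test_that("vertical GRF is non-negative, stance-only, and above threshold at contact", {
  co <- mini_cohort(n_subjects = 1, speeds = 2, duration = 6)
  for (x in co$trials) {
    expect_true(all(x$trial$vgrf_right >= 0))
    expect_true(all(x$trial$vgrf_left >= 0))
    expect_gt(sum(x$trial$vgrf_right == 0), 0)  # swing exists
    expect_true(all(x$trial$vgrf_right[x$truth$true_heel_strikes_right] >= 20))
  }
})

test_that("phase-averaged raw channels separate subjects (identity dispersion)", {
  co <- mini_cohort(n_subjects = 5, speeds = 3, duration = 10)
  loops <- lapply(seq_along(co$trials), function(i) {
    x <- co$trials[[i]]
    as.vector(phase_average(x$trial$samples,
                            events_from_truth(x$truth), 50)$loop)
  })
  V <- do.call(rbind, loops)
  D <- as.matrix(dist(V))
  subj <- co$metadata$subject_id
  ut <- which(upper.tri(D), arr.ind = TRUE)
  same <- subj[ut[, 1]] == subj[ut[, 2]]
  expect_gt(mean(D[ut][!same]), mean(D[ut][same]))
})

test_that("write_cohort produces one CSV per trial plus metadata", {
  co <- mini_cohort(n_subjects = 2, speeds = 2, duration = 2)
  dir <- withr::local_tempdir()
  files <- write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "metadata.csv")))
  expect_length(list.files(dir, pattern = "^S.*\\.csv$"), 4)
  df <- read.csv(file.path(dir, paste0(co$metadata$trial_id[1], ".csv")),
                 check.names = FALSE)
  expect_equal(nrow(df), 200)
  expect_true(all(c("time", "vgrf_right", "vgrf_left") %in% names(df)))
})
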