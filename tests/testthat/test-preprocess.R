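test_that("low-pass filter passes DC and separates band components", {
  fs <- 100
  x <- rep(3.7, 500)
  expect_lt(max(abs(lowpass_filter(x, 6, fs) - 3.7)), 1e-9)

  t <- (0:1999) / fs
  mix <- sin(2 * pi * 1 * t) + sin(2 * pi * 40 * t)
  y <- lowpass_filter(mix, 6, fs)
  amp <- function(sig, f) {
    n <- length(sig)
    2 * Mod(fft(sig))[1 + round(f * n / fs)] / n
  }
  expect_lt(amp(y, 40), amp(mix, 40) / 20)    # stopband attenuation >= 20x
  expect_equal(amp(y, 1), amp(mix, 1), tolerance = 0.02)
  expect_error(lowpass_filter(mix, 50, fs), "Nyquist")
})

test_that("filtering twice squares the magnitude response", {
  fs <- 100
  x <- with_seed <- local({set.seed(1); rnorm(4096)})
  y1 <- lowpass_filter(x, 10, fs)
  y2 <- lowpass_filter(y1, 10, fs)
  n <- length(x)
  H1 <- Mod(fft(y1)) / pmax(Mod(fft(x)), 1e-9)
  H2 <- Mod(fft(y2)) / pmax(Mod(fft(x)), 1e-9)
  # compare in the well-conditioned passband/transition region
  band <- 2:round(8 * n / fs)
  expect_lt(median(abs(H2[band] - H1[band]^2)), 0.02)
})

test_that("downsampling decimates after anti-alias filtering", {
  x <- sin(2 * pi * 3 * (0:3999) / 2000)   # 2 s at 2000 Hz
  y <- downsample(x, 2000, 100)
  expect_length(y, 200)
  expect_identical(downsample(x, 2000, 2000), x)
  expect_error(downsample(x, 150, 100), "integer multiple")
  amp <- function(sig, f, fs) 2 * Mod(fft(sig))[1 + round(f * length(sig) / fs)] / length(sig)
  expect_equal(amp(y, 3, 100), 1, tolerance = 0.01)
})

test_that("event detection recovers ground truth exactly on clean trials", {
  co <- mini_cohort(n_subjects = 2, speeds = 3, duration = 10)
  for (x in co$trials) {
    ev <- trial_gait_events(x$trial)
    expect_identical(ev$heel_strikes_right, x$truth$true_heel_strikes_right)
    expect_identical(ev$heel_strikes_left, x$truth$true_heel_strikes_left)
    expect_identical(ev$toe_offs_right, x$truth$true_toe_offs_right)
    expect_identical(ev$toe_offs_left, x$truth$true_toe_offs_left)
    # exactly one toe-off between consecutive same-side heel strikes
    hs <- ev$heel_strikes_right
    for (i in seq_len(length(hs) - 1))
      expect_equal(sum(ev$toe_offs_right > hs[i] & ev$toe_offs_right < hs[i + 1]), 1)
  }
  expect_error(detect_gait_events(rep(0, 1000), 100), "insufficient strides")
})

test_that("threshold 0 shifts onsets only across the sub-threshold rise", {
  co <- mini_cohort(n_subjects = 1, speeds = 1, duration = 10)
  v <- co$trials[[1]]$trial$vgrf_right
  e20 <- detect_gait_events(v, 100, threshold = 20)
  e0 <- detect_gait_events(v, 100, threshold = 0)
  expect_length(e0$heel_strikes, length(e20$heel_strikes))
  for (i in seq_along(e0$heel_strikes)) {
    lag <- e20$heel_strikes[i] - e0$heel_strikes[i]
    expect_gte(lag, 0)
    if (lag > 0) {
      seg <- v[e0$heel_strikes[i]:(e20$heel_strikes[i] - 1)]
      expect_true(all(seg > 0 & seg < 20))  # direct scan oracle
    }
  }
})

test_that("noisy vertical GRF still yields cadence within 1% after filtering", {
  co <- mini_cohort(n_subjects = 1, speeds = 1, duration = 20, jitter_sd = 0.02)
  x <- co$trials[[1]]
  v <- x$trial$vgrf_right
  vn <- pmax(v + local({set.seed(33); rnorm(length(v), 0, 5)}), 0)
  vf <- pmax(lowpass_filter(vn, 30, 100), 0)
  ev <- detect_gait_events(vf, 100)
  cad <- 60 / (mean(diff(ev$heel_strikes)) / 100 / 2)
  expect_lt(abs(cad - x$truth$true_cadence) / x$truth$true_cadence, 0.01)
})

test_that("feature sets have the contracted channel counts and units", {
  cfg <- cohort_config(n_subjects = 1, speeds_per_subject = 1,
                       duration_s = 5, data_type = "combined", seed = 3)
  x <- generate_cohort(cfg)$trials[[1]]$trial
  expect_equal(ncol(assemble_feature_set(x, "kin2d")$features), 6)
  expect_equal(ncol(assemble_feature_set(x, "kin3d")$features), 18)
  expect_equal(ncol(assemble_feature_set(x, "kinetics3d")$features), 42)
  expect_equal(ncol(assemble_feature_set(x, "combined")$features), 60)
  # GRF channels rescaled to body-weight units: O(1), not hundreds of newtons
  k <- assemble_feature_set(x, "kinetics3d")
  expect_lt(max(abs(k$features[, "grf_vert_r"])), 3)

  x2 <- mini_cohort(n_subjects = 1, speeds = 1, duration = 5,
                    data_type = "kin2d")$trials[[1]]$trial
  expect_error(assemble_feature_set(x2, "kinetics3d"), "missing channel")
})

test_that("spatiotemporal record matches ground truth at sample resolution", {
  co <- mini_cohort(n_subjects = 1, speeds = 2, duration = 20)
  for (x in co$trials) {
    ev <- trial_gait_events(x$trial)
    st <- compute_spatiotemporal(x$trial, ev, x$truth)
    tu <- x$truth
    for (i in 1:2) {
      expect_equal(st$cadence[i], tu$true_cadence, tolerance = 2e-3)
      expect_equal(st$stance_duration[i], tu$true_stance_duration,
                   tolerance = 0.02)
      expect_equal(st$swing_duration[i], tu$true_swing_duration,
                   tolerance = 0.02)
      # stance + swing equals the stride period identically
      expect_equal(st$stance_duration[i] + st$swing_duration[i],
                   60 * 2 / st$cadence[i], tolerance = 1e-9)
      # definitional identity survives sampling exactly
      expect_equal(st$step_length[i] * st$cadence[i] / 60, x$trial$speed,
                   tolerance = 1e-9)
    }
  }
})

test_that("halving the stride period doubles cadence", {
  cfg <- cohort_config(n_subjects = 1, speeds_per_subject = 1, duration_s = 20,
                       noise_sd = 0, jitter_sd = 0, seed = 4)
  p <- draw_subject_params(cfg, 1)
  p2 <- p; p2$c0 <- 2 * p$c0; p2$c1 <- 2 * p$c1
  t1 <- generate_trial(p, 1, cfg)$truth
  t2 <- generate_trial(p2, 1, cfg)$truth
  expect_equal(t2$true_stance_duration + t2$true_swing_duration,
               (t1$true_stance_duration + t1$true_swing_duration) / 2,
               tolerance = 1e-9)
})

test_that("discrete variables: closed forms and contracted lengths", {
  # constant channel: peak = minimum, zero excursion
  cfg <- cohort_config(n_subjects = 1, speeds_per_subject = 1, duration_s = 10,
                       data_type = "kin2d", noise_sd = 0, jitter_sd = 0,
                       n_harmonics = 1, gamma = 0, seed = 8)
  x <- generate_cohort(cfg)$trials[[1]]
  tr <- x$trial
  tr$samples[, "ang_hip_sag_r"] <- 12.5
  ev <- events_from_truth(x$truth)
  v <- compute_discrete_variables(tr, ev, "kinematic18")
  expect_equal(unname(v["hip_sag_peak_r"]), unname(v["hip_sag_minimum_r"]))
  expect_equal(unname(v["hip_sag_excursion_r"]), 0)

  # single cosine of amplitude A: excursion 2A (to sampling resolution)
  p <- draw_subject_params(cfg, 1)
  cat_ <- channel_catalogue("kin2d")
  A <- p$A[which(cat_$label == "ang_knee_sag_r"), 1]
  expect_equal(unname(v["knee_sag_excursion_r"]), 2 * A, tolerance = 2e-3)

  # full bilateral biomechanical row
  cfgC <- cohort_config(n_subjects = 1, speeds_per_subject = 1,
                        duration_s = 10, data_type = "combined",
                        noise_sd = 0, jitter_sd = 0, seed = 8)
  xc <- generate_cohort(cfgC)$trials[[1]]
  expect_length(compute_discrete_variables(xc$trial,
                                           events_from_truth(xc$truth),
                                           "biomech26"), 26)
  expect_length(compute_discrete_variables(xc$trial,
                                           events_from_truth(xc$truth),
                                           "kinetic8"), 8)
  expect_length(compute_discrete_variables(xc$trial,
                                           events_from_truth(xc$truth),
                                           "spatiotemporal10",
                                           truth = xc$truth), 10)
})

test_that("phase reconstructed from detected heel strikes is monotone", {
  co <- mini_cohort(n_subjects = 1, speeds = 1, duration = 10,
                    jitter_sd = 0.03)
  x <- co$trials[[1]]
  hs <- trial_gait_events(x$trial)$heel_strikes_right
  phase <- rep(NA_real_, nrow(x$trial$samples))
  for (i in seq_len(length(hs) - 1)) {
    idx <- hs[i]:(hs[i + 1] - 1)
    phase[idx] <- (i - 1) + (idx - hs[i]) / (hs[i + 1] - hs[i])
  }
  ph <- phase[!is.na(phase)]
  expect_true(all(diff(ph) > 0))
})
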