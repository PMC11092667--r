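#' Configuration for a synthetic multi-subject, multi-speed gait cohort
#'
#' The generator emulates a treadmill study in which every subject walks one
#' trial at each of several fixed belt speeds while continuous joint angles
#' (and, for the kinetic channel sets, ground reaction forces, joint moments
#' and powers) are recorded together with bilateral vertical ground reaction
#' forces. Each channel is a sum of stride-locked cosine harmonics whose
#' amplitudes and phases are individual-specific, giving the cohort a known
#' ground-truth identity structure; amplitude and cadence are modulated
#' linearly with belt speed, giving it a known speed structure.
#'
#' @param n_subjects number of subjects.
#' @param speeds_per_subject number of belt-speed conditions per subject.
#' @param speed_min,speed_max slowest / fastest belt speed (m/s).
#' @param duration_s trial duration in seconds.
#' @param fs sampling rate (Hz). `duration_s * fs` must be an integer.
#' @param data_type one of `"kin2d"` (6 channels), `"kin3d"` (18),
#'   `"kinetics3d"` (42) or `"combined"` (60).
#' @param n_harmonics number of stride harmonics per channel.
#' @param noise_sd additive Gaussian noise SD on every channel, in channel
#'   units (degrees for angles).
#' @param jitter_sd SD of the per-stride multiplicative period jitter, as a
#'   fraction of the stride period.
#' @param gamma dimensionless amplitude speed-gain: channel amplitudes scale by
#'   `1 + gamma * (speed - mid_speed) / mid_speed`.
#' @param amp_dispersion between-subject relative SD of harmonic amplitudes.
#' @param phase_dispersion between-subject SD of harmonic phases (radians).
#' @param cadence_dispersion multiplier on the between-subject SDs of the
#'   cadence intercept (6 steps/min) and slope (4 steps/min per m/s).
#' @param ss_balance_r target Pearson correlation between each subject's
#'   self-selected speed and narrowing-beam balance score.
#' @param speed_perturb SD of a subject-specific perturbation added to the
#'   common speed grid (m/s); 0 keeps the grid identical across subjects.
#' @param seed integer seed; the cohort is a pure function of the config.
#'
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 17, speeds_per_subject = 9,
                          speed_min = 0.3, speed_max = 2.0,
                          duration_s = 60, fs = 100,
                          data_type = c("kin3d", "kin2d", "kinetics3d", "combined"),
                          n_harmonics = 4, noise_sd = 0.5, jitter_sd = 0.02,
                          gamma = 0.3, amp_dispersion = 0.15,
                          phase_dispersion = 0.25, cadence_dispersion = 1,
                          ss_balance_r = 0.5, speed_perturb = 0, seed = 1L) {
  data_type <- match.arg(data_type)
  cfg <- list(n_subjects = as.integer(n_subjects),
              speeds_per_subject = as.integer(speeds_per_subject),
              speed_min = speed_min, speed_max = speed_max,
              duration_s = duration_s, fs = fs, data_type = data_type,
              n_harmonics = as.integer(n_harmonics), noise_sd = noise_sd,
              jitter_sd = jitter_sd, gamma = gamma,
              amp_dispersion = amp_dispersion,
              phase_dispersion = phase_dispersion,
              cadence_dispersion = cadence_dispersion,
              ss_balance_r = ss_balance_r, speed_perturb = speed_perturb,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  errs <- validate_cohort_config(cfg)
  if (length(errs)) stop("invalid cohort config: ", paste(errs, collapse = "; "))
  cfg
}

validate_cohort_config <- function(cfg) {
  errs <- character()
  chk <- function(ok, msg) if (!isTRUE(ok)) errs <<- c(errs, msg)
  chk(cfg$n_subjects >= 1, "n_subjects must be >= 1")
  chk(cfg$speeds_per_subject >= 1, "speeds_per_subject must be >= 1")
  chk(cfg$speed_min > 0, "speed_min must be > 0")
  chk(cfg$speed_max >= cfg$speed_min, "speed_max must be >= speed_min")
  chk(cfg$fs > 0, "fs must be > 0")
  chk(abs(cfg$duration_s * cfg$fs - round(cfg$duration_s * cfg$fs)) < 1e-9,
      "duration_s * fs must be an integer")
  chk(cfg$data_type %in% c("kin2d", "kin3d", "kinetics3d", "combined"),
      "unknown data_type")
  chk(cfg$n_harmonics >= 1, "n_harmonics must be >= 1")
  chk(cfg$noise_sd >= 0, "noise_sd must be >= 0")
  chk(cfg$jitter_sd >= 0, "jitter_sd must be >= 0")
  chk(abs(cfg$ss_balance_r) <= 1, "ss_balance_r must be in [-1, 1]")
  errs
}

#' Channel catalogue for a data type
#'
#' Column order is fixed: for each side (right, left) the angle channels run
#' joint-major (hip, knee, ankle) and plane-major (sagittal, frontal,
#' transverse); kinetic sets append ground reaction forces (vertical,
#' anterior-posterior, medio-lateral), then joint moments, then joint powers in
#' the same joint/plane order.
#'
#' @param data_type one of `"kin2d"`, `"kin3d"`, `"kinetics3d"`, `"combined"`.
#' @return data.frame with columns `label`, `kind`, `side`, `base_amp`,
#'   `amp_unit` (`"unit"`, `"bw"` = scaled by body weight in N, `"mass"` =
#'   scaled by body mass in kg) and `stance_gated`.
#' @export
channel_catalogue <- function(data_type) {
  joints <- c("hip", "knee", "ankle")
  planes <- c("sag", "fro", "tra")
  ang_amp <- matrix(c(40, 12, 10, 60, 8, 12, 30, 10, 8), nrow = 3,
                    byrow = TRUE, dimnames = list(joints, planes))
  mom_amp <- c(hip = 1.0, knee = 0.8, ankle = 1.4)   # x body mass
  pow_amp <- c(hip = 1.0, knee = 1.2, ankle = 3.0)   # x body mass
  grf_amp <- c(vert = 0.55, ap = 0.18, ml = 0.06)    # x body weight

  rows <- list()
  add <- function(label, kind, side, amp, unit, gated) {
    rows[[length(rows) + 1]] <<- data.frame(
      label = label, kind = kind, side = side, base_amp = amp,
      amp_unit = unit, stance_gated = gated, stringsAsFactors = FALSE)
  }
  for (side in c("r", "l")) {
    for (j in joints) for (p in planes) {
      if (data_type == "kin2d" && p != "sag") next
      if (data_type != "kinetics3d")
        add(sprintf("ang_%s_%s_%s", j, p, side), "angle", side,
            ang_amp[j, p], "unit", FALSE)
    }
  }
  if (data_type %in% c("kinetics3d", "combined")) {
    for (side in c("r", "l"))
      for (ax in names(grf_amp))
        add(sprintf("grf_%s_%s", ax, side), "grf", side, grf_amp[[ax]],
            "bw", TRUE)
    for (side in c("r", "l"))
      for (j in joints) for (p in planes)
        add(sprintf("mom_%s_%s_%s", j, p, side), "moment", side,
            mom_amp[[j]], "mass", FALSE)
    for (side in c("r", "l"))
      for (j in joints) for (p in planes)
        add(sprintf("pow_%s_%s_%s", j, p, side), "power", side,
            pow_amp[[j]], "mass", FALSE)
  }
  do.call(rbind, rows)
}

#' Number of channels implied by a data type
#' @param data_type channel-set name.
#' @export
n_channels <- function(data_type) {
  c(kin2d = 6L, kin3d = 18L, kinetics3d = 42L, combined = 60L)[[data_type]]
}

#' Draw the individual-specific generative parameters of one subject
#'
#' Deterministic given `(config$seed, subject_index)`. The cohort-level base
#' waveform (common harmonic amplitudes and phases) is drawn from the config
#' seed alone; subject-specific deviations are scaled by the dispersion
#' settings, so zero dispersion collapses the cohort onto one shared gait.
#' Self-selected speed and balance score are drawn jointly with target
#' correlation `config$ss_balance_r`.
#'
#' @param config a [cohort_config()].
#' @param subject_index 1-based subject index.
#' @return An object of class `subject_params`.
#' @export
draw_subject_params <- function(config, subject_index) {
  stopifnot(inherits(config, "cohort_config"))
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop("subject_index must be in 1..n_subjects")
  cat_ <- channel_catalogue(config$data_type)
  C <- nrow(cat_)
  H <- config$n_harmonics
  rel <- 0.5^(seq_len(H) - 1)

  base <- with_seed(config$seed, {
    list(psi = matrix(runif(C * H, -pi, pi), C, H))
  })

  with_seed(derive_seed(config$seed, 104729 * subject_index), {
    A <- outer(cat_$base_amp, rel) *
      (1 + config$amp_dispersion * matrix(rnorm(C * H), C, H))
    A <- abs(A)
    psi <- wrap_pi(base$psi + config$phase_dispersion * matrix(rnorm(C * H), C, H))
    c0 <- 95 + 6 * config$cadence_dispersion * rnorm(1)
    c1 <- 25 + 4 * config$cadence_dispersion * rnorm(1)
    z1 <- rnorm(1); z2 <- rnorm(1)
    r <- config$ss_balance_r
    ss_speed <- 1.2 + 0.15 * z1
    ss_speed <- min(max(ss_speed, config$speed_min), config$speed_max)
    balance <- 18 + 4 * (r * z1 + sqrt(1 - r^2) * z2)
    out <- list(subject_id = sprintf("S%02d", subject_index),
                subject_index = subject_index,
                body_mass = max(45, 77 + 10 * rnorm(1)),
                c0 = c0, c1 = c1, A = A, psi = psi,
                gamma = config$gamma,
                ss_speed = ss_speed, balance_score = balance,
                step_width = max(0.05, 0.12 + 0.02 * rnorm(1)))
    class(out) <- "subject_params"
    out
  })
}

# Two-peak stance template on u in [0, 1]; strictly positive, >= 0.3 body
# weight at stance onset so a 20 N threshold detects the onset sample itself.
vgrf_template <- function(u) {
  v <- 0.05 + 0.9 * u
  1.15 * (sin(pi * v) + 0.35 * sin(3 * pi * v))
}

stance_fraction <- function(speed, config) {
  if (config$speed_max <= config$speed_min) return(0.65)
  f <- (speed - config$speed_min) / (config$speed_max - config$speed_min)
  0.65 - 0.10 * min(max(f, 0), 1)
}

#' Generate one synthetic gait trial with ground truth
#'
#' Stride phase advances at `cadence / 120` strides per second with
#' per-stride multiplicative period jitter. Channel `c` is
#' `sum_h A[c,h] * (1 + gamma * (s - s_mid)/s_mid) * cos(2*pi*h*phase + psi[c,h])`
#' plus Gaussian noise; ground-reaction-force channels are additionally gated
#' to that side's stance phase. The bilateral vertical GRF used for event
#' detection is a body-weight-scaled two-peak stance template, exactly zero
#' during swing, with the stance fraction decreasing linearly from 0.65 at the
#' slowest to 0.55 at the fastest cohort speed. Left events are offset from
#' right by half a stride.
#'
#' @param params a [draw_subject_params()] result.
#' @param speed belt speed (m/s), within the config's speed range.
#' @param config the [cohort_config()].
#' @return list with elements `trial` (class `trial_timeseries`: `samples`
#'   T x C matrix, `channel_labels`, `vgrf_right`, `vgrf_left`, metadata) and
#'   `truth` (class `gait_ground_truth`: true event indices (1-based sample
#'   numbers) and true spatiotemporal values).
#' @export
generate_trial <- function(params, speed, config) {
  stopifnot(inherits(params, "subject_params"), inherits(config, "cohort_config"))
  if (speed < config$speed_min - 1e-9 || speed > config$speed_max + 1e-9)
    stop("speed outside [speed_min, speed_max]")
  cadence <- params$c0 + params$c1 * speed
  if (cadence <= 0)
    stop(sprintf("non-positive cadence for subject %s at speed %.2f m/s",
                 params$subject_id, speed))

  fs <- config$fs
  T_ <- as.integer(round(config$duration_s * fs))
  tt <- (seq_len(T_) - 1) / fs
  stride_period <- 120 / cadence  # seconds per stride (2 steps per stride)

  trial_seed <- derive_seed(config$seed, params$subject_index,
                            round(speed * 1e4))
  n_strides_max <- ceiling(config$duration_s / stride_period) + 3L
  rngout <- with_seed(trial_seed, {
    jit <- pmax(0.2, 1 + config$jitter_sd * rnorm(n_strides_max))
    noise <- if (config$noise_sd > 0)
      matrix(rnorm(T_ * nrow(params$A), 0, config$noise_sd), T_) else NULL
    width_noise <- if (config$jitter_sd > 0) rnorm(1, 0, 0.003) else 0
    list(jit = jit, noise = noise, width_noise = width_noise)
  })
  durs <- stride_period * rngout$jit
  bounds <- c(0, cumsum(durs))                   # right heel-strike times (s)
  n_str <- max(which(bounds < config$duration_s))
  # piecewise-linear stride phase
  k <- findInterval(tt, bounds, rightmost.closed = FALSE)
  phase <- (k - 1) + (tt - bounds[k]) / durs[k]

  mid <- (config$speed_min + config$speed_max) / 2
  gain <- 1 + params$gamma * (speed - mid) / mid

  cat_ <- channel_catalogue(config$data_type)
  C <- nrow(cat_)
  Hh <- config$n_harmonics
  bw <- params$body_mass * 9.81

  sf <- stance_fraction(speed, config)
  frac_r <- phase %% 1
  frac_l <- (phase + 0.5) %% 1
  stance_r <- frac_r < sf
  stance_l <- frac_l < sf

  X <- matrix(0, T_, C)
  for (ci in seq_len(C)) {
    x <- numeric(T_)
    for (h in seq_len(Hh))
      x <- x + params$A[ci, h] * gain *
        cos(2 * pi * h * phase + params$psi[ci, h])
    scale_ <- switch(cat_$amp_unit[ci], unit = 1, bw = bw,
                     mass = params$body_mass)
    x <- x * scale_
    if (cat_$stance_gated[ci])
      x <- x * (if (cat_$side[ci] == "r") stance_r else stance_l)
    X[, ci] <- x
  }
  if (!is.null(rngout$noise)) X <- X + rngout$noise
  colnames(X) <- cat_$label

  vgrf_r <- ifelse(stance_r, bw * vgrf_template(frac_r / sf), 0)
  vgrf_l <- ifelse(stance_l, bw * vgrf_template(frac_l / sf), 0)

  # true events: first sample at or after each crossing time; events at or
  # before time 0 (the trial opens at a right heel strike, left mid-stance)
  # are not listed, matching what a force-threshold detector can observe
  to_sample <- function(times) {
    idx <- as.integer(ceiling(times * fs - 1e-9)) + 1L
    idx[times > 1e-12 & idx <= T_]
  }
  ks <- seq_len(n_str)
  hs_time_r <- bounds[ks]
  hs_time_l <- bounds[ks] + durs[ks] * 0.5
  to_time_r <- bounds[ks] + durs[ks] * sf
  to_time_l <- hs_time_l + durs[ks] * sf
  hs_r <- to_sample(hs_time_r)
  hs_l <- to_sample(hs_time_l)
  # a detector only sees toe-offs after the first observable right heel strike
  to_r <- to_sample(if (n_str >= 2) to_time_r[-1] else numeric(0))
  to_l <- to_sample(to_time_l)

  mean_stride <- mean(durs[seq_len(max(n_str - 1, 1))])
  step_time <- mean_stride / 2
  truth <- list(true_heel_strikes_right = hs_r,
                true_heel_strikes_left = hs_l,
                true_toe_offs_right = to_r,
                true_toe_offs_left = to_l,
                true_cadence = 60 / step_time,
                true_step_length = speed * step_time,
                true_stance_duration = sf * mean_stride,
                true_swing_duration = (1 - sf) * mean_stride,
                true_step_width = params$step_width + rngout$width_noise,
                stance_fraction = sf)
  class(truth) <- "gait_ground_truth"

  trial <- list(subject_id = params$subject_id, speed = speed,
                data_type = config$data_type, samples = X,
                channel_labels = cat_$label, fs = fs,
                body_mass = params$body_mass,
                vgrf_right = vgrf_r, vgrf_left = vgrf_l)
  class(trial) <- "trial_timeseries"
  list(trial = trial, truth = truth)
}

#' Generate a full synthetic cohort
#'
#' Every subject walks one trial at each point of an evenly spaced speed grid
#' spanning `[speed_min, speed_max]` (plus an optional subject-specific
#' perturbation). The trial closest to the subject's self-selected speed is
#' flagged `is_ss` in the metadata.
#'
#' @param config a [cohort_config()].
#' @param exclude optional data.frame with columns `subject_id` and
#'   `speed_index` naming trials to drop (emulating technical losses).
#' @return list of class `gait_cohort`: `trials` (list of
#'   `list(trial, truth)`), `subjects` (list of `subject_params`), `metadata`
#'   (one row per retained trial) and `config`.
#' @export
generate_cohort <- function(config, exclude = NULL) {
  stopifnot(inherits(config, "cohort_config"))
  grid <- if (config$speeds_per_subject == 1) config$speed_min else
    seq(config$speed_min, config$speed_max, length.out = config$speeds_per_subject)

  subjects <- lapply(seq_len(config$n_subjects),
                     function(i) draw_subject_params(config, i))
  trials <- list(); meta <- list()
  for (i in seq_len(config$n_subjects)) {
    p <- subjects[[i]]
    speeds <- grid
    if (config$speed_perturb > 0) {
      speeds <- with_seed(derive_seed(config$seed, 7 * i, 13), {
        pmin(pmax(grid + rnorm(length(grid), 0, config$speed_perturb),
                  config$speed_min), config$speed_max)
      })
    }
    ss_idx <- which.min(abs(speeds - p$ss_speed))
    for (j in seq_along(speeds)) {
      if (!is.null(exclude) &&
          any(exclude$subject_id == p$subject_id & exclude$speed_index == j))
        next
      tr <- generate_trial(p, speeds[j], config)
      trials[[length(trials) + 1]] <- tr
      meta[[length(meta) + 1]] <- data.frame(
        trial_id = sprintf("%s_v%02d", p$subject_id, j),
        subject_id = p$subject_id, speed = speeds[j], speed_index = j,
        is_ss = (j == ss_idx), ss_speed = p$ss_speed,
        balance_score = p$balance_score, body_mass = p$body_mass,
        stringsAsFactors = FALSE)
    }
  }
  out <- list(trials = trials, subjects = subjects,
              metadata = do.call(rbind, meta), config = config)
  class(out) <- "gait_cohort"
  out
}

#' @export
print.gait_cohort <- function(x, ...) {
  cat(sprintf("gait_cohort: %d trials (%d subjects x %d speeds, %s, %g s @ %g Hz)\n",
              length(x$trials), x$config$n_subjects,
              x$config$speeds_per_subject, x$config$data_type,
              x$config$duration_s, x$config$fs))
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' One CSV per trial (time, channels, bilateral vertical GRF), a cohort
#' metadata CSV, and the config as JSON.
#'
#' @param cohort a [generate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "gait_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (i in seq_along(cohort$trials)) {
    tr <- cohort$trials[[i]]$trial
    df <- data.frame(time = (seq_len(nrow(tr$samples)) - 1) / tr$fs,
                     tr$samples,
                     vgrf_right = tr$vgrf_right, vgrf_left = tr$vgrf_left,
                     check.names = FALSE)
    f <- file.path(dir, paste0(cohort$metadata$trial_id[i], ".csv"))
    write.csv(df, f, row.names = FALSE)
    files <- c(files, f)
  }
  f <- file.path(dir, "metadata.csv")
  write.csv(cohort$metadata, f, row.names = FALSE)
  files <- c(files, f)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    f <- file.path(dir, "config.json")
    jsonlite::write_json(unclass(cohort$config), f, auto_unbox = TRUE)
    files <- c(files, f)
  }
  invisible(files)
}
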