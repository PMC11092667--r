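# One steady-state-initialized pass: past inputs pinned at x[1], past outputs
# at x[1] times the DC gain, so a constant series passes through untouched.
filter_ss <- function(b, a, x) {
  g0 <- sum(b) / sum(a)
  as.numeric(signal::filter(b, a, x,
                            init.x = rep(x[1], length(b) - 1),
                            init.y = rep(x[1] * g0, length(a) - 1)))
}

# Forward-backward IIR filtering with reflect-and-invert end padding and
# steady-state initialization: zero phase, no edge transient leaking into
# the series.
filtfilt_ss <- function(b, a, x) {
  n <- length(x)
  p <- min(n - 1, 9 * max(length(a), length(b)))
  xe <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- filter_ss(b, a, xe)
  y <- rev(filter_ss(b, a, rev(y)))
  y[(p + 1):(p + n)]
}

#' Zero-phase low-pass filter
#'
#' Butterworth design applied forward and backward (zero phase, so event
#' timing is untouched — the conventional gait-lab choice), with
#' steady-state-initialized ends to avoid edge transients.
#'
#' @param series numeric vector or T x C matrix.
#' @param cutoff cutoff frequency (Hz); must be below the Nyquist rate.
#' @param fs sampling rate (Hz).
#' @param order filter order (default 4).
#' @return filtered series, same shape as the input.
#' @export
lowpass_filter <- function(series, cutoff, fs, order = 4) {
  if (cutoff >= fs / 2) stop("cutoff must be below the Nyquist frequency fs/2")
  if (cutoff <= 0) stop("cutoff must be positive")
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  if (is.matrix(series)) {
    out <- apply(series, 2, function(x) filtfilt_ss(bf$b, bf$a, x))
    dimnames(out) <- dimnames(series)
    out
  } else {
    filtfilt_ss(bf$b, bf$a, series)
  }
}

#' Down-sample a series by an integer factor
#'
#' Anti-alias low-pass filtering (zero-phase Butterworth at 80% of the target
#' Nyquist rate) followed by decimation.
#'
#' @param series numeric vector or T x C matrix.
#' @param from_fs,to_fs original and target sampling rates; `from_fs` must be
#'   an integer multiple of `to_fs`.
#' @return the decimated series with `ceiling(T * to_fs / from_fs)` samples.
#' @export
downsample <- function(series, from_fs, to_fs) {
  fac <- from_fs / to_fs
  if (abs(fac - round(fac)) > 1e-9)
    stop("from_fs must be an integer multiple of to_fs")
  fac <- as.integer(round(fac))
  if (fac == 1L) return(series)
  filtered <- lowpass_filter(series, 0.8 * to_fs / 2, from_fs, order = 4)
  n <- if (is.matrix(series)) nrow(series) else length(series)
  keep <- seq(1L, n, by = fac)
  if (is.matrix(series)) filtered[keep, , drop = FALSE] else filtered[keep]
}

# Threshold crossings of one side's vertical GRF.
detect_events_side <- function(vgrf, fs, threshold = 20, min_swing_s = 0.05,
                               refractory = 0.2) {
  if (any(vgrf < 0)) stop("vgrf must be non-negative")
  n <- length(vgrf)
  above <- if (threshold > 0) vgrf >= threshold else vgrf > 0
  # the series may open mid-stance, so sample 1 is never a crossing
  ups <- which(above & !c(TRUE, above[-n]))
  downs <- which(!above & c(FALSE, above[-n]))
  # require a minimum swing time below threshold before each heel strike
  min_sw <- max(1L, as.integer(round(min_swing_s * fs)))
  keep <- vapply(ups, function(u) {
    lo <- max(1L, u - min_sw)
    all(!above[lo:(u - 1L)])
  }, logical(1))
  ups <- ups[keep]
  if (length(ups) >= 3) {
    med <- median(diff(ups))
    kept <- ups[1]
    for (u in ups[-1]) if (u - kept[length(kept)] >= refractory * med)
      kept <- c(kept, u)
    ups <- kept
  }
  if (length(ups) < 4) stop("insufficient strides")
  # one toe-off per stride interval [HS_i, HS_{i+1})
  tos <- integer(0)
  for (i in seq_len(length(ups) - 1)) {
    d <- downs[downs > ups[i] & downs <= ups[i + 1]]
    if (length(d)) tos <- c(tos, d[1])
  }
  trailing <- downs[downs > ups[length(ups)]]
  if (length(trailing)) tos <- c(tos, trailing[1])
  list(heel_strikes = ups, toe_offs = tos)
}

#' Detect gait events from a vertical ground reaction force
#'
#' Heel strike is the first sample at or above the force threshold following a
#' swing interval below it; toe-off is the first sample below the threshold
#' after stance. Crossings closer than a refractory fraction of the median
#' stride are merged.
#'
#' @param vgrf non-negative vertical GRF vector (N).
#' @param fs sampling rate (Hz).
#' @param threshold force threshold (N), default 20.
#' @param min_swing_s minimum time below threshold before a heel strike (s).
#' @return list with 1-based sample indices `heel_strikes` and `toe_offs`.
#' @export
detect_gait_events <- function(vgrf, fs, threshold = 20, min_swing_s = 0.05) {
  detect_events_side(vgrf, fs, threshold, min_swing_s)
}

#' Detect bilateral gait events for a trial
#'
#' @param trial a `trial_timeseries`.
#' @param threshold vertical-GRF threshold (N).
#' @return object of class `gait_events` with strictly increasing 1-based
#'   indices `heel_strikes_right`, `heel_strikes_left`, `toe_offs_right`,
#'   `toe_offs_left`.
#' @export
trial_gait_events <- function(trial, threshold = 20) {
  r <- detect_events_side(trial$vgrf_right, trial$fs, threshold)
  l <- detect_events_side(trial$vgrf_left, trial$fs, threshold)
  ev <- list(heel_strikes_right = r$heel_strikes, toe_offs_right = r$toe_offs,
             heel_strikes_left = l$heel_strikes, toe_offs_left = l$toe_offs)
  class(ev) <- "gait_events"
  ev
}

#' Events taken directly from generator ground truth
#'
#' @param truth a `gait_ground_truth`.
#' @return a `gait_events` object.
#' @export
events_from_truth <- function(truth) {
  ev <- list(heel_strikes_right = truth$true_heel_strikes_right,
             toe_offs_right = truth$true_toe_offs_right,
             heel_strikes_left = truth$true_heel_strikes_left,
             toe_offs_left = truth$true_toe_offs_left)
  class(ev) <- "gait_events"
  ev
}

#' Assemble the channel matrix an RNN consumes
#'
#' Selects the requested channel set (in the fixed catalogue order) from a
#' trial; ground-reaction-force channels are converted to body-weight units
#' (force / (body mass x 9.81 m/s^2)).
#'
#' @param trial a `trial_timeseries`.
#' @param data_type requested channel set; must be a subset of the trial's
#'   channels (e.g. `"kin2d"` from a `"kin3d"` trial).
#' @return list with `features` (T x C matrix) and `labels`.
#' @export
assemble_feature_set <- function(trial, data_type = trial$data_type) {
  cat_ <- channel_catalogue(data_type)
  missing <- setdiff(cat_$label, trial$channel_labels)
  if (length(missing))
    stop("trial is missing channel(s): ", paste(head(missing, 5), collapse = ", "))
  X <- trial$samples[, cat_$label, drop = FALSE]
  grf <- cat_$kind == "grf"
  if (any(grf)) X[, grf] <- X[, grf] / (trial$body_mass * 9.81)
  list(features = X, labels = cat_$label)
}

side_events <- function(events, side) {
  side <- c(r = "right", l = "left")[[side]]
  list(hs = events[[paste0("heel_strikes_", side)]],
       to = events[[paste0("toe_offs_", side)]])
}

#' Trial-averaged spatiotemporal variables
#'
#' Cadence is 60 over the mean step time (half the mean stride time of the
#' side); stance duration is the mean heel-strike-to-toe-off time; swing is
#' stride minus stance; step length is belt speed times mean step time
#' (belt-frame definition). Step width is taken from ground truth when
#' supplied (no lateral foot positions exist in this data model).
#'
#' @param trial a `trial_timeseries`.
#' @param events a `gait_events`.
#' @param truth optional `gait_ground_truth` supplying step width.
#' @return object of class `spatiotemporal_record`: data.frame with one row
#'   per side and columns cadence (steps/min), step_length (m),
#'   stance_duration (s), swing_duration (s), step_width (m).
#' @export
compute_spatiotemporal <- function(trial, events, truth = NULL) {
  fs <- trial$fs
  rows <- lapply(c("r", "l"), function(side) {
    se <- side_events(events, side)
    if (length(se$hs) < 4) stop("insufficient strides on side ", side)
    strides <- diff(se$hs) / fs
    step_time <- mean(strides) / 2
    stance <- vapply(seq_len(length(se$hs) - 1), function(i) {
      d <- se$to[se$to > se$hs[i] & se$to <= se$hs[i + 1]]
      if (length(d)) (d[1] - se$hs[i]) / fs else NA_real_
    }, numeric(1))
    stance <- mean(stance, na.rm = TRUE)
    data.frame(side = side,
               cadence = 60 / step_time,
               step_length = trial$speed * step_time,
               stance_duration = stance,
               swing_duration = mean(strides) - stance,
               step_width = if (!is.null(truth)) truth$true_step_width else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("spatiotemporal_record", class(out))
  out
}

# Per-stride summary of one channel, averaged across the side's strides.
stride_stats <- function(x, hs, fs) {
  n <- length(x)
  hs <- hs[hs <= n]
  if (length(hs) < 4) stop("insufficient strides")
  pk <- mn <- numeric(length(hs) - 1)
  for (i in seq_len(length(hs) - 1)) {
    seg <- x[hs[i]:(hs[i + 1] - 1)]
    pk[i] <- max(seg); mn[i] <- min(seg)
  }
  c(peak = mean(pk), minimum = mean(mn), excursion = mean(pk - mn))
}

#' One row of a discrete-variable table
#'
#' Feature sets: `kinematic18` is the per-side peak, minimum and excursion of
#' the sagittal hip, knee and ankle angles (2 x 3 x 3 = 18); `kinetic8` is the
#' per-side peak vertical GRF (body weights), peak propulsive GRF, peak ankle
#' moment and peak ankle power (2 x 4 = 8); `biomech26` is their union;
#' `spatiotemporal10` is the bilateral [compute_spatiotemporal()] record. All
#' values are averaged across the trial's strides.
#'
#' @param trial a `trial_timeseries`.
#' @param events a `gait_events`.
#' @param set_name one of `"biomech26"`, `"kinematic18"`, `"kinetic8"`,
#'   `"spatiotemporal10"`.
#' @param truth optional ground truth (step width passthrough).
#' @return named numeric vector (length 26 / 18 / 8 / 10).
#' @export
compute_discrete_variables <- function(trial, events,
                                       set_name = c("biomech26", "kinematic18",
                                                    "kinetic8", "spatiotemporal10"),
                                       truth = NULL) {
  set_name <- match.arg(set_name)
  labs <- trial$channel_labels
  getch <- function(lab) {
    if (!lab %in% labs) stop("trial is missing channel: ", lab)
    trial$samples[, lab]
  }
  kin18 <- function() {
    out <- c()
    for (side in c("r", "l")) {
      hs <- side_events(events, side)$hs
      for (j in c("hip", "knee", "ankle")) {
        st <- stride_stats(getch(sprintf("ang_%s_sag_%s", j, side)), hs, trial$fs)
        names(st) <- sprintf("%s_sag_%s_%s", j, names(st), side)
        out <- c(out, st)
      }
    }
    out
  }
  kin8 <- function() {
    bw <- trial$body_mass * 9.81
    out <- c()
    for (side in c("r", "l")) {
      hs <- side_events(events, side)$hs
      vg <- if (side == "r") trial$vgrf_right else trial$vgrf_left
      v <- c(stride_stats(vg / bw, hs, trial$fs)["peak"],
             stride_stats(getch(paste0("grf_ap_", side)) / bw, hs, trial$fs)["peak"],
             stride_stats(getch(paste0("mom_ankle_sag_", side)), hs, trial$fs)["peak"],
             stride_stats(getch(paste0("pow_ankle_sag_", side)), hs, trial$fs)["peak"])
      names(v) <- paste0(c("vgrf_peak_", "grf_prop_peak_", "ankle_mom_peak_",
                           "ankle_pow_peak_"), side)
      out <- c(out, v)
    }
    out
  }
  st10 <- function() {
    rec <- compute_spatiotemporal(trial, events, truth)
    out <- c()
    for (i in seq_len(nrow(rec))) {
      v <- unlist(rec[i, c("cadence", "step_length", "stance_duration",
                           "swing_duration", "step_width")])
      names(v) <- paste0(c("cadence_", "step_length_", "stance_duration_",
                           "swing_duration_", "step_width_"), rec$side[i])
      out <- c(out, v)
    }
    out
  }
  switch(set_name,
         kinematic18 = kin18(),
         kinetic8 = kin8(),
         biomech26 = c(kin18(), kin8()),
         spatiotemporal10 = st10())
}

#' Discrete-variable table for a whole cohort
#'
#' @param cohort a `gait_cohort`.
#' @param set_name feature-set name, see [compute_discrete_variables()].
#' @param use_truth_events use generator ground-truth events instead of
#'   GRF-detected ones.
#' @return data.frame: metadata columns plus one column per variable.
#' @export
cohort_discrete_table <- function(cohort, set_name = "biomech26",
                                  use_truth_events = FALSE) {
  rows <- lapply(seq_along(cohort$trials), function(i) {
    tr <- cohort$trials[[i]]$trial
    tu <- cohort$trials[[i]]$truth
    ev <- if (use_truth_events) events_from_truth(tu) else trial_gait_events(tr)
    as.data.frame(t(compute_discrete_variables(tr, ev, set_name, truth = tu)))
  })
  cbind(cohort$metadata[, c("trial_id", "subject_id", "speed")],
        do.call(rbind, rows))
}
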