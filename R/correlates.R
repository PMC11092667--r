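condition_row <- function(meta, subject, condition) {
  rows <- which(meta$subject_id == subject)
  if (!length(rows)) return(NA_integer_)
  switch(condition,
         extreme_slow = rows[which.min(meta$speed[rows])],
         extreme_fast = rows[which.max(meta$speed[rows])],
         ss = {
           fl <- rows[which(meta$is_ss[rows])]
           if (length(fl)) fl[1] else NA_integer_
         },
         stop("unknown condition: ", condition))
}

#' Euclidean shift of a subject's signature between two speed conditions
#'
#' Conditions are `"ss"` (the flagged self-selected trial), `"extreme_slow"`
#' (the subject's slowest trial) and `"extreme_fast"` (fastest). By default
#' the shift is measured between the subject's two trial positions in the 3D
#' gait map; full flattened signature vectors can be used instead.
#'
#' @param coords an `mds_map`, coordinate matrix, or `signature_set`
#'   (full-vector mode).
#' @param meta trial metadata (`subject_id`, `speed`, `is_ss`), not needed
#'   when `coords` is a `signature_set`.
#' @param subject subject id.
#' @param cond_a,cond_b condition names.
#' @return Euclidean distance (NA with a warning when a trial is missing).
#' @export
signature_shift <- function(coords, meta = NULL, subject,
                            cond_a = "ss", cond_b = "extreme_slow") {
  if (inherits(coords, "signature_set")) {
    meta <- meta %||% coords$meta
    x <- coords$vectors
  } else {
    x <- coords_matrix(coords)
  }
  ia <- condition_row(meta, subject, cond_a)
  ib <- condition_row(meta, subject, cond_b)
  if (is.na(ia) || is.na(ib)) {
    warning("subject ", subject, " is missing a condition trial; skipped")
    return(NA_real_)
  }
  sqrt(sum((x[ia, ] - x[ib, ])^2))
}

#' Per-subject signature shifts and covariates
#'
#' @param coords an `mds_map` or coordinate matrix.
#' @param meta trial metadata with `subject_id`, `speed`, `is_ss`,
#'   `ss_speed`, `balance_score`.
#' @return data.frame per subject: `shift_slow` (self-selected to extreme
#'   slow), `shift_fast`, `ss_speed`, `balance_score`.
#' @export
compute_signature_shifts <- function(coords, meta) {
  subs <- unique(meta$subject_id)
  do.call(rbind, lapply(subs, function(s) {
    data.frame(subject_id = s,
               shift_slow = signature_shift(coords, meta, s, "ss", "extreme_slow"),
               shift_fast = signature_shift(coords, meta, s, "ss", "extreme_fast"),
               ss_speed = meta$ss_speed[meta$subject_id == s][1],
               balance_score = meta$balance_score[meta$subject_id == s][1],
               stringsAsFactors = FALSE)
  }))
}

#' Pearson correlation with two-sided p-value
#'
#' @param x,y numeric vectors (n >= 3, finite, non-constant).
#' @param alpha significance level recorded with the result.
#' @param pair label for the tested variable pair.
#' @return one-row data.frame: pair, r, p, n, alpha, significant.
#' @export
pearson_correlation <- function(x, y, alpha = 0.05, pair = "x~y") {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need at least 3 finite pairs")
  if (sd(x) < 1e-300 || sd(y) < 1e-300)
    stop("zero variance: Pearson r undefined")
  ct <- cor.test(x, y)
  data.frame(pair = pair, r = unname(ct$estimate), p = ct$p.value,
             n = length(x), alpha = alpha,
             significant = ct$p.value < alpha, stringsAsFactors = FALSE)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @return `alpha / m`.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 10) {
  stopifnot(m >= 1)
  alpha / m
}

#' Full correlation suite: shifts vs balance, speed and spatiotemporal deltas
#'
#' Block A (level `alpha`): balance score against self-selected speed, against
#' the self-selected-to-extreme-slow shift, and against the
#' self-selected-to-extreme-fast shift, plus the slow shift against
#' self-selected speed. Block B (Bonferroni level `alpha / 10`): each shift
#' against the ten bilateral spatiotemporal deltas (5 variables x 2 sides)
#' for its condition pair. All tests are reported regardless of significance.
#'
#' @param shifts data.frame from [compute_signature_shifts()].
#' @param deltas_slow,deltas_fast per-subject data.frames of spatiotemporal
#'   deltas (condition minus self-selected), 10 numeric columns each, rows
#'   aligned with `shifts`.
#' @param alpha base significance level.
#' @return data.frame of [pearson_correlation()] rows, with a `block` column.
#' @export
run_correlate_suite <- function(shifts, deltas_slow = NULL, deltas_fast = NULL,
                                alpha = 0.05) {
  out <- list()
  add <- function(df, block) {
    df$block <- block
    out[[length(out) + 1]] <<- df
  }
  add(pearson_correlation(shifts$balance_score, shifts$ss_speed, alpha,
                          "balance~ss_speed"), "primary")
  add(pearson_correlation(shifts$balance_score, shifts$shift_slow, alpha,
                          "balance~shift_slow"), "primary")
  add(pearson_correlation(shifts$balance_score, shifts$shift_fast, alpha,
                          "balance~shift_fast"), "primary")
  add(pearson_correlation(shifts$ss_speed, shifts$shift_slow, alpha,
                          "ss_speed~shift_slow"), "primary")
  a_b <- bonferroni_alpha(alpha, 10)
  for (blk in list(list(d = deltas_slow, shift = shifts$shift_slow,
                        tag = "slow"),
                   list(d = deltas_fast, shift = shifts$shift_fast,
                        tag = "fast"))) {
    if (is.null(blk$d)) next
    num <- blk$d[, vapply(blk$d, is.numeric, logical(1)), drop = FALSE]
    if (ncol(num) != 10)
      warning("expected 10 spatiotemporal delta columns, got ", ncol(num))
    for (v in names(num))
      add(pearson_correlation(blk$shift, num[[v]], a_b,
                              sprintf("shift_%s~delta_%s", blk$tag, v)),
          paste0("spatiotemporal_", blk$tag))
  }
  do.call(rbind, out)
}

#' Linear relationships of spatiotemporal variables with speed
#'
#' OLS of each trial-averaged bilateral variable against belt speed, reported
#' with Pearson r and the Bonferroni-adjusted level.
#'
#' @param st_table data.frame of trial-level variables (metadata columns
#'   `trial_id`, `subject_id`, `speed` are ignored as predictors).
#' @param speeds trial speeds (taken from the table when present).
#' @param alpha adjusted significance level (default 0.05 / 10).
#' @return data.frame: variable, slope, r, p, n, alpha, significant.
#' @export
spatiotemporal_speed_regressions <- function(st_table, speeds = st_table$speed,
                                             alpha = 0.005) {
  vars <- setdiff(names(st_table)[vapply(st_table, is.numeric, logical(1))],
                  c("speed", "speed_index"))
  do.call(rbind, lapply(vars, function(v) {
    y <- st_table[[v]]
    fit <- lm(y ~ speeds)
    ct <- suppressWarnings(cor.test(speeds, y))
    data.frame(variable = v, slope = unname(coef(fit)[2]),
               r = unname(ct$estimate), p = ct$p.value, n = length(y),
               alpha = alpha, significant = ct$p.value < alpha,
               stringsAsFactors = FALSE)
  }))
}

#' Spatiotemporal deltas between two conditions, per subject
#'
#' @param st_table trial-level spatiotemporal table (from
#'   [cohort_discrete_table()] with set `"spatiotemporal10"`).
#' @param meta cohort metadata aligned with `st_table` rows.
#' @param condition `"extreme_slow"` or `"extreme_fast"`; deltas are
#'   condition value minus self-selected value.
#' @return per-subject data.frame of 10 delta columns.
#' @export
spatiotemporal_deltas <- function(st_table, meta, condition = "extreme_slow") {
  vars <- setdiff(names(st_table)[vapply(st_table, is.numeric, logical(1))],
                  c("speed", "speed_index"))
  subs <- unique(meta$subject_id)
  do.call(rbind, lapply(subs, function(s) {
    ia <- condition_row(meta, s, "ss")
    ib <- condition_row(meta, s, condition)
    row <- as.data.frame(as.list(
      vapply(vars, function(v) st_table[[v]][ib] - st_table[[v]][ia],
             numeric(1))))
    cbind(data.frame(subject_id = s, stringsAsFactors = FALSE), row)
  }))
}
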