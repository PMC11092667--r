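coords_matrix <- function(coords) {
  if (inherits(coords, "mds_map")) coords <- coords$points
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 1,
                                             dimnames = list(NULL, "X"))
  if (is.null(colnames(coords)))
    colnames(coords) <- c("X", "Y", "Z")[seq_len(ncol(coords))]
  coords
}

#' Per-subject simple linear regressions of map coordinates on speed
#'
#' Ordinary least squares per (subject, coordinate); slope p-values are
#' two-sided. Subjects with fewer than 3 trials are skipped with a warning.
#'
#' @param coords an `mds_map` or N x d coordinate matrix.
#' @param speeds trial speeds (m/s).
#' @param subjects subject label per trial.
#' @return data.frame: subject_id, coordinate, slope, intercept, r2, p.
#' @export
per_subject_linear_fits <- function(coords, speeds, subjects) {
  pts <- coords_matrix(coords)
  rows <- list()
  for (s in unique(subjects)) {
    idx <- which(subjects == s)
    if (length(idx) < 3) {
      warning("subject ", s, " has fewer than 3 trials; skipped")
      next
    }
    for (a in colnames(pts)) {
      fit <- lm(pts[idx, a] ~ speeds[idx])
      sm <- summary(fit)
      r2 <- sm$r.squared
      # constant response: no variance to explain (avoid 0/0 round-off)
      if (!is.finite(r2) || sd(pts[idx, a]) < 1e-12) r2 <- 0
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, coordinate = a,
        slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
        r2 = r2,
        p = if (nrow(sm$coefficients) > 1) sm$coefficients[2, 4] else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# One random-intercept LME fit; ML estimation, Satterthwaite p for the slope.
fit_lme_single <- function(y, speeds, subjects, use_lmerTest = TRUE) {
  dat <- data.frame(y = y, speed = speeds, subject = factor(subjects))
  # degenerate resamples can hit the variance boundary; singularity is
  # reported via the `singular` flag rather than as console noise
  fit <- suppressWarnings(suppressMessages(
    if (use_lmerTest)
      lmerTest::lmer(y ~ speed + (1 | subject), data = dat, REML = FALSE)
    else
      lme4::lmer(y ~ speed + (1 | subject), data = dat, REML = FALSE)))
  fe <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  ranef_sd <- vc$sdcor[vc$grp == "subject"]
  resid_sd <- vc$sdcor[vc$grp == "Residual"]
  p <- NA_real_
  if (use_lmerTest) {
    cf <- coef(summary(fit))
    if ("Pr(>|t|)" %in% colnames(cf)) p <- cf["speed", "Pr(>|t|)"]
  }
  list(beta0 = unname(fe[1]), beta1 = unname(fe[2]),
       ranef_sd = ranef_sd, resid_sd = resid_sd, p_beta1 = p,
       r2 = cor(fitted(fit), y)^2,
       singular = lme4::isSingular(fit), model = fit)
}

#' Random-intercept mixed-effects models of map position versus speed
#'
#' Per coordinate: `coord ~ beta0 + beta1 * speed + (1 | subject)` fitted by
#' maximum likelihood. R^2 is the squared correlation between fitted values
#' (including the subject random effects) and observations. Singular fits
#' (random-intercept variance estimated at zero) are flagged, not hidden.
#'
#' @param coords an `mds_map` or coordinate matrix / vector.
#' @param speeds trial speeds (m/s).
#' @param subjects subject labels.
#' @return object of class `lme_speed_fit`: `table` (one row per coordinate:
#'   beta0, beta1, ranef_sd, resid_sd, p_beta1, r2, singular) and the fitted
#'   `models`.
#' @export
fit_lme <- function(coords, speeds, subjects) {
  pts <- coords_matrix(coords)
  if (length(unique(subjects)) < 2) stop("need at least 2 subjects")
  fits <- lapply(colnames(pts), function(a)
    fit_lme_single(pts[, a], speeds, subjects))
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    data.frame(coordinate = colnames(pts)[i], beta0 = f$beta0,
               beta1 = f$beta1, ranef_sd = f$ranef_sd,
               resid_sd = f$resid_sd, p_beta1 = f$p_beta1, r2 = f$r2,
               singular = f$singular, stringsAsFactors = FALSE)
  }))
  models <- lapply(fits, `[[`, "model")
  names(models) <- colnames(pts)
  out <- list(table = tab, models = models)
  class(out) <- "lme_speed_fit"
  out
}

#' @export
print.lme_speed_fit <- function(x, ...) {
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Hierarchical leave-one-subject-out bootstrap of the LME speed models
#'
#' For every left-out subject, every training-trial count `k`, and every
#' seeded random selection of `k` speed trials per remaining subject, the
#' random-intercept model is refitted. Selection seeds derive from
#' (left-out index, k, replicate), so the grid is reproducible. Summaries
#' report the mean and SD of the fixed effects and the range of the
#' random-intercept SD per coordinate, plus the per-k SD of the fixed slope
#' (expected to grow as k shrinks).
#'
#' @param coords an `mds_map` or coordinate matrix.
#' @param speeds trial speeds.
#' @param subjects subject labels.
#' @param trial_counts training-trial counts per subject.
#' @param n_selections random selections per (left-out subject, k) cell.
#' @param seed base seed for the selection hierarchy.
#' @return object of class `bootstrap_summary`: `fits` (one row per fit and
#'   coordinate), `summary` (per coordinate), `per_k` (per coordinate and k).
#' @export
hierarchical_bootstrap <- function(coords, speeds, subjects,
                                   trial_counts = 4:8, n_selections = 5,
                                   seed = 1L) {
  pts <- coords_matrix(coords)
  subj_levels <- unique(subjects)
  per <- table(subjects)
  if (any(trial_counts > min(per)))
    stop("trial_counts exceed the smallest per-subject trial count")
  rows <- list()
  for (li in seq_along(subj_levels)) {
    left_out <- subj_levels[li]
    keep0 <- which(subjects != left_out)
    for (k in trial_counts) {
      for (sel in seq_len(n_selections)) {
        idx <- with_seed(derive_seed(seed, li, k, sel), {
          unlist(lapply(setdiff(subj_levels, left_out), function(s) {
            rows_s <- keep0[subjects[keep0] == s]
            sample(rows_s, k)
          }))
        })
        for (a in colnames(pts)) {
          f <- fit_lme_single(pts[idx, a], speeds[idx], subjects[idx],
                              use_lmerTest = FALSE)
          rows[[length(rows) + 1]] <- data.frame(
            coordinate = a, left_out = left_out, k = k, selection = sel,
            beta0 = f$beta0, beta1 = f$beta1, ranef_sd = f$ranef_sd,
            resid_sd = f$resid_sd, singular = f$singular,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  fits <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(fits, fits$coordinate), function(d) {
    data.frame(coordinate = d$coordinate[1],
               beta0_mean = mean(d$beta0), beta0_sd = sd(d$beta0),
               beta1_mean = mean(d$beta1), beta1_sd = sd(d$beta1),
               ranef_sd_min = min(d$ranef_sd), ranef_sd_max = max(d$ranef_sd),
               n_fits = nrow(d), stringsAsFactors = FALSE)
  }))
  per_k <- do.call(rbind, lapply(split(fits, list(fits$coordinate, fits$k)),
                                 function(d) {
    data.frame(coordinate = d$coordinate[1], k = d$k[1],
               beta1_sd = sd(d$beta1), beta0_sd = sd(d$beta0),
               stringsAsFactors = FALSE)
  }))
  rownames(summary) <- rownames(per_k) <- NULL
  out <- list(fits = fits, summary = summary, per_k = per_k,
              grid = c(n_subjects = length(subj_levels),
                       n_counts = length(trial_counts),
                       n_selections = n_selections))
  class(out) <- "bootstrap_summary"
  out
}

#' Residual diagnostics for the LME speed models
#'
#' Residuals and fitted values per coordinate with a Shapiro-Wilk normality
#' test and a heteroscedasticity statistic (Pearson correlation between
#' absolute residuals and fitted values).
#'
#' @param fit an `lme_speed_fit` (or a single merMod).
#' @return list per coordinate: `table` (fitted, residual), `shapiro_p`,
#'   `het_cor`, `het_p`, `resid_mean`.
#' @export
residual_diagnostics <- function(fit) {
  models <- if (inherits(fit, "lme_speed_fit")) fit$models else list(model = fit)
  lapply(models, function(m) {
    r <- residuals(m); f <- fitted(m)
    ht <- suppressWarnings(cor.test(abs(r), f))
    list(table = data.frame(fitted = f, residual = r),
         shapiro_p = if (length(r) >= 3 && length(r) <= 5000)
           shapiro.test(r)$p.value else NA_real_,
         het_cor = unname(ht$estimate), het_p = ht$p.value,
         resid_mean = mean(r))
  })
}
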