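#' End-to-end run configuration
#'
#' Bundles the cohort and model configs with the analysis parameters. The
#' master seed propagates deterministic sub-seeds: the cohort uses
#' `master_seed`, model training `master_seed + 1`, classifier splits the run
#' number, and the bootstrap a seed derived from (left-out subject, k,
#' replicate).
#'
#' @param cohort a [cohort_config()].
#' @param rnn an [rnn_config()].
#' @param n_bins phase bins per gait cycle.
#' @param pca_threshold variance-retention threshold for the PC count.
#' @param k_range training-set sizes for the identification experiment.
#' @param n_runs seeded runs per training-set size.
#' @param trial_counts,n_selections hierarchical bootstrap grid.
#' @param master_seed master integer seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(), rnn = rnn_config(),
                       n_bins = 100, pca_threshold = 0.80,
                       k_range = 1:8, n_runs = 140,
                       trial_counts = 4:8, n_selections = 5,
                       master_seed = 1L) {
  cohort$seed <- as.integer(master_seed)
  rnn$seed <- as.integer(master_seed) + 1L
  cfg <- list(cohort = cohort, rnn = rnn, n_bins = as.integer(n_bins),
              pca_threshold = pca_threshold, k_range = k_range,
              n_runs = as.integer(n_runs), trial_counts = trial_counts,
              n_selections = as.integer(n_selections),
              master_seed = as.integer(master_seed))
  class(cfg) <- "run_config"
  cfg
}

#' Validate a run configuration
#'
#' Checks every invariant and returns a human-readable report instead of
#' failing.
#'
#' @param config a `run_config` (or a `cohort_config` / `rnn_config`).
#' @return data.frame of violations (zero rows when the config is valid).
#' @export
validate_config <- function(config) {
  viol <- list()
  note <- function(field, msg)
    viol[[length(viol) + 1]] <<- data.frame(field = field, problem = msg,
                                            stringsAsFactors = FALSE)
  if (inherits(config, "cohort_config")) {
    for (e in validate_cohort_config(config)) note("cohort", e)
  } else if (inherits(config, "rnn_config")) {
    if (config$dropout_rate < 0 || config$dropout_rate >= 1)
      note("rnn.dropout_rate", "must be in [0, 1)")
    if (config$learning_rate <= 0) note("rnn.learning_rate", "must be > 0")
  } else if (inherits(config, "run_config")) {
    for (e in validate_cohort_config(config$cohort)) note("cohort", e)
    if (config$rnn$dropout_rate < 0 || config$rnn$dropout_rate >= 1)
      note("rnn.dropout_rate", "must be in [0, 1)")
    if (config$rnn$learning_rate <= 0) note("rnn.learning_rate", "must be > 0")
    if (config$n_bins < 2) note("n_bins", "must be >= 2")
    if (config$pca_threshold <= 0 || config$pca_threshold > 1)
      note("pca_threshold", "must be in (0, 1]")
    if (any(config$k_range < 1) ||
        any(config$k_range >= config$cohort$speeds_per_subject))
      note("k_range", "k_train must be between 1 and trials_per_subject - 1")
    if (any(config$trial_counts >= config$cohort$speeds_per_subject))
      note("trial_counts", "must be below trials_per_subject")
    if (config$n_runs < 1) note("n_runs", "must be >= 1")
  } else {
    note("config", "unknown configuration object")
  }
  if (length(viol)) do.call(rbind, viol) else
    data.frame(field = character(), problem = character())
}

write_stage <- function(df, out_dir, name, files_env) {
  f <- file.path(out_dir, name)
  write.csv(df, f, row.names = FALSE)
  files_env$files <- c(files_env$files, f)
  f
}

#' Run the full gait-signatures pipeline
#'
#' simulate -> preprocess -> train -> signatures -> discriminate -> map ->
#' speed models -> correlates, writing every stage result as CSV plus a
#' manifest with file hashes, seeds and session info. Re-running with the
#' same config reproduces identical numeric outputs.
#'
#' @param config a [run_config()].
#' @param out_dir writable output directory.
#' @param quiet suppress stage log lines.
#' @return the manifest (invisibly also written as CSV), as a list with the
#'   stage outputs attached.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  rep <- validate_config(config)
  if (nrow(rep))
    stop("invalid config: ",
         paste(sprintf("%s (%s)", rep$problem, rep$field), collapse = "; "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("output directory is not writable: ", out_dir)
  fe <- new.env(); fe$files <- character()
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    say("[%s] done in %.1f s", name, as.numeric(Sys.time() - t0, units = "secs"))
    out
  }

  cohort <- stage("simulate", generate_cohort(config$cohort))
  write_stage(cohort$metadata, out_dir, "cohort_metadata.csv", fe)

  prep <- stage("preprocess", {
    feats <- lapply(cohort$trials, function(x)
      assemble_feature_set(x$trial)$features)
    events <- lapply(cohort$trials, function(x) trial_gait_events(x$trial))
    st <- cohort_discrete_table(cohort, "spatiotemporal10")
    list(feats = feats, events = events, st = st)
  })
  write_stage(prep$st, out_dir, "spatiotemporal.csv", fe)

  model <- stage("train", train_dynamics_model(prep$feats, config$rnn))
  write_stage(data.frame(epoch = seq_along(model$loss_history),
                         mse = model$loss_history),
              out_dir, "training_history.csv", fe)

  sigs <- stage("signatures", {
    lat <- lapply(prep$feats, function(f) extract_latent_states(model, f))
    basis <- fit_latent_pca(lat)
    curve <- variance_explained_curve(model, basis, prep$feats,
                                      config$pca_threshold, latents = lat)
    n_pcs <- curve$n_retained
    set <- build_signatures(model, basis, prep$feats, prep$events, n_pcs,
                            config$n_bins, meta = cohort$metadata)
    list(basis = basis, curve = curve, n_pcs = n_pcs, set = set)
  })
  write_stage(data.frame(n_pcs = seq_along(sigs$curve$r2), r2 = sigs$curve$r2),
              out_dir, "variance_curve.csv", fe)
  write_stage(cbind(sigs$set$meta, as.data.frame(sigs$set$vectors)),
              out_dir, "signatures.csv", fe)

  disc <- stage("discriminate", {
    complete <- filter_complete_subjects(sigs$set,
                                         config$cohort$speeds_per_subject)
    speed_generalization_experiment(complete, config$k_range, config$n_runs,
                                    label = config$cohort$data_type)
  })
  write_stage(disc$results, out_dir, "classification_runs.csv", fe)
  write_stage(disc$summary, out_dir, "classification_summary.csv", fe)

  map <- stage("map", {
    D <- pairwise_signature_distances(sigs$set)
    m <- mds_embed(D, 3, speeds = sigs$set$meta$speed,
                   subjects = sigs$set$meta$subject_id)
    dstats <- intra_inter_stats(as.matrix(dist(m$points)),
                                sigs$set$meta$subject_id)
    list(D = D, map = m, dstats = dstats)
  })
  write_stage(cbind(sigs$set$meta[, c("trial_id", "subject_id", "speed")],
                    as.data.frame(map$map$points)),
              out_dir, "gait_map.csv", fe)

  spd <- stage("speedmodels", {
    fits <- per_subject_linear_fits(map$map, sigs$set$meta$speed,
                                    sigs$set$meta$subject_id)
    lme <- fit_lme(map$map, sigs$set$meta$speed, sigs$set$meta$subject_id)
    boot <- hierarchical_bootstrap(map$map, sigs$set$meta$speed,
                                   sigs$set$meta$subject_id,
                                   config$trial_counts, config$n_selections,
                                   seed = config$master_seed)
    list(fits = fits, lme = lme, boot = boot)
  })
  write_stage(spd$fits, out_dir, "per_subject_fits.csv", fe)
  write_stage(spd$lme$table, out_dir, "lme_fits.csv", fe)
  write_stage(spd$boot$summary, out_dir, "bootstrap_summary.csv", fe)

  corr <- stage("correlates", {
    shifts <- compute_signature_shifts(map$map, sigs$set$meta)
    d_slow <- spatiotemporal_deltas(prep$st, cohort$metadata, "extreme_slow")
    d_fast <- spatiotemporal_deltas(prep$st, cohort$metadata, "extreme_fast")
    suite <- run_correlate_suite(shifts, d_slow[, -1], d_fast[, -1])
    regs <- spatiotemporal_speed_regressions(prep$st)
    list(shifts = shifts, suite = suite, regs = regs)
  })
  write_stage(corr$suite, out_dir, "correlations.csv", fe)
  write_stage(corr$regs, out_dir, "spatiotemporal_regressions.csv", fe)

  manifest <- data.frame(file = basename(fe$files),
                         md5 = unname(tools::md5sum(fe$files)),
                         stringsAsFactors = FALSE)
  manifest_path <- file.path(out_dir, "manifest.csv")
  write.csv(cbind(manifest,
                  master_seed = config$master_seed,
                  r_version = as.character(getRversion())),
            manifest_path, row.names = FALSE)
  say("[manifest] %d files", nrow(manifest))

  invisible(list(manifest = manifest, cohort = cohort, model = model,
                 signatures = sigs, discrimination = disc, map = map,
                 speed_models = spd, correlates = corr, config = config))
}
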