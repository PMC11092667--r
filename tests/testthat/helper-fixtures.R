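# Shared fixtures, built once per test run and memoized.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]]))
    assign(key, force(expr), envir = .fixture_cache)
  .fixture_cache[[key]]
}

# A small clean cohort for generator/preprocess tests.
mini_cohort <- function(n_subjects = 3, speeds = 3, duration = 10,
                        data_type = "kin3d", noise_sd = 0, jitter_sd = 0,
                        seed = 7, ...) {
  generate_cohort(cohort_config(n_subjects = n_subjects,
                                speeds_per_subject = speeds,
                                duration_s = duration, data_type = data_type,
                                noise_sd = noise_sd, jitter_sd = jitter_sd,
                                seed = seed, ...))
}

# A tiny trained dynamics model on a clean single-harmonic 2D-kinematics
# cohort: cheap enough for unit tests, accurate enough to have structure.
tiny_stack <- function() {
  cached("tiny_stack", {
    cfg <- cohort_config(n_subjects = 4, speeds_per_subject = 3,
                         duration_s = 8, data_type = "kin2d",
                         n_harmonics = 1, noise_sd = 0, jitter_sd = 0,
                         seed = 11)
    co <- generate_cohort(cfg)
    feats <- lapply(co$trials, function(x) assemble_feature_set(x$trial)$features)
    events <- lapply(co$trials, function(x) trial_gait_events(x$trial))
    model <- train_dynamics_model(
      feats, rnn_config(hidden_units = 24, learning_rate = 5e-3,
                        dropout_rate = 0, l2_strength = 0, epochs = 150,
                        patience = 0, seed = 12))
    lat <- lapply(feats, function(f) extract_latent_states(model, f))
    basis <- fit_latent_pca(lat)
    list(cohort = co, feats = feats, events = events, model = model,
         latents = lat, basis = basis)
  })
}

# The study-scale stack used by the acceptance tests: 8 subjects x 6 speeds,
# 20 s @ 100 Hz, 3D kinematics, 64-unit model.
acceptance_stack <- function() {
  cached("acceptance_stack", {
    cfg <- cohort_config(n_subjects = 8, speeds_per_subject = 6,
                         duration_s = 20, data_type = "kin3d", seed = 20)
    co <- generate_cohort(cfg)
    feats <- lapply(co$trials, function(x) assemble_feature_set(x$trial)$features)
    events <- lapply(co$trials, function(x) trial_gait_events(x$trial))
    model <- train_dynamics_model(
      feats, rnn_config(hidden_units = 64, learning_rate = 3e-3,
                        epochs = 60, patience = 0, seed = 21))
    lat <- lapply(feats, function(f) extract_latent_states(model, f))
    basis <- fit_latent_pca(lat)
    curve <- variance_explained_curve(model, basis, feats, latents = lat)
    n_pcs <- max(curve$n_retained, 3)
    sigs <- build_signatures(model, basis, feats, events, n_pcs,
                             n_bins = 100, meta = co$metadata)
    list(cohort = co, feats = feats, events = events, model = model,
         latents = lat, basis = basis, curve = curve, sigs = sigs)
  })
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected) / pmax(abs(expected), 1e-12)), tol)
}
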