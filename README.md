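# gaitsignatures

Individual humans walk in recognizably individual ways, and they keep doing
so across walking speeds. **gaitsignatures** implements an analysis pipeline
that makes this quantitative: a recurrent dynamics model (a single-layer LSTM
with a linear readout) is trained to predict continuous multi-channel gait
time series — joint angles, and optionally ground reaction forces, joint
moments and powers — one sample ahead, jointly for all subjects and speeds.
The model's per-time-step hidden states are reduced with PCA and
phase-averaged over the gait cycle, yielding one *gait signature* per trial:

```
x(t) ──LSTM──> h(t) ──PCA──> scores(t) ──phase-average──> loop (n_PCs × 100)
                                                            └── flatten → signature vector
```

On top of the signatures the package provides the full set of downstream
analyses:

* **Identification** — seeded linear-SVM experiments asking whether a
  subject can be named from held-out speed trials (`k` training trials per
  subject, accuracy pooled over test trials, Mann-Whitney comparisons with
  effect size r = Z/sqrt(n)).
* **Gait map** — classical MDS embedding of all pairwise signature
  distances into 3-D, with z-scored intra- vs inter-individual distance
  statistics.
* **Speed models** — per-subject OLS of map coordinates on belt speed, and
  random-intercept linear mixed-effects models
  `coord ~ speed + (1 | subject)` with a hierarchical leave-one-subject-out
  bootstrap.
* **Correlates** — Pearson correlations relating signature shifts between
  speed conditions to balance ability, self-selected speed and
  spatiotemporal changes, with Bonferroni control.

Because real motion-capture cohorts cannot ship with a package, a synthetic
cohort generator (`generate_cohort()`) produces multi-subject, multi-speed
trials with known individual identity, known linear speed modulation, and
ground-truth gait events — so every stage can be tested against a known
answer. Audience: movement scientists and methods developers who want a
complete, deterministic, unit-tested reference implementation of the
signature pipeline.

## Worked example

Eight subjects, six speeds each, 20-s trials of 3-D kinematics (18
channels), 64 hidden units:

```r
library(gaitsignatures)

cfg    <- cohort_config(n_subjects = 8, speeds_per_subject = 6,
                        duration_s = 20, data_type = "kin3d", seed = 20)
cohort <- generate_cohort(cfg)
feats  <- lapply(cohort$trials, function(x) assemble_feature_set(x$trial)$features)
events <- lapply(cohort$trials, function(x) trial_gait_events(x$trial))

model  <- train_dynamics_model(feats,
            rnn_config(hidden_units = 64, learning_rate = 3e-3,
                       epochs = 60, patience = 0, seed = 21))
lat    <- lapply(feats, function(f) extract_latent_states(model, f))
basis  <- fit_latent_pca(lat)
curve  <- variance_explained_curve(model, basis, feats, latents = lat)
curve$n_retained
#> [1] 3            # 3 PCs explain >= 80% of the original channels

sigs <- build_signatures(model, basis, feats, events,
                         n_pcs = curve$n_retained, n_bins = 100,
                         meta = cohort$metadata)

res <- speed_generalization_experiment(filter_complete_subjects(sigs, 6),
                                       k_range = 4, n_runs = 20)
res$summary$mean_accuracy
#> [1] 1            # every held-out speed trial assigned to the right subject

map <- mds_embed(pairwise_signature_distances(sigs), 3,
                 speeds = sigs$meta$speed, subjects = sigs$meta$subject_id)
map
#> mds_map: 48 trials in 3D (distance correlation 0.981, stress 0.121)

intra_inter_stats(as.matrix(dist(map$points)), sigs$meta$subject_id)
#> distance_stats: 120 intra / 1008 inter pairs; median z -0.59 vs -0.05;
#> MWU p = 6.85e-07   # same-subject trials sit significantly closer together

fit_lme(map, sigs$meta$speed, sigs$meta$subject_id)
#>  coordinate      beta0      beta1  ranef_sd  resid_sd      p_beta1        r2
#>           X -3.90       3.39       0.71      0.18         2.1e-44     0.994
#>           Y  0.51      -0.44       1.16      0.12         2.4e-18     0.992
#>           Z  0.34      -0.29       0.82      0.07         5.6e-20     0.994
```

The interpretation: trials of the same subject cluster tightly in the map
while remaining linearly ordered by speed along the first axis — individual
identity and speed modulation coexist in the same low-dimensional space,
which is the core phenomenon the pipeline is built to expose.

`run_pipeline(run_config(...), out_dir)` chains all stages and writes every
result as CSV with a hash manifest; reruns are byte-identical.

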