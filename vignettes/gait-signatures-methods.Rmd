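---
title: "Gait signatures: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait signatures: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The idea

Walking looks stereotyped, yet every person organizes their joints over time
in a recognizably individual way. A *gait signature* is a compact description
of that organization. Instead of summarizing a trial by discrete numbers
(peak knee flexion, cadence, step length), we fit a dynamics model — a
single-hidden-layer LSTM with a linear readout — that predicts every measured
channel one sample ahead, jointly for all subjects and speeds. The model's
hidden state at each time step is then a learned coordinate system for the
cohort's gait dynamics. Per trial, we project the hidden-state trajectory
onto the leading principal components of the pooled latent space, resample
each stride onto a common 0–100% gait-cycle axis, and average across strides.
The resulting loop (retained PCs × phase bins), flattened to one vector per
trial, is the signature: it can be classified (who is walking?), embedded
into a 3-D gait map (how do trials relate?), and regressed on belt speed
(how does coordination change when walking faster?).

`run_pipeline()` chains all stages; each stage is also exported on its own.

## The synthetic cohort

Real motion-capture cohorts cannot ship inside a package, so
`generate_cohort()` produces a synthetic one with *known* answers for every
downstream question. Each subject is a set of stride-locked cosine harmonics:

* channel $c$ at stride phase $\varphi$ is
  $\sum_h A_{ch}\,(1+\gamma\,(s-\bar s)/\bar s)\cos(2\pi h\varphi + \psi_{ch})$,
* the harmonic amplitudes $A$ and phases $\psi$ are individual-specific
  (between-subject dispersion 15% and 0.25 rad by default) — this is the
  identity signal,
* cadence rises linearly with belt speed $s$ (intercept ~95 steps/min,
  slope ~25 steps/min per m/s), and amplitudes scale linearly through the
  speed gain $\gamma = 0.3$ about the cohort mid-speed $\bar s$ — this is the
  speed signal,
* stride periods carry multiplicative jitter (SD 2% of the period), channels
  carry additive Gaussian noise (SD 0.5 channel units), and each side's
  vertical ground reaction force is a body-weight-scaled two-peak stance
  template, exactly zero in swing, with the stance fraction falling linearly
  from 0.65 at the slowest to 0.55 at the fastest cohort speed.

Channel sets mirror common laboratory exports: 6 sagittal angles (`kin2d`),
18 three-plane angles (`kin3d`), 42 kinetic channels — body-weight-normalized
ground reaction forces, joint moments and powers (`kinetics3d`) — or all 60
(`combined`). Kinetic channels reuse the harmonic model with stance-gated
envelopes for the forces; the pipeline cares about cyclic structure, not
biomechanical fidelity.

Defaults (17 subjects × 9 speeds from 0.3 to 2.0 m/s, 60 s at 100 Hz) mirror
a full treadmill protocol spanning very slow walking up to the walk-to-run
transition. Self-selected speed and a narrowing-beam balance score are drawn
jointly with correlation 0.5, so the correlate analyses have a known positive
dependence to find. What the generator deliberately does **not** emulate:
non-sinusoidal waveform detail, asymmetric or impaired gait, soft-tissue or
marker artifacts, non-stationarity within a trial, and any nonlinear
speed–amplitude relation. Tests passing on this cohort therefore certify the
pipeline's mechanics and statistics, not its behavior on any real population.

Every quantity is reproducible: a cohort is a pure function of its config
(seeds for subject draws and trials are derived from the config seed), and
ground-truth events, cadence, step length, stance/swing durations and step
width accompany every trial.

## The dynamics model

`train_dynamics_model()` fits the LSTM (default 512 units; the bundled
experiments use 64) full-batch — one batch contains every trial — with Adam,
to minimize the mean squared one-step-ahead prediction error on per-channel
standardized data. Regularization follows gait-modelling practice for
stereotyped cyclic data: a dropout layer (rate 0.2) after the hidden layer,
active only in training, and an L2 penalty (0.01) on the input kernel.
Training is deterministic given the config seed (weight initialization and
dropout masks come from a dedicated generator), and the per-epoch loss is
stored with the model. The backward pass is plain BPTT; its gradients are
verified against central finite differences in the test suite.

Choices worth recording:

* *Latent state.* "Internal activations" is read as the hidden state $h_t$
  (the layer's output, which feeds the readout); `extract_latent_states()`
  can concatenate the cell state on request.
* *Teacher forcing.* Prediction of row $t+1$ always conditions on the
  *observed* rows up to $t$ — the plain reading of sequence-to-sequence
  one-step prediction.
* *Dropout at extraction.* Latents are extracted with dropout disabled;
  extraction is a pure function of (weights, input).
* *Epochs.* The bundled experiments train for a fixed 60 epochs at learning
  rate 3e-3 on 20-s trials (48 trials × 18 channels × 64 units), which
  reaches a stable mean-squared-error plateau (~0.08 in standardized units)
  in a few minutes on one CPU; the defaults (500 epochs, early stopping with
  patience 25 at tolerance 1e-5, learning rate 1e-4) suit overnight-scale
  fits of larger models.
* *Standardization.* Channel means/SDs are computed on the training cohort
  and stored with the model, so later trials are embedded on the same scale.

## From latents to signatures

`fit_latent_pca()` pools all trials' hidden-state rows, centers them, and
eigen-decomposes the covariance; component signs are canonicalized (largest
loading positive) so refits are bit-identical. `phase_average()` resamples
each right-heel-strike-to-right-heel-strike stride onto `n_bins = 100`
equispaced phase points (the conventional "% gait cycle" resolution; phase is
defined from right heel strikes) and averages pointwise; strides shorter than
half or longer than twice the median stride are excluded and counted.
Because projection and phase-averaging are both linear they commute — a
property the tests exploit as an oracle.

The retained dimensionality comes from `variance_explained_curve()`: for
each $N$, every trial's latents are replaced by their rank-$N$ PCA
reconstruction, passed through the model's existing linear readout (no
retraining — the deterministic reading of "update the model to the top-N
PCs"), and compared against the measured standardized channels as a pooled
$1 - \mathrm{SSE}/\mathrm{SST}$ across all channels and trials. The smallest
$N$ reaching 80% cumulative $R^2$ is retained. Two numerical notes: at
$N = K$ the curve equals the full model's one-step $R^2$ exactly (the basis
is complete), and the curve is monotone only up to ~1e-5 wiggles in its flat
tail, because PC directions orthogonal in latent space are merely
near-orthogonal after the readout; tests assert monotonicity with a 1e-4
tolerance for this reason.

## Identification, map, speed models, correlates

*Identification.* `speed_generalization_experiment()` asks whether a linear
SVM (one-vs-one, cost 1, features z-scored with training-set statistics
only) can name the subject of held-out speed trials. For each training-set
size $k$ it runs seeded splits (seed = run number; 140 runs at full scale,
20 in the bundled experiments), drawing $k$ of each subject's trials into
training and pooling accuracy over all test trials. Subjects lacking the
full set of speed trials are excluded first (`filter_complete_subjects()`).
Accuracy distributions between channel sets are compared with two-sided
Mann-Whitney U tests; the effect size is $r = Z/\sqrt{n_a+n_b}$ with a
tie-corrected normal $Z$. Discrete-variable baselines (26 biomechanical, 18
kinematic-only, 8 kinetic-only, 10 spatiotemporal) run the identical
protocol. The exact membership of the 26-variable set follows common gait
practice (per-side peak/minimum/excursion of sagittal hip, knee, ankle
angles, plus per-side peak vertical and propulsive GRF, ankle moment and
power); the feature *counts* are the binding contract.

*Gait map.* `mds_embed()` uses classical (Torgerson) scaling — chosen over
iterative stress-minimizing MDS because it is deterministic — with axis
signs canonicalized against speed (axis 1) and subject order (axes 2–3).
`intra_inter_stats()` z-scores all pairwise distances with their pooled
mean/SD and compares intra- vs inter-individual groups with a Mann-Whitney
U test; lower- and upper-tail proportions (|z| beyond 2) are reported
separately per group, since tightly clustered within-subject trials populate
the *lower* tail by construction. The distance statistics default to the 3-D
map coordinates (a config switch computes them on the full >100-D vectors
instead; both contrasts agree in sign).

*Speed models.* Per subject and axis, `per_subject_linear_fits()` runs OLS
of map position on speed. `fit_lme()` fits
$\mathrm{coord} \sim \beta_0 + \beta_1\,\mathrm{speed} + (1\,|\,\mathrm{subject})$
by maximum likelihood (not REML — a documented choice; the Satterthwaite
$p$ for $\beta_1$ comes from lmerTest), reporting $R^2$ as the squared
correlation of fitted (including random effects) and observed values.
Singular fits are flagged, never hidden. `hierarchical_bootstrap()` refits
the model over a leave-one-subject-out × trials-per-subject (4–8) × 5
random-selection grid with seeds derived from the cell coordinates; slope
variability is expected to grow as trials per subject shrink.
`residual_diagnostics()` reports Shapiro-Wilk normality and an
|residual|-vs-fitted correlation as the heteroscedasticity check.

*Correlates.* `run_correlate_suite()` relates per-subject signature shifts
(self-selected → extreme-slow and → extreme-fast, Euclidean in the 3-D map
by default) to balance score and self-selected speed at α = 0.05 (four
tests), and to the ten bilateral spatiotemporal deltas per condition pair at
the Bonferroni level 0.05/10 = 0.005. All results are reported regardless of
significance. Two-sided tests throughout.

## Degenerate inputs and tie-breaks

Zero-variance feature columns are left unscaled rather than dividing by
zero; an all-identical distance matrix yields all-zero z-scores with a
warning; subjects with a single trial contribute no intra-individual
distances (warned); constant responses get $R^2 = 0$; fewer than 3 strides,
empty sequences, mismatched channel counts and invalid configs raise errors
naming the offender. Event detection merges threshold crossings closer than
0.2 median strides and requires 50 ms below threshold before a heel strike;
series that open mid-stance do not produce a phantom strike at sample 1.

## Problem sizes in the bundled experiments

The packaged tests and the acceptance script run the full pipeline on an
8-subject × 6-speed cohort of 20-s three-plane-kinematics trials with a
64-unit model, 20 identification runs per condition, a 100-replicate
mixed-model recovery simulation at the full 17 × 9 design, and a bootstrap
over trial counts 4–8. These sizes were chosen as the smallest at which every
statistical property of interest is comfortably away from its noise floor on
a single desktop CPU; all of them are plain arguments, so larger studies
only change the config.

## Known limitations

The generator's harmonic gait is far more linearly speed-modulated than real
walking, so the near-perfect linear fits on synthetic maps should not be
read as a claim about human data. The LSTM trainer is full-batch only (the
intended regime here); it does not shard batches or run on GPUs. Classical
MDS assumes Euclidean embeddability; strongly non-Euclidean signature
distances would call for the metric-stress variant behind the same
interface. The 26-variable discrete set is a documented stand-in for
laboratory conventions that vary between sites.
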