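test_that("latent PCA matches the prcomp oracle and is canonicalized", {
  set.seed(10)
  L <- matrix(rnorm(400 * 6), 400, 6) %*% matrix(rnorm(36), 6)
  basis <- fit_latent_pca(list(L[1:200, ], L[201:400, ]))
  expect_lt(max(abs(crossprod(basis$rotation) - diag(ncol(basis$rotation)))), 1e-8)
  expect_true(all(diff(basis$eigenvalues) <= 1e-8))
  pr <- prcomp(L, center = TRUE, scale. = FALSE)
  k <- ncol(basis$rotation)
  expect_equal(abs(basis$rotation), abs(pr$rotation[, 1:k]), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(basis$eigenvalues, pr$sdev[1:k]^2, tolerance = 1e-6)
  # deterministic re-fit
  basis2 <- fit_latent_pca(list(L[1:200, ], L[201:400, ]))
  expect_identical(basis$rotation, basis2$rotation)

  # exact low-rank input: trailing eigenvalues vanish, back-projection exact
  W <- matrix(rnorm(18), 6, 3)
  L3 <- matrix(rnorm(300 * 3), 300, 3) %*% t(W)
  expect_warning(b3 <- fit_latent_pca(list(L3[1:150, ], L3[151:300, ])),
                 "rank-deficient")
  expect_lte(ncol(b3$rotation), 3)
  cent <- sweep(L3, 2, b3$mean)
  back <- (cent %*% b3$rotation) %*% t(b3$rotation)
  expect_lt(max(abs(back - cent)), 1e-8)
})

test_that("phase averaging reproduces closed forms", {
  # constant trajectory -> constant loop
  ev <- list(heel_strikes_right = seq(1, 901, by = 100))
  class(ev) <- "gait_events"
  traj <- matrix(4.2, 1000, 2)
  pa <- phase_average(traj, ev, 50)
  expect_equal(dim(pa$loop), c(2, 50))
  expect_true(all(abs(pa$loop - 4.2) < 1e-12))

  # noise-free cosine with exact strides -> one sampled cosine period
  t <- 0:999
  stride <- 100
  x <- cos(2 * pi * t / stride + 0.7)
  pa2 <- phase_average(cbind(x), ev, 50)
  expected <- cos(2 * pi * (0:49) / 50 + 0.7)
  expect_lt(max(abs(pa2$loop[1, ] - expected)), 1e-3)

  # duplicating the strides leaves the mean loop unchanged
  traj2 <- rbind(cbind(x), cbind(x))
  ev2 <- list(heel_strikes_right = c(ev$heel_strikes_right,
                                     1000 + ev$heel_strikes_right))
  class(ev2) <- "gait_events"
  pa3 <- phase_average(traj2, ev2, 50)
  expect_equal(pa3$loop, pa2$loop, tolerance = 1e-9)

  expect_error(phase_average(traj, list(heel_strikes_right = c(1, 101, 201)), 50),
               "3 complete strides")
})

test_that("outlier strides are excluded and counted", {
  ev <- list(heel_strikes_right = c(1, 101, 201, 301, 331, 431))  # one 30-sample stride
  class(ev) <- "gait_events"
  pa <- phase_average(matrix(rnorm(500), 500, 1), ev, 20)
  expect_equal(pa$n_excluded, 1)
  expect_equal(pa$n_strides, 4)
})

test_that("phase-averaging commutes with PC projection", {
  co <- tiny_stack()
  st <- extract_latent_states(co$model, co$feats[[1]])
  ev <- co$events[[1]]
  sc <- project_latents(co$basis, st, 4)
  a <- phase_average(sc, ev, 40)$loop
  b_lat <- phase_average(st$states, ev, 40)$loop     # n_units x bins
  b <- t(co$basis$rotation[, 1:4]) %*% (b_lat - matrix(co$basis$mean, nrow(b_lat), 40))
  expect_lt(max(abs(a - b)), 1e-8)
})

test_that("signature vectors have the contracted length and determinism", {
  co <- tiny_stack()
  sigs <- build_signatures(co$model, co$basis, co$feats, co$events,
                           n_pcs = 6, n_bins = 100,
                           meta = co$cohort$metadata)
  expect_equal(ncol(sigs$vectors), 600)
  s10 <- build_signatures(co$model, co$basis, co$feats[1:2], co$events[1:2],
                          n_pcs = 10, n_bins = 100)
  expect_equal(ncol(s10$vectors), 1000)
  # identical trials -> identical signatures
  dup <- build_signatures(co$model, co$basis,
                          list(co$feats[[1]], co$feats[[1]]),
                          list(co$events[[1]], co$events[[1]]), 4, 50)
  expect_identical(dup$vectors[1, ], dup$vectors[2, ])
  # row-major flattening of the loop
  expect_identical(sigs$vectors[1, ], as.vector(t(sigs$loops[[1]])))
})

test_that("variance curve is monotone and complete at full rank", {
  co <- tiny_stack()
  curve <- variance_explained_curve(co$model, co$basis, co$feats,
                                    latents = co$latents)
  # monotone up to numerical tolerance: the PC directions are orthogonal in
  # latent space but only approximately so after the linear readout
  expect_true(all(diff(curve$r2) >= -1e-4))
  full_r2 <- gaitsignatures:::one_step_r2(co$model, co$feats)
  expect_equal(curve$r2[length(curve$r2)], full_r2, tolerance = 1e-6)
})

test_that("constructed rank-2 latent structure plateaus by N = 2", {
  set.seed(3)
  H <- 8; C <- 3; T_ <- 300
  R <- qr.Q(qr(matrix(rnorm(H * 2), H, 2)))
  S1 <- cbind(sin(2 * pi * (1:T_) / 40), cos(2 * pi * (1:T_) / 40)) %*% diag(c(3, 1.5))
  S2 <- cbind(sin(2 * pi * (1:T_) / 40 + 1), cos(2 * pi * (1:T_) / 40 + 1))
  # a whisper of isotropic noise keeps the basis full-rank so the plateau
  # claim (PCs 3..K add nothing) is non-trivial
  lat1 <- S1 %*% t(R) + matrix(rnorm(T_ * H, 0, 1e-4), T_, H)
  lat2 <- S2 %*% t(R) + matrix(rnorm(T_ * H, 0, 1e-4), T_, H)
  Wy <- matrix(rnorm(H * C), H, C); by <- rnorm(C)
  model <- structure(list(Wx = matrix(0, C, 4 * H), Wh = matrix(0, H, 4 * H),
                          b = rep(0, 4 * H), Wy = Wy, by = by,
                          center = rep(0, C), scale = rep(1, C),
                          trained = TRUE, config = rnn_config(hidden_units = H)),
                     class = "gait_dynamics_model")
  mk_trial <- function(lat) rbind(0, lat %*% Wy + matrix(by, T_, C, byrow = TRUE))
  trials <- list(mk_trial(lat1), mk_trial(lat2))
  basis <- fit_latent_pca(list(lat1, lat2))
  curve <- variance_explained_curve(model, basis, trials,
                                    latents = list(lat1, lat2))
  K <- length(curve$r2)
  expect_gt(K, 2)
  expect_lt(abs(curve$r2[2] - curve$r2[K]), 1e-3)
  expect_gt(curve$r2[K], 0.999)
})

test_that("PC retention rule picks the smallest sufficient count", {
  expect_equal(select_n_pcs(list(r2 = c(0.5, 0.7, 0.83, 0.9)), 0.8), 3)
  expect_equal(select_n_pcs(list(r2 = c(0.5, 0.7, 0.83, 0.9)), 0.0), 1)
  expect_warning(n <- select_n_pcs(list(r2 = c(0.1, 0.2)), 0.8),
                 "never reached")
  expect_equal(n, 2)
  expect_error(select_n_pcs(list(r2 = numeric(0))), "empty")
})
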