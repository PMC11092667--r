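#' Fit a PCA basis on pooled latent states
#'
#' Principal components of the time-concatenated latent matrix across all
#' trials (rows = time steps), centred on the pooled mean. Computed by
#' eigen-decomposition of the latent covariance; component signs are
#' canonicalized (largest-magnitude loading positive) so repeated fits are
#' identical.
#'
#' @param latents list of `latent_states` (or plain T' x H matrices).
#' @return object of class `latent_pca`: `mean` (H), `rotation` (H x K,
#'   orthonormal columns), `eigenvalues` (non-increasing, length K).
#' @export
fit_latent_pca <- function(latents) {
  mats <- lapply(latents, function(l) if (inherits(l, "latent_states")) l$states else l)
  if (length(mats) < 2) stop("need latent states from at least 2 trials")
  L <- do.call(rbind, mats)
  mu <- colMeans(L)
  Lc <- sweep(L, 2, mu)
  cv <- crossprod(Lc) / (nrow(Lc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  K <- sum(eg$values > max(eg$values[1], 0) * 1e-12)
  if (K < ncol(L))
    warning(sprintf("latents are rank-deficient: keeping %d of %d components",
                    K, ncol(L)))
  K <- max(K, 1L)
  rot <- eg$vectors[, seq_len(K), drop = FALSE]
  for (k in seq_len(K)) {
    j <- which.max(abs(rot[, k]))
    if (rot[j, k] < 0) rot[, k] <- -rot[, k]
  }
  out <- list(mean = mu, rotation = rot,
              eigenvalues = pmax(eg$values[seq_len(K)], 0))
  class(out) <- "latent_pca"
  out
}

#' Project latent states onto a PCA basis
#'
#' @param basis a `latent_pca`.
#' @param states `latent_states` or T' x H matrix.
#' @param n_pcs number of leading components (default: all).
#' @return T' x n_pcs score matrix.
#' @export
project_latents <- function(basis, states, n_pcs = ncol(basis$rotation)) {
  if (inherits(states, "latent_states")) states <- states$states
  if (n_pcs > ncol(basis$rotation)) stop("n_pcs exceeds available components")
  sweep(states, 2, basis$mean) %*% basis$rotation[, seq_len(n_pcs), drop = FALSE]
}

#' Phase-average a trajectory over the gait cycle
#'
#' Each right-side stride `[HS_i, HS_{i+1})` is linearly resampled onto
#' `n_bins` equispaced phase points (bin 1 at the heel strike; the loop is
#' periodic, bin `n_bins` abutting bin 1) and the strides are averaged
#' pointwise. Strides shorter than half or longer than twice the median
#' stride are excluded and counted.
#'
#' @param trajectory T' x d numeric matrix.
#' @param events a `gait_events` (right heel strikes define phase).
#' @param n_bins number of phase bins (conventional gait-cycle resolution 100).
#' @return list: `loop` (d x n_bins matrix), `n_strides` used, `n_excluded`.
#' @export
phase_average <- function(trajectory, events, n_bins = 100) {
  if (is.null(dim(trajectory))) trajectory <- matrix(trajectory, ncol = 1)
  hs <- events$heel_strikes_right
  hs <- hs[hs <= nrow(trajectory)]
  if (length(hs) < 4) stop("need at least 3 complete strides")
  lens <- diff(hs)
  med <- median(lens)
  ok <- lens >= 0.5 * med & lens <= 2 * med
  starts <- hs[-length(hs)][ok]
  lens <- lens[ok]
  if (length(starts) < 3) stop("need at least 3 valid strides")
  d <- ncol(trajectory)
  acc <- matrix(0, n_bins, d)
  ph <- (seq_len(n_bins) - 1) / n_bins
  for (i in seq_along(starts)) {
    at <- starts[i] + ph * lens[i]
    lo <- floor(at); w <- at - lo
    hi <- pmin(lo + 1, nrow(trajectory))
    acc <- acc + (1 - w) * trajectory[lo, , drop = FALSE] +
      w * trajectory[hi, , drop = FALSE]
  }
  loop <- t(acc / length(starts))
  list(loop = loop, n_strides = length(starts),
       n_excluded = sum(!ok))
}

#' Build gait signatures for a set of trials
#'
#' One signature per trial: latent states are extracted with the trained
#' dynamics model, projected onto the retained principal components, and
#' phase-averaged over the gait cycle. The flattened vector (row-major over
#' the loop, i.e. PC-major) is the object that is classified, mapped and
#' compared downstream.
#'
#' @param model trained `gait_dynamics_model`.
#' @param basis `latent_pca` fitted on the cohort's latents.
#' @param trials list of T x C matrices (original units).
#' @param events_list list of `gait_events`, parallel to `trials`.
#' @param n_pcs retained components.
#' @param n_bins phase bins per gait cycle.
#' @param meta optional data.frame (one row per trial) with at least
#'   `trial_id`, `subject_id`, `speed`.
#' @return object of class `signature_set`: `vectors` (N x (n_pcs * n_bins)
#'   matrix), `loops` (list of n_pcs x n_bins matrices), `meta`, `n_pcs`,
#'   `n_bins`.
#' @export
build_signatures <- function(model, basis, trials, events_list, n_pcs,
                             n_bins = 100, meta = NULL) {
  stopifnot(length(trials) == length(events_list))
  if (is.null(meta))
    meta <- data.frame(trial_id = sprintf("trial%03d", seq_along(trials)),
                       subject_id = NA_character_, speed = NA_real_)
  loops <- vector("list", length(trials))
  vecs <- matrix(NA_real_, length(trials), n_pcs * n_bins)
  for (i in seq_along(trials)) {
    sc <- project_latents(basis, extract_latent_states(model, trials[[i]]), n_pcs)
    pa <- phase_average(sc, events_list[[i]], n_bins)
    loops[[i]] <- pa$loop
    vecs[i, ] <- as.vector(t(pa$loop))
  }
  out <- list(vectors = vecs, loops = loops, meta = meta,
              n_pcs = n_pcs, n_bins = n_bins)
  class(out) <- "signature_set"
  out
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d trials, %d PCs x %d phase bins (%d-D vectors)\n",
              nrow(x$vectors), x$n_pcs, x$n_bins, ncol(x$vectors)))
  invisible(x)
}

#' Cumulative variance explained in the original channels per latent PC
#'
#' For each N, every trial's latent states are replaced by their rank-N PCA
#' reconstruction (mean plus top-N components), passed through the model's
#' linear readout, and compared to the measured standardized channels. R^2 is
#' pooled (1 - SSE/SST across all channels and trials, SST about each
#' channel's mean), so the curve at N = K equals the full model's one-step
#' prediction R^2.
#'
#' @param model trained `gait_dynamics_model`.
#' @param basis `latent_pca`.
#' @param trials list of T x C matrices (original units).
#' @param threshold retention threshold on the cumulative curve.
#' @param latents optional list of precomputed `latent_states` (or matrices)
#'   parallel to `trials`, e.g. from an earlier [extract_latent_states()]
#'   pass; avoids re-running the forward pass.
#' @return object of class `variance_curve`: `r2` (length K), `threshold`,
#'   `n_retained`.
#' @export
variance_explained_curve <- function(model, basis, trials, threshold = 0.80,
                                     latents = NULL) {
  K <- ncol(basis$rotation)
  if (!is.null(latents) && length(latents) != length(trials))
    stop("latents must be parallel to trials")
  # y_N = y_mean + scores[,1:N] %*% P[1:N,]  with  P = t(rotation) %*% Wy
  P <- t(basis$rotation) %*% model$Wy
  y_mean <- drop(basis$mean %*% model$Wy) + model$by
  sse <- numeric(K); sst <- 0
  resids <- list(); scores <- list()
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    z <- standardize_seq(model, tr)
    h <- if (is.null(latents)) {
      lstm_forward_cpp(model$Wx, model$Wh, model$b, model$Wy, model$by, z)$h
    } else {
      l <- latents[[i]]
      if (inherits(l, "latent_states")) l$states else l
    }
    tgt <- z[-1, , drop = FALSE]
    resids[[length(resids) + 1]] <- sweep(tgt, 2, y_mean)
    scores[[length(scores) + 1]] <- sweep(h, 2, basis$mean) %*% basis$rotation
  }
  tgt_all <- do.call(rbind, lapply(seq_along(trials), function(i) {
    sweep(resids[[i]], 2, -y_mean)
  }))
  sst <- sum(sweep(tgt_all, 2, colMeans(tgt_all))^2)
  R <- do.call(rbind, resids)          # residual at N = 0
  S <- do.call(rbind, scores)
  for (N in seq_len(K)) {
    R <- R - S[, N] %*% P[N, , drop = FALSE]
    sse[N] <- sum(R^2)
  }
  r2 <- 1 - sse / sst
  out <- list(r2 = r2, threshold = threshold,
              n_retained = select_n_pcs(list(r2 = r2), threshold))
  class(out) <- "variance_curve"
  out
}

#' Smallest number of PCs reaching the retention threshold
#'
#' @param curve a `variance_curve` (or list with element `r2`).
#' @param threshold cumulative R^2 threshold (default 0.80).
#' @return integer count; returns K with a warning if never reached.
#' @export
select_n_pcs <- function(curve, threshold = 0.80) {
  r2 <- curve$r2
  if (!length(r2)) stop("empty curve")
  hit <- which(r2 >= threshold)
  if (!length(hit)) {
    warning("threshold never reached; returning all components")
    return(length(r2))
  }
  hit[1]
}
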