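#' Configuration of the recurrent dynamics model
#'
#' A single-hidden-layer LSTM with a linear readout, trained full-batch (one
#' batch = all trials) with Adam to predict every channel one time step ahead.
#' A dropout layer after the hidden layer and an L2 penalty on the input
#' kernel regularize the fit. Defaults follow common practice for modelling
#' stereotyped cyclic kinematics: 512 units, learning rate 1e-4, 20% dropout,
#' L2 strength 0.01.
#'
#' @param hidden_units number of LSTM units (H).
#' @param learning_rate Adam step size.
#' @param dropout_rate dropout fraction in `[0, 1)` applied to the hidden
#'   state feeding the readout, training only.
#' @param l2_strength L2 penalty weight on the input kernel.
#' @param epochs maximum full-batch epochs.
#' @param patience early-stopping patience (epochs without improvement beyond
#'   `tol`); 0 disables early stopping.
#' @param tol minimum loss improvement counted as progress.
#' @param seed integer seed for weight initialization and dropout masks.
#' @return object of class `rnn_config`.
#' @export
rnn_config <- function(hidden_units = 512, learning_rate = 1e-4,
                       dropout_rate = 0.2, l2_strength = 0.01,
                       epochs = 500, patience = 25, tol = 1e-5, seed = 1L) {
  stopifnot(dropout_rate >= 0, dropout_rate < 1, learning_rate > 0,
            hidden_units >= 1, epochs >= 1)
  cfg <- list(hidden_units = as.integer(hidden_units),
              learning_rate = learning_rate, dropout_rate = dropout_rate,
              l2_strength = l2_strength, epochs = as.integer(epochs),
              patience = as.integer(patience), tol = tol,
              seed = as.integer(seed))
  class(cfg) <- "rnn_config"
  cfg
}

#' Train the gait dynamics model
#'
#' All trials are standardized per channel with pooled cohort statistics
#' (stored with the model so later trials are embedded on the same scale) and
#' fed as one batch; the model minimizes the mean squared one-step-ahead
#' prediction error. Training is deterministic given the config seed.
#'
#' @param trials list of T x C numeric matrices, all with the same dimensions
#'   and channel order.
#' @param config an [rnn_config()].
#' @return object of class `gait_dynamics_model`: weights, standardization
#'   statistics, per-epoch training loss and the config snapshot.
#' @export
train_dynamics_model <- function(trials, config = rnn_config()) {
  stopifnot(inherits(config, "rnn_config"), length(trials) >= 1)
  dims <- vapply(trials, dim, integer(2))
  if (length(unique(dims[2, ])) != 1) stop("all trials must share channel count C")
  if (length(unique(dims[1, ])) != 1)
    stop("all trials must share length T for full-batch training")
  T_ <- dims[1, 1]; C <- dims[2, 1]; B <- length(trials)

  pooled <- do.call(rbind, trials)
  center <- colMeans(pooled)
  scale_ <- apply(pooled, 2, sd)
  scale_[scale_ < 1e-12] <- 1
  X <- array(0, dim = c(T_, C, B))
  for (b in seq_len(B))
    X[, , b] <- sweep(sweep(trials[[b]], 2, center), 2, scale_, "/")

  fit <- lstm_train_cpp(X, config$hidden_units, config$learning_rate,
                        config$dropout_rate, config$l2_strength,
                        config$epochs, config$patience, config$tol,
                        config$seed)
  model <- list(Wx = fit$Wx, Wh = fit$Wh, b = as.numeric(fit$b),
                Wy = fit$Wy, by = as.numeric(fit$by),
                center = center, scale = scale_,
                channel_labels = colnames(trials[[1]]),
                loss_history = fit$loss_history,
                epochs_run = fit$epochs_run,
                config = config, trained = TRUE)
  class(model) <- "gait_dynamics_model"
  model
}

#' @export
print.gait_dynamics_model <- function(x, ...) {
  cat(sprintf("gait_dynamics_model: C = %d channels, H = %d units, %d epochs, final MSE %.3g\n",
              nrow(x$Wx), nrow(x$Wh), x$epochs_run,
              x$loss_history[length(x$loss_history)]))
  invisible(x)
}

standardize_seq <- function(model, sequence) {
  if (ncol(sequence) != nrow(model$Wx))
    stop("sequence channel count does not match the model")
  sweep(sweep(sequence, 2, model$center), 2, model$scale, "/")
}

#' One-step-ahead prediction
#'
#' Row `t` of the output estimates input row `t + 1`. Inference is
#' deterministic (dropout disabled); predictions are returned on the original
#' channel scale.
#'
#' @param model a trained `gait_dynamics_model`.
#' @param sequence T x C matrix in original units.
#' @return (T - 1) x C matrix of predictions.
#' @export
predict_one_step <- function(model, sequence) {
  stopifnot(inherits(model, "gait_dynamics_model"))
  if (is.null(dim(sequence)) || nrow(sequence) < 2) stop("sequence must have >= 2 rows")
  z <- standardize_seq(model, sequence)
  fw <- lstm_forward_cpp(model$Wx, model$Wh, model$b, model$Wy, model$by, z)
  out <- sweep(sweep(fw$y, 2, model$scale, "*"), 2, model$center, "+")
  colnames(out) <- colnames(sequence)
  out
}

#' Extract per-time-step latent states
#'
#' Returns the LSTM hidden state (the layer's output activation) after each
#' input row, computed with dropout disabled; the cell state can be
#' concatenated on request. A pure function of (model parameters, input).
#'
#' @param model a trained `gait_dynamics_model`.
#' @param sequence T x C matrix in original units.
#' @param include_cell also concatenate the cell state (doubling the width).
#' @return object of class `latent_states` with `states` ((T - 1) x H matrix).
#' @export
extract_latent_states <- function(model, sequence, include_cell = FALSE) {
  stopifnot(inherits(model, "gait_dynamics_model"))
  if (!isTRUE(model$trained)) stop("model is not trained")
  z <- standardize_seq(model, sequence)
  fw <- lstm_forward_cpp(model$Wx, model$Wh, model$b, model$Wy, model$by, z)
  states <- if (include_cell) cbind(fw$h, fw$c) else fw$h
  out <- list(states = states,
              which_state = if (include_cell) "hidden+cell" else "hidden")
  class(out) <- "latent_states"
  out
}

# Pooled one-step R^2 of the model on a set of trials, in standardized units;
# SST is taken about each channel's mean over the pooled target rows.
one_step_r2 <- function(model, trials) {
  sse <- 0; targets <- list()
  resid2 <- 0
  for (tr in trials) {
    z <- standardize_seq(model, tr)
    fw <- lstm_forward_cpp(model$Wx, model$Wh, model$b, model$Wy, model$by, z)
    tgt <- z[-1, , drop = FALSE]
    resid2 <- resid2 + sum((fw$y - tgt)^2)
    targets[[length(targets) + 1]] <- tgt
  }
  tgt_all <- do.call(rbind, targets)
  sst <- sum(sweep(tgt_all, 2, colMeans(tgt_all))^2)
  1 - resid2 / sst
}
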