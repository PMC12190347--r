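# Feed-forward maps between cluster expression and mechanistic state.
#
# Architecture: input -> 64 -> 128 -> output, a rectifier after each hidden
# layer, dropout (p = 0.2) after each hidden layer during training only.
# Training minimizes mean squared error with the Adam optimizer on
# per-feature standardized inputs and targets; standardization is inverted
# at prediction. Everything is plain matrix arithmetic, so a fixed seed
# gives bit-identical weights.

#' Specification of a feed-forward map
#'
#' @param input_dim,output_dim layer widths at the two ends.
#' @param hidden_dims hidden layer widths, default `c(64, 128)` (three weight
#'   layers in total).
#' @param dropout_p dropout probability after each hidden layer during
#'   training (default 0.2).
#' @param seed RNG seed for initialization, shuffling and dropout.
#' @param learning_rate Adam step size (default 1e-3).
#' @param epochs training epochs (default 2000).
#' @param batch_size rows per batch; `NULL` (default) trains full-batch.
#' @return A `net_spec` list.
#' @export
net_spec <- function(input_dim, output_dim, hidden_dims = c(64, 128),
                     dropout_p = 0.2, seed = 1, learning_rate = 1e-3,
                     epochs = 2000, batch_size = NULL) {
  if (input_dim < 1 || output_dim < 1 || any(hidden_dims < 1))
    stop("all layer dims must be positive")
  if (dropout_p < 0 || dropout_p >= 1) stop("dropout_p must lie in [0, 1)")
  structure(list(input_dim = as.integer(input_dim),
                 hidden_dims = as.integer(hidden_dims),
                 output_dim = as.integer(output_dim),
                 dropout_p = dropout_p, seed = as.integer(seed),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = batch_size),
            class = "net_spec")
}

#' Number of trainable parameters of a net specification
#'
#' Sum over weight layers of `in * out + out` (weights plus biases).
#'
#' @param spec a [net_spec()].
#' @return Integer parameter count.
#' @export
parameter_count <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  sum(vapply(seq_len(length(dims) - 1),
             function(i) dims[i] * dims[i + 1] + dims[i + 1], 0))
}

# He-uniform initialization
init_layers <- function(spec) {
  dims <- c(spec$input_dim, spec$hidden_dims, spec$output_dim)
  lapply(seq_len(length(dims) - 1), function(i) {
    lim <- sqrt(6 / dims[i])
    list(W = matrix(stats::runif(dims[i] * dims[i + 1], -lim, lim),
                    dims[i], dims[i + 1]),
         b = rep(0, dims[i + 1]))
  })
}

# forward pass; returns activations for backprop. drop_masks NULL = inference
mlp_forward <- function(layers, X, drop_masks = NULL) {
  L <- length(layers)
  acts <- vector("list", L + 1)
  acts[[1]] <- X
  for (i in seq_len(L)) {
    Z <- acts[[i]] %*% layers[[i]]$W +
      matrix(layers[[i]]$b, nrow(X), length(layers[[i]]$b), byrow = TRUE)
    if (i < L) {
      Z[Z < 0] <- 0
      if (!is.null(drop_masks)) Z <- Z * drop_masks[[i]]
    }
    acts[[i + 1]] <- Z
  }
  acts
}

# gradients of mean squared error w.r.t. all weights
mlp_backward <- function(layers, acts, Y, drop_masks = NULL) {
  L <- length(layers)
  n <- nrow(Y)
  grads <- vector("list", L)
  delta <- 2 * (acts[[L + 1]] - Y) / (n * ncol(Y))
  for (i in rev(seq_len(L))) {
    grads[[i]] <- list(W = crossprod(acts[[i]], delta),
                       b = colSums(delta))
    if (i > 1) {
      delta <- delta %*% t(layers[[i]]$W)
      relu_grad <- acts[[i]] > 0
      delta <- delta * relu_grad
      if (!is.null(drop_masks)) delta <- delta * drop_masks[[i - 1]]
    }
  }
  grads
}

mse <- function(a, b) mean((a - b)^2)

standardizer <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}
std_apply <- function(X, s) sweep(sweep(X, 2, s$mu), 2, s$sd, "/")
std_invert <- function(X, s) sweep(sweep(X, 2, s$sd, "*"), 2, s$mu, "+")

#' Build training pairs linking cluster expression and simulated state
#'
#' Forward direction: each usable (patient, time) contributes a row mapping
#' the K-cluster expression vector (optionally with the patient's resection
#' fraction appended) to the 10-component mechanistic state vector of that
#' patient's simulation at the same time. Reverse direction swaps input and
#' target (without the resection feature). A (patient, time) is usable only
#' when every cluster is observed there.
#'
#' @param traj a [cluster_profiles()] result.
#' @param sims named list (by patient id) of [simulate_patient()]
#'   trajectories over the same grid.
#' @param direction `"forward"` or `"reverse"`.
#' @param include_f append the resection fraction to forward inputs
#'   (default `TRUE`).
#' @return A `training_set`: `inputs`, `targets` matrices and `provenance`
#'   data.frame (patient, timepoint).
#' @export
build_training_pairs <- function(traj, sims, direction = c("forward", "reverse"),
                                 include_f = TRUE) {
  direction <- match.arg(direction)
  ins <- list(); tgt <- list(); prov <- list()
  for (p in seq_along(traj$patient_ids)) {
    pid <- traj$patient_ids[p]
    sim <- sims[[pid]]
    if (is.null(sim)) stop("no simulated trajectory for patient ", pid)
    for (tt in seq_along(traj$grid$hours)) {
      if (!all(traj$mask[, p, tt])) next
      cl <- traj$values[, p, tt]
      st <- sim$states[tt, STATE_ORDER]
      row_in <- if (direction == "forward") {
        if (include_f) c(cl, sim$f) else cl
      } else st
      row_tg <- if (direction == "forward") st else cl
      ins[[length(ins) + 1L]] <- row_in
      tgt[[length(tgt) + 1L]] <- row_tg
      prov[[length(prov) + 1L]] <- data.frame(patient = pid,
                                              timepoint = traj$grid$labels[tt])
    }
  }
  if (!length(ins)) stop("zero usable training rows")
  structure(list(inputs = do.call(rbind, ins), targets = do.call(rbind, tgt),
                 provenance = do.call(rbind, prov), direction = direction),
            class = "training_set")
}

#' Train a feed-forward map
#'
#' Minimizes mean squared error with Adam for `spec$epochs` epochs on
#' per-feature standardized data. Dropout is active during training only;
#' the returned map predicts deterministically. The same seed and data give
#' bit-identical weights and loss log.
#'
#' @param set a [build_training_pairs()] result, or any list with `inputs`
#'   and `targets` matrices.
#' @param spec a [net_spec()]; its `input_dim`/`output_dim` must match the
#'   data.
#' @return A `trained_map`: `spec`, `layers` (weights/biases), `norm`
#'   (standardization stats), `training_log` (per-epoch standardized-scale
#'   MSE), `direction`.
#' @export
train_map <- function(set, spec) {
  X <- as.matrix(set$inputs); Y <- as.matrix(set$targets)
  if (nrow(X) == 0) stop("empty training set")
  if (ncol(X) != spec$input_dim || ncol(Y) != spec$output_dim)
    stop(sprintf("data width (%d -> %d) does not match spec (%d -> %d)",
                 ncol(X), ncol(Y), spec$input_dim, spec$output_dim))
  nx <- standardizer(X); ny <- standardizer(Y)
  Xs <- std_apply(X, nx); Ys <- std_apply(Y, ny)
  n <- nrow(Xs)
  bs <- spec$batch_size %||% n
  with_seed(spec$seed, {
    layers <- init_layers(spec)
    L <- length(layers)
    adam <- lapply(layers, function(l)
      list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0))
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; step <- 0
    log <- numeric(spec$epochs)
    keep <- 1 - spec$dropout_p
    for (e in seq_len(spec$epochs)) {
      ord <- if (bs < n) sample.int(n) else seq_len(n)
      epoch_loss <- 0; nb <- 0
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        Xb <- Xs[idx, , drop = FALSE]; Yb <- Ys[idx, , drop = FALSE]
        drop_masks <- if (spec$dropout_p > 0)
          lapply(spec$hidden_dims, function(h)
            matrix(stats::rbinom(length(idx) * h, 1, keep) / keep,
                   length(idx), h))
        else NULL
        acts <- mlp_forward(layers, Xb, drop_masks)
        loss <- mse(acts[[L + 1]], Yb)
        if (!is.finite(loss)) stop(sprintf("non-finite loss at epoch %d", e))
        grads <- mlp_backward(layers, acts, Yb, drop_masks)
        step <- step + 1
        for (i in seq_len(L)) {
          adam[[i]]$mW <- b1 * adam[[i]]$mW + (1 - b1) * grads[[i]]$W
          adam[[i]]$vW <- b2 * adam[[i]]$vW + (1 - b2) * grads[[i]]$W^2
          adam[[i]]$mb <- b1 * adam[[i]]$mb + (1 - b1) * grads[[i]]$b
          adam[[i]]$vb <- b2 * adam[[i]]$vb + (1 - b2) * grads[[i]]$b^2
          mhW <- adam[[i]]$mW / (1 - b1^step); vhW <- adam[[i]]$vW / (1 - b2^step)
          mhb <- adam[[i]]$mb / (1 - b1^step); vhb <- adam[[i]]$vb / (1 - b2^step)
          layers[[i]]$W <- layers[[i]]$W - spec$learning_rate * mhW / (sqrt(vhW) + eps)
          layers[[i]]$b <- layers[[i]]$b - spec$learning_rate * mhb / (sqrt(vhb) + eps)
        }
        epoch_loss <- epoch_loss + loss; nb <- nb + 1
      }
      log[e] <- epoch_loss / nb
    }
    structure(list(spec = spec, layers = layers, norm = list(x = nx, y = ny),
                   training_log = log,
                   direction = set$direction %||% "unspecified"),
              class = "trained_map")
  })
}

#' @export
print.trained_map <- function(x, ...) {
  cat(sprintf("<trained_map> %s: %d -> %s -> %d; final training MSE %.4g\n",
              x$direction, x$spec$input_dim,
              paste(x$spec$hidden_dims, collapse = " -> "),
              x$spec$output_dim, tail(x$training_log, 1)))
  invisible(x)
}

#' Apply a trained map
#'
#' Deterministic forward pass with dropout disabled; standardization applied
#' to the input and inverted on the output.
#'
#' @param map a [train_map()] result.
#' @param x numeric vector of length `input_dim` or a matrix with that many
#'   columns.
#' @return A vector (if `x` was a vector) or matrix of predictions.
#' @export
apply_map <- function(map, x) {
  vec <- is.null(dim(x))
  X <- if (vec) matrix(x, 1) else as.matrix(x)
  if (ncol(X) != map$spec$input_dim)
    stop(sprintf("input width %d does not match spec input_dim %d",
                 ncol(X), map$spec$input_dim))
  acts <- mlp_forward(map$layers, std_apply(X, map$norm$x))
  out <- std_invert(acts[[length(acts)]], map$norm$y)
  if (vec) drop(out) else out
}

#' Training-set mean squared error of a map (standardized scale)
#'
#' @param map a [train_map()] result.
#' @param set a set with `inputs` and `targets`.
#' @return MSE between predictions and targets on the standardized target
#'   scale, matching the training log's units.
#' @export
map_mse <- function(map, set) {
  pred <- apply_map(map, set$inputs)
  mse(std_apply(as.matrix(pred), map$norm$y),
      std_apply(as.matrix(set$targets), map$norm$y))
}
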