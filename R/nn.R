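# Minimal neural-network building blocks shared by the frame detector and
# the segmenter: He initialization, batch normalization, ReLU, fully
# connected layers, softmax, Adam with a stepped learning-rate schedule and
# early stopping. Convolutions and pooling live in src/convops.cpp.
# Feature-map layout everywhere: channel is the second-to-last dimension,
# batch the last.

nn_he <- function(dims, fan_in) {
  array(rnorm(prod(dims), 0, sqrt(2 / fan_in)), dims)
}

bn_new <- function(channels) {
  list(gamma = rep(1, channels), beta = rep(0, channels),
       rm = rep(0, channels), rv = rep(1, channels))
}

# Batch normalization over all dims except the channel one.
bn_forward <- function(x, bn, train, momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  nd <- length(d)
  C <- d[nd - 1]; N <- d[nd]; S <- prod(d[seq_len(nd - 2)])
  x3 <- x; dim(x3) <- c(S, C, N)
  if (train) {
    mu <- apply(x3, 2, mean)
    vr <- apply(x3, 2, function(z) mean(z * z)) - mu^2
    bn$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn$rv <- (1 - momentum) * bn$rv + momentum * vr
  } else {
    mu <- bn$rm; vr <- bn$rv
  }
  istd <- 1 / sqrt(vr + eps)
  ex <- function(v) rep(rep(v, each = S), times = N)
  xhat <- (as.vector(x3) - ex(mu)) * ex(istd)
  y <- ex(bn$gamma) * xhat + ex(bn$beta)
  dim(y) <- d
  list(y = y, bn = bn,
       cache = list(xhat = xhat, istd = istd, S = S, C = C, N = N, d = d))
}

bn_backward <- function(dy, cache, gamma) {
  S <- cache$S; C <- cache$C; N <- cache$N
  m <- S * N
  dyv <- as.vector(dy)
  ex <- function(v) rep(rep(v, each = S), times = N)
  per_channel_sum <- function(v) {
    dim(v) <- c(S, C, N)
    apply(v, 2, sum)
  }
  dbeta <- per_channel_sum(dyv)
  dgamma <- per_channel_sum(dyv * cache$xhat)
  dx <- ex(gamma * cache$istd) *
    (dyv - ex(dbeta / m) - cache$xhat * ex(dgamma / m))
  dim(dx) <- cache$d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) pmax(x, 0)
relu_backward <- function(dy, x) dy * (x > 0)

# Pixel-wise softmax over the channel dimension (2-or-more classes).
softmax_channels <- function(z) {
  d <- dim(z)
  nd <- length(d)
  nc <- d[nd - 1]
  idx <- function(c) {
    ix <- as.list(rep(TRUE, nd)); ix[[nd - 1]] <- c
    do.call(`[`, c(list(z), ix, drop = FALSE))
  }
  mx <- do.call(pmax, lapply(seq_len(nc), idx))
  out <- z
  norm <- array(0, dim(mx))
  slices <- vector("list", nc)
  for (c in seq_len(nc)) {
    slices[[c]] <- exp(idx(c) - mx)
    norm <- norm + slices[[c]]
  }
  for (c in seq_len(nc)) {
    ix <- as.list(rep(TRUE, nd)); ix[[nd - 1]] <- c
    out <- do.call(`[<-`, c(list(out), ix, list(slices[[c]] / norm)))
  }
  out
}

# ---- Adam -----------------------------------------------------------------

adam_new <- function(params) {
  list(t = 0,
       m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' Optimization settings shared by the detector and segmenter trainers:
#' Adam with initial learning rate 0.001, stepped schedule multiplying the
#' rate by `drop_factor` every `drop_period` epochs, at most `max_epochs`
#' epochs, and early stopping once the validation loss has failed to
#' improve for `patience` consecutive epochs (the best-validation weights
#' are kept).
#'
#' @param lr initial learning rate.
#' @param drop_factor multiplicative learning-rate drop.
#' @param drop_period epochs between drops.
#' @param max_epochs maximum number of epochs.
#' @param patience consecutive non-improving validation epochs tolerated.
#' @param batch_size mini-batch size.
#' @param epoch_repeats passes over the training set that constitute one
#'   schedule epoch. The drop period is expressed in epochs; on small
#'   (phantom-scale) training sets a single pass contains far fewer
#'   optimizer steps than at acquisition scale, so one schedule epoch is
#'   allowed to span several passes to keep the step count per
#'   learning-rate stage comparable.
#' @param seed integer seed controlling initialization, shuffling and
#'   dropout.
#' @export
train_config <- function(lr = 0.001, drop_factor = 0.2, drop_period = 5L,
                         max_epochs = 50L, patience = 5L, batch_size = 8L,
                         epoch_repeats = 1L, seed = 1L) {
  assert_that(lr > 0 && drop_factor > 0 && drop_period >= 1 &&
                max_epochs >= 1 && patience >= 1 && batch_size >= 1 &&
                epoch_repeats >= 1,
              "all training parameters must be positive")
  assert_that(patience <= max_epochs, "patience must be <= max_epochs")
  structure(list(lr = lr, drop_factor = drop_factor,
                 drop_period = as.integer(drop_period),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 epoch_repeats = as.integer(epoch_repeats),
                 seed = as.integer(seed)), class = "train_config")
}

#' Learning rate at a given epoch under the stepped schedule
#'
#' @param cfg a [train_config()].
#' @param epoch 1-based epoch number.
#' @return the learning rate used during that epoch.
#' @export
schedule_lr <- function(cfg, epoch) {
  cfg$lr * cfg$drop_factor^((epoch - 1) %/% cfg$drop_period)
}

# Generic epoch loop: `step_fn(idx, lr)` runs one optimizer step on the
# sample indices `idx` and returns the batch loss; `val_fn()` returns the
# validation loss. Early stopping restores the best parameters via
# `get_params`/`set_params` closures.
run_training <- function(n_samples, cfg, step_fn, val_fn,
                         get_params, set_params) {
  history <- data.frame(epoch = integer(), lr = numeric(),
                        train_loss = numeric(), val_loss = numeric())
  best_val <- Inf
  best_params <- get_params()
  wait <- 0L
  reps <- cfg$epoch_repeats %||% 1L
  for (epoch in seq_len(cfg$max_epochs)) {
    lr <- schedule_lr(cfg, epoch)
    order <- as.vector(unlist(lapply(seq_len(reps),
                                     function(i) sample(n_samples))))
    batches <- split(order, ceiling(seq_along(order) / cfg$batch_size))
    losses <- vapply(batches, function(idx) step_fn(idx, lr), numeric(1))
    val_loss <- val_fn()
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, train_loss = mean(losses),
      val_loss = val_loss))
    if (val_loss < best_val - 1e-8) {
      best_val <- val_loss
      best_params <- get_params()
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  set_params(best_params)
  history
}

#' Save and load model checkpoints
#'
#' Stores a trained model with R's native serialization plus a JSON
#' sidecar describing its configuration.
#'
#' @param model a trained detector or segmenter.
#' @param path checkpoint path (`.rds`); the sidecar is written next to it
#'   as `<path>.json`.
#' @return `save_model()` the path invisibly; `load_model()` the model.
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  side <- list(class = class(model)[1], config = unclass(model$config))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, force = TRUE)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
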