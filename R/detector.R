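#' Frame-detector configuration
#'
#' Architecture of the 3D CNN that classifies each frame of a preprocessed
#' pullback as "calcification" or "other" from a 5-frame window. The
#' default mirrors the full-scale network: five convolution blocks
#' (3D convolution, batch normalization, ReLU), kernel `(3, 5, 5)` over
#' (pullback depth, theta, r) with stride 1, each followed by 2 x 2 max
#' pooling over (theta, r) with depth never pooled, then two fully
#' connected layers (1024 units with ReLU and dropout, then a 2-class
#' softmax). The published filter sequence lists four counts (96, 128,
#' 256, 324) for five convolution layers; the fifth layer repeats 324
#' here, and the whole sequence is configurable. Smaller settings are used
#' for desk-scale phantom studies.
#'
#' @param conv_filters integer vector of filters per convolution block.
#' @param kernel length-3 kernel size (depth, theta, r).
#' @param pool pooling window over (theta, r).
#' @param fc1_units width of the first fully connected layer.
#' @param dropout_rate dropout probability after the first FC layer.
#' @param n_classes number of output classes.
#' @export
detector_config <- function(conv_filters = c(96L, 128L, 256L, 324L, 324L),
                            kernel = c(3L, 5L, 5L), pool = 2L,
                            fc1_units = 1024L, dropout_rate = 0.5,
                            n_classes = 2L) {
  assert_that(length(conv_filters) >= 1 && all(conv_filters >= 1),
              "need at least one convolution block")
  assert_that(length(kernel) == 3 && all(kernel >= 1) && all(kernel %% 2 == 1),
              "kernel must be three odd sizes (depth, theta, r)")
  assert_that(dropout_rate >= 0 && dropout_rate < 1, "invalid dropout rate")
  structure(list(conv_filters = as.integer(conv_filters),
                 kernel = as.integer(kernel), pool = as.integer(pool),
                 fc1_units = as.integer(fc1_units),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes)),
            class = "detector_config")
}

#' Build a 5-frame detector input window
#'
#' Extracts the depth-5 window centred on frame `i` (pullback ends
#' replicate the boundary frame), and attaches the parametric theta
#' padding rows: for each depth slice, the top padding row is the last
#' A-line of the preceding frame and the bottom padding row is the first
#' A-line of the following frame; the first frame supplies its own last
#' A-line as top padding and the last frame its own first A-line as
#' bottom padding. Radial padding during convolution is zero.
#'
#' @param stack preprocessed array `(n_frames, n_alines, roi_depth)`.
#' @param i centre frame index.
#' @return array `(5, n_alines + 2, roi_depth)`; rows 2..(n_alines+1) of
#'   depth slice 3 equal frame `i`.
#' @export
build_window <- function(stack, i) {
  d <- dim(stack)
  assert_that(d[1] >= 1, "stack must contain at least one frame")
  assert_that(i >= 1 && i <= d[1], "frame index out of range")
  win <- array(0, c(5L, d[2] + 2L, d[3]))
  depths <- pmin(pmax(i + (-2:2), 1L), d[1])
  for (k in seq_len(5)) {
    j <- depths[k]
    top <- stack[max(j - 1L, 1L), d[2], ]
    bottom <- stack[min(j + 1L, d[1]), 1L, ]
    win[k, 1L, ] <- top
    win[k, 2L:(d[2] + 1L), ] <- stack[j, , ]
    win[k, d[2] + 2L, ] <- bottom
  }
  win
}

detector_init <- function(config, input_dim) {
  k <- config$kernel
  filters <- config$conv_filters
  params <- list()
  cin <- 1L
  h <- input_dim[2]; w <- input_dim[3]
  for (l in seq_along(filters)) {
    fan_in <- prod(k) * cin
    params[[paste0("conv", l, "_w")]] <-
      nn_he(c(k[1], k[2], k[3], cin, filters[l]), fan_in)
    params[[paste0("conv", l, "_b")]] <- rep(0, filters[l])
    params[[paste0("bn", l, "_gamma")]] <- rep(1, filters[l])
    params[[paste0("bn", l, "_beta")]] <- rep(0, filters[l])
    cin <- filters[l]
    h <- h %/% config$pool; w <- w %/% config$pool
  }
  flat <- input_dim[1] * h * w * cin
  params$fc1_w <- nn_he(c(config$fc1_units, flat), flat)
  params$fc1_b <- rep(0, config$fc1_units)
  params$fc2_w <- nn_he(c(config$n_classes, config$fc1_units),
                        config$fc1_units)
  params$fc2_b <- rep(0, config$n_classes)
  running <- lapply(filters, function(f) list(rm = rep(0, f), rv = rep(1, f)))
  structure(list(config = config, params = params, running = running,
                 input_dim = input_dim, flat = flat),
            class = "oct_detector")
}

#' @export
print.oct_detector <- function(x, ...) {
  cat(sprintf(
    "oct_detector: %d conv blocks (%s filters), kernel %s, fc %d -> %d, input (%s)\n",
    length(x$config$conv_filters),
    paste(x$config$conv_filters, collapse = "/"),
    paste(x$config$kernel, collapse = "x"),
    x$config$fc1_units, x$config$n_classes,
    paste(x$input_dim, collapse = ", ")))
  invisible(x)
}

detector_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  L <- length(cfg$conv_filters)
  p <- model$params
  caches <- vector("list", L)
  a <- x
  for (l in seq_len(L)) {
    z <- conv3d_fwd(a, p[[paste0("conv", l, "_w")]],
                    p[[paste0("conv", l, "_b")]])
    bnp <- list(gamma = p[[paste0("bn", l, "_gamma")]],
                beta = p[[paste0("bn", l, "_beta")]],
                rm = model$running[[l]]$rm, rv = model$running[[l]]$rv)
    bnf <- bn_forward(z, bnp, train)
    if (train) model$running[[l]] <- list(rm = bnf$bn$rm, rv = bnf$bn$rv)
    r <- relu_forward(bnf$y)
    pl <- maxpool3d_hw_fwd(r, cfg$pool)
    caches[[l]] <- list(a = a, z = z, bn_cache = bnf$cache, bn_y = bnf$y,
                        idx = pl$idx, pre_dim = dim(r))
    a <- pl$y
  }
  pooled_dim <- dim(a)
  N <- pooled_dim[length(pooled_dim)]
  xf <- a; dim(xf) <- c(model$flat, N)
  z1 <- p$fc1_w %*% xf + p$fc1_b
  r1 <- pmax(z1, 0)
  if (train && cfg$dropout_rate > 0) {
    keep <- (runif(length(r1)) >= cfg$dropout_rate) / (1 - cfg$dropout_rate)
    dim(keep) <- dim(r1)
    r1d <- r1 * keep
  } else {
    keep <- NULL
    r1d <- r1
  }
  logits <- p$fc2_w %*% r1d + p$fc2_b
  probs <- softmax_cols(logits)
  list(probs = probs, model = model,
       cache = list(caches = caches, xf = xf, z1 = z1, r1 = r1,
                    r1d = r1d, keep = keep, pooled_dim = pooled_dim))
}

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), `/`)
}

# Cross-entropy backward through the detector; dlogits (C, N).
detector_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  grads$fc2_w <- dlogits %*% t(cache$r1d)
  grads$fc2_b <- rowSums(dlogits)
  dr1d <- t(p$fc2_w) %*% dlogits
  if (!is.null(cache$keep)) dr1d <- dr1d * cache$keep
  dz1 <- dr1d * (cache$z1 > 0)
  grads$fc1_w <- dz1 %*% t(cache$xf)
  grads$fc1_b <- rowSums(dz1)
  da <- t(p$fc1_w) %*% dz1
  dim(da) <- cache$pooled_dim
  L <- length(cfg$conv_filters)
  for (l in rev(seq_len(L))) {
    cc <- cache$caches[[l]]
    dr <- array(0, cc$pre_dim)
    dr[as.vector(cc$idx) + 1] <- as.vector(da)      # unpool the gradient
    dbn_y <- relu_backward(dr, cc$bn_y)
    bnb <- bn_backward(dbn_y, cc$bn_cache, p[[paste0("bn", l, "_gamma")]])
    grads[[paste0("bn", l, "_gamma")]] <- bnb$dgamma
    grads[[paste0("bn", l, "_beta")]] <- bnb$dbeta
    cb <- conv3d_bwd(cc$a, p[[paste0("conv", l, "_w")]], bnb$dx)
    grads[[paste0("conv", l, "_w")]] <- cb$dw
    grads[[paste0("conv", l, "_b")]] <- cb$db
    da <- cb$dx
  }
  grads
}

ce_loss_grad <- function(probs, targets) {
  # targets: integer vector in 1..C; probs (C, N)
  N <- ncol(probs)
  idx <- cbind(targets, seq_len(N))
  pt <- pmax(probs[cbind(targets, seq_len(N))], 1e-12)
  loss <- mean(-log(pt))
  onehot <- matrix(0, nrow(probs), N)
  onehot[cbind(targets, seq_len(N))] <- 1
  list(loss = loss, dlogits = (probs - onehot) / N)
}

#' Train the frame detector
#'
#' Trains the 3D CNN on preprocessed pullback stacks with per-frame
#' binary labels, using Adam under the stepped learning-rate schedule and
#' early stopping of [train_config()]. All randomness (weight
#' initialization, shuffling, dropout) is driven by the config seed.
#'
#' @param stacks list of preprocessed arrays `(n_frames, n_alines,
#'   roi_depth)` used for training.
#' @param labels list of binary per-frame label vectors (1 =
#'   calcification), aligned with `stacks`.
#' @param val_stacks,val_labels validation pullbacks in the same format.
#' @param config a [detector_config()].
#' @param train_cfg a [train_config()].
#' @param augment apply random circular theta rolls to training windows
#'   (the vessel wall is rotationally symmetric, so a lesion is equally
#'   plausible at any angle); padding rows are rebuilt after the roll.
#' @return an `oct_detector` model with a `history` data.frame of
#'   per-epoch learning rates and train/validation losses.
#' @export
train_detector <- function(stacks, labels, val_stacks, val_labels,
                           config = detector_config(),
                           train_cfg = train_config(),
                           augment = TRUE) {
  all_lab <- unlist(labels)
  assert_that(length(unique(all_lab)) == 2,
              "training labels must contain both classes")
  tr <- collect_windows(stacks, labels)
  va <- collect_windows(val_stacks, val_labels)
  with_seed(train_cfg$seed, {
    model <- detector_init(config, dim(tr$x)[1:3])
    state <- adam_new(model$params)
    step_fn <- function(idx, lr) {
      x <- tr$x[, , , , idx, drop = FALSE]
      if (augment) {
        theta <- dim(x)[2] - 2L
        for (k in seq_along(idx))
          x[, , , 1L, k] <- roll_window(x[, , , 1L, k],
                                        sample(0:(theta - 1L), 1))
      }
      fw <- detector_forward(model, x, train = TRUE)
      model$running <<- fw$model$running
      lg <- ce_loss_grad(fw$probs, tr$y[idx])
      grads <- detector_backward(model, fw$cache, lg$dlogits)
      upd <- adam_step(model$params, grads, state, lr)
      model$params <<- upd$params
      state <<- upd$state
      lg$loss
    }
    val_fn <- function() {
      fw <- detector_forward(model, va$x, train = FALSE)
      ce_loss_grad(fw$probs, va$y)$loss
    }
    history <- run_training(
      length(tr$y), train_cfg, step_fn, val_fn,
      get_params = function() model$params,
      set_params = function(p) model$params <<- p)
    model$history <- history
    model
  })
}

# Circularly roll the theta axis of a (5, theta+2, r) window by k
# A-lines and rebuild the parametric padding rows from the rolled slices.
roll_window <- function(win, k) {
  d <- dim(win)
  theta <- d[2] - 2L
  if (k %% theta == 0) return(win)
  perm <- ((seq_len(theta) - 1L - k) %% theta) + 1L
  inner <- win[, 1L + seq_len(theta), , drop = FALSE][, perm, , drop = FALSE]
  out <- win
  out[, 1L + seq_len(theta), ] <- inner
  for (s in seq_len(d[1])) {
    out[s, 1L, ] <- inner[max(s - 1L, 1L), theta, ]
    out[s, d[2], ] <- inner[min(s + 1L, d[1]), 1L, ]
  }
  out
}

# Assemble all 5-frame windows of a list of stacks into one batch array
# (5, theta+2, r, 1, n) plus the label vector as class indices.
collect_windows <- function(stacks, labels) {
  xs <- list(); ys <- integer(0)
  for (s in seq_along(stacks)) {
    st <- stacks[[s]]
    for (f in seq_len(dim(st)[1])) xs[[length(xs) + 1]] <- build_window(st, f)
    ys <- c(ys, as.integer(labels[[s]]) + 1L)   # 1 = other, 2 = calcification
  }
  d <- dim(xs[[1]])
  x <- array(0, c(d, 1L, length(xs)))
  for (i in seq_along(xs)) x[, , , 1L, i] <- xs[[i]]
  list(x = x, y = ys)
}

#' Classify every frame of a preprocessed pullback
#'
#' Runs the trained detector over all 5-frame windows of a stack in
#' inference mode (running batch-norm statistics, no dropout), which is
#' deterministic.
#'
#' @param stack preprocessed array `(n_frames, n_alines, roi_depth)`.
#' @param model a trained `oct_detector`.
#' @param batch_size inference batch size.
#' @return list with `labels` (binary vector, 1 = calcification; argmax
#'   ties resolve to "other") and `probabilities` (matrix `n_frames x 2`,
#'   rows sum to 1).
#' @export
classify_frames <- function(stack, model, batch_size = 16L) {
  d <- dim(stack)
  expect <- model$input_dim
  assert_that(all(d[2:3] + c(2L, 0L) == expect[2:3]),
              sprintf("stack dims (%d, %d) do not match model input (theta %d - 2, r %d)",
                      d[2], d[3], expect[2], expect[3]))
  n <- d[1]
  probs <- matrix(0, n, model$config$n_classes)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    x <- array(0, c(expect, 1L, length(idx)))
    for (k in seq_along(idx)) x[, , , 1L, k] <- build_window(stack, idx[k])
    fw <- detector_forward(model, x, train = FALSE)
    probs[idx, ] <- t(fw$probs)
  }
  list(labels = as.integer(probs[, 2] > probs[, 1]), probabilities = probs)
}

#' @export
predict.oct_detector <- function(object, stack, ...) {
  classify_frames(stack, object, ...)
}
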