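#' Segmenter configuration
#'
#' Architecture and loss of the encoder-decoder pixel classifier. The
#' encoder default is the VGG-16 convolution arrangement -- stages
#' (64,64), (128,128), (256,256,256), (512,512,512), (512,512,512), each
#' convolution 3 x 3 with batch normalization and ReLU, each stage ending
#' in a 2 x 2 stride-2 max pool whose argmax indices are stored. The
#' decoder mirrors the encoder, upsampling with max-unpooling through the
#' stored indices of the counterpart encoder stage, and a 1 x 1
#' convolution with softmax produces per-pixel class probabilities (13 +
#' 13 = 26 convolutions, 5 pools, 5 unpools at the default). Theta is
#' padded circularly during convolution (the vessel wall is a cylinder);
#' r is zero-padded. Smaller stage lists are used for desk-scale phantom
#' studies.
#'
#' @param stages list of integer vectors: filters of each convolution in
#'   each encoder stage.
#' @param loss `"tversky"`, `"dice"` or `"wce"`.
#' @param tversky_alpha,tversky_beta false-negative and false-positive
#'   weights of the Tversky index (defaults 0.7 / 0.3, emphasizing
#'   recall).
#' @param n_classes number of classes (calcification is the last).
#' @param theta_circular pad theta circularly during convolution.
#' @export
segmenter_config <- function(stages = list(c(64L, 64L), c(128L, 128L),
                                           c(256L, 256L, 256L),
                                           c(512L, 512L, 512L),
                                           c(512L, 512L, 512L)),
                             loss = c("tversky", "dice", "wce"),
                             tversky_alpha = 0.7, tversky_beta = 0.3,
                             n_classes = 2L, theta_circular = TRUE) {
  loss <- match.arg(loss)
  assert_that(length(stages) >= 1 && all(vapply(stages, length, 1L) >= 1),
              "stages must be a nonempty list of filter vectors")
  assert_that(tversky_alpha > 0 && tversky_beta > 0,
              "tversky alpha and beta must be > 0")
  structure(list(stages = lapply(stages, as.integer), loss = loss,
                 tversky_alpha = tversky_alpha, tversky_beta = tversky_beta,
                 n_classes = as.integer(n_classes),
                 theta_circular = isTRUE(theta_circular)),
            class = "segmenter_config")
}

#' Inverse-median-frequency class weights
#'
#' `weight_c = median(freq) / freq_c`, where `freq_c` is the pixel count
#' of class `c` divided by the total pixel count of the frames in which
#' class `c` appears. Rarer classes therefore receive larger weights.
#'
#' @param masks binary array `(n_frames, n_alines, roi_depth)`; class 1 is
#'   "other" (0 pixels) and class 2 "calcification" (1 pixels).
#' @return numeric vector of per-class weights `(other, calcification)`.
#' @export
median_freq_weights <- function(masks) {
  d <- dim(masks)
  per_frame <- apply(masks > 0, 1, sum)
  frame_px <- prod(d[2:3])
  freqs <- vapply(1:2, function(cls) {
    counts <- if (cls == 2) per_frame else frame_px - per_frame
    present <- counts > 0
    assert_that(any(present),
                sprintf("class %d absent from every frame", cls))
    sum(counts[present]) / (sum(present) * frame_px)
  }, numeric(1))
  median(freqs) / freqs
}

#' Weighted cross-entropy loss
#'
#' Mean over pixels of `-weight[target] * log(prob[target])`, with the
#' log clamped at `eps`.
#'
#' @param probs matrix `(n_pixels, n_classes)` of valid class
#'   probabilities.
#' @param targets integer vector of 1-based target classes.
#' @param weights per-class weights.
#' @param eps clamp for the logarithm.
#' @return scalar loss, >= 0.
#' @export
wce_loss <- function(probs, targets, weights = rep(1, ncol(probs)),
                     eps = 1e-12) {
  assert_that(nrow(probs) == length(targets), "shape mismatch")
  assert_that(all(is.finite(probs)) && min(probs) >= 0 && max(probs) <= 1,
              "invalid probabilities")
  pt <- pmax(probs[cbind(seq_along(targets), targets)], eps)
  mean(-weights[targets] * log(pt))
}

# Soft confusion counts of the foreground class.
soft_counts <- function(probs, targets) {
  p <- as.numeric(probs); t <- as.numeric(targets)
  assert_that(length(p) == length(t), "shape mismatch")
  list(tp = sum(p * t), fn = sum((1 - p) * t), fp = sum(p * (1 - t)))
}

#' Tversky and Dice losses on soft counts
#'
#' `tversky_loss()` is `1 - (TP + s) / (TP + alpha FN + beta FP + s)` on
#' probabilistic (soft) counts of the calcification class;
#' `dice_loss()` is `1 - (2 TP + 2 s) / (2 TP + FP + FN + 2 s)`. With
#' `alpha = beta = 0.5` the Tversky loss reduces exactly to the Dice
#' loss; both are 0 for a perfect prediction and 1 for a completely
#' disjoint hard prediction (up to the smoothing term `s`).
#'
#' @param probs array of foreground (calcification) probabilities.
#' @param targets binary array of the same shape.
#' @param alpha,beta Tversky false-negative / false-positive weights.
#' @param smooth smoothing term protecting empty masks.
#' @return scalar loss in `[0, 1]`.
#' @export
tversky_loss <- function(probs, targets, alpha = 0.7, beta = 0.3,
                         smooth = 1e-6) {
  assert_that(alpha > 0 && beta > 0, "alpha and beta must be > 0")
  sc <- soft_counts(probs, targets)
  1 - (sc$tp + smooth) / (sc$tp + alpha * sc$fn + beta * sc$fp + smooth)
}

#' @rdname tversky_loss
#' @export
dice_loss <- function(probs, targets, smooth = 1e-6) {
  sc <- soft_counts(probs, targets)
  1 - (2 * sc$tp + 2 * smooth) / (2 * sc$tp + sc$fp + sc$fn + 2 * smooth)
}

# ---- network --------------------------------------------------------------

segnet_init <- function(config, in_channels = 1L) {
  stages <- config$stages
  S <- length(stages)
  params <- list()
  running <- list()
  cin <- in_channels
  enc_in <- integer(S)
  for (s in seq_len(S)) {
    enc_in[s] <- cin
    for (j in seq_along(stages[[s]])) {
      co <- stages[[s]][j]
      nm <- sprintf("enc%d_%d", s, j)
      params[[paste0(nm, "_w")]] <- nn_he(c(3, 3, cin, co), 9 * cin)
      params[[paste0(nm, "_b")]] <- rep(0, co)
      params[[paste0(nm, "_gamma")]] <- rep(1, co)
      params[[paste0(nm, "_beta")]] <- rep(0, co)
      running[[nm]] <- list(rm = rep(0, co), rv = rep(1, co))
      cin <- co
    }
  }
  for (s in rev(seq_len(S))) {
    outs <- rev(stages[[s]])
    outs <- c(outs[-1], if (s > 1) enc_in[s] else stages[[1]][1])
    for (j in seq_along(outs)) {
      co <- outs[j]
      nm <- sprintf("dec%d_%d", s, j)
      params[[paste0(nm, "_w")]] <- nn_he(c(3, 3, cin, co), 9 * cin)
      params[[paste0(nm, "_b")]] <- rep(0, co)
      params[[paste0(nm, "_gamma")]] <- rep(1, co)
      params[[paste0(nm, "_beta")]] <- rep(0, co)
      running[[nm]] <- list(rm = rep(0, co), rv = rep(1, co))
      cin <- co
    }
  }
  params$head_w <- nn_he(c(1, 1, cin, config$n_classes), cin)
  params$head_b <- rep(0, config$n_classes)
  structure(list(config = config, params = params, running = running),
            class = "oct_segmenter")
}

#' @export
print.oct_segmenter <- function(x, ...) {
  n_conv <- 2 * sum(lengths(x$config$stages))
  cat(sprintf(
    "oct_segmenter: %d conv layers, %d pool/unpool stages (%s), loss %s\n",
    n_conv, length(x$config$stages),
    paste(vapply(x$config$stages, function(s) paste(s, collapse = ","), ""),
          collapse = " | "),
    x$config$loss))
  invisible(x)
}

# One conv + BN + ReLU block; returns output, cache and updated running.
segnet_block_fwd <- function(model, nm, a, train) {
  p <- model$params
  z <- conv2d_fwd(a, p[[paste0(nm, "_w")]], p[[paste0(nm, "_b")]],
                  model$config$theta_circular)
  bnp <- list(gamma = p[[paste0(nm, "_gamma")]],
              beta = p[[paste0(nm, "_beta")]],
              rm = model$running[[nm]]$rm, rv = model$running[[nm]]$rv)
  bnf <- bn_forward(z, bnp, train)
  r <- relu_forward(bnf$y)
  list(y = r, running = list(rm = bnf$bn$rm, rv = bnf$bn$rv),
       cache = list(nm = nm, a = a, bn_cache = bnf$cache, bn_y = bnf$y))
}

segnet_block_bwd <- function(model, cache, dy, grads) {
  p <- model$params
  nm <- cache$nm
  dbn_y <- relu_backward(dy, cache$bn_y)
  bnb <- bn_backward(dbn_y, cache$bn_cache, p[[paste0(nm, "_gamma")]])
  grads[[paste0(nm, "_gamma")]] <- bnb$dgamma
  grads[[paste0(nm, "_beta")]] <- bnb$dbeta
  cb <- conv2d_bwd(cache$a, p[[paste0(nm, "_w")]], bnb$dx,
                   model$config$theta_circular)
  grads[[paste0(nm, "_w")]] <- cb$dw
  grads[[paste0(nm, "_b")]] <- cb$db
  list(dx = cb$dx, grads = grads)
}

segnet_forward <- function(model, x, train = FALSE) {
  cfg <- model$config
  S <- length(cfg$stages)
  blocks <- list()
  pools <- vector("list", S)
  a <- x
  for (s in seq_len(S)) {
    for (j in seq_along(cfg$stages[[s]])) {
      bf <- segnet_block_fwd(model, sprintf("enc%d_%d", s, j), a, train)
      if (train) model$running[[bf$cache$nm]] <- bf$running
      blocks[[bf$cache$nm]] <- bf$cache
      a <- bf$y
    }
    pl <- maxpool2d_fwd(a, 2L)
    pools[[s]] <- list(idx = pl$idx, pre_dim = dim(a))
    a <- pl$y
  }
  dec_names <- character(0)
  for (s in rev(seq_len(S))) {
    up <- array(0, pools[[s]]$pre_dim)
    up[as.vector(pools[[s]]$idx) + 1] <- as.vector(a)   # max-unpool
    a <- up
    n_dec <- length(cfg$stages[[s]])
    for (j in seq_len(n_dec)) {
      bf <- segnet_block_fwd(model, sprintf("dec%d_%d", s, j), a, train)
      if (train) model$running[[bf$cache$nm]] <- bf$running
      blocks[[bf$cache$nm]] <- bf$cache
      dec_names <- c(dec_names, bf$cache$nm)
      a <- bf$y
    }
  }
  logits <- conv2d_fwd(a, model$params$head_w, model$params$head_b, FALSE)
  probs <- softmax_channels(logits)
  list(probs = probs, model = model,
       cache = list(blocks = blocks, pools = pools, head_in = a,
                    logits = logits))
}

segnet_backward <- function(model, cache, dlogits) {
  cfg <- model$config
  S <- length(cfg$stages)
  grads <- list()
  cb <- conv2d_bwd(cache$head_in, model$params$head_w, dlogits, FALSE)
  grads$head_w <- cb$dw
  grads$head_b <- cb$db
  da <- cb$dx
  # decoder ran s = S..1 forward, so backward visits s = 1..S; the
  # gradient passes through each max-unpool by gathering at the stored
  # indices.
  for (s in seq_len(S)) {
    for (j in rev(seq_along(cfg$stages[[s]]))) {
      bb <- segnet_block_bwd(model, cache$blocks[[sprintf("dec%d_%d", s, j)]],
                             da, grads)
      grads <- bb$grads
      da <- bb$dx
    }
    da <- array(as.vector(da)[as.vector(cache$pools[[s]]$idx) + 1],
                dim(cache$pools[[s]]$idx))     # through unpool: gather
  }
  # encoder backward, s = S..1; each max-pool scatters the gradient back
  # to the argmax positions.
  for (s in rev(seq_len(S))) {
    dpre <- array(0, cache$pools[[s]]$pre_dim)
    dpre[as.vector(cache$pools[[s]]$idx) + 1] <- as.vector(da)
    da <- dpre
    for (j in rev(seq_along(cfg$stages[[s]]))) {
      bb <- segnet_block_bwd(model, cache$blocks[[sprintf("enc%d_%d", s, j)]],
                             da, grads)
      grads <- bb$grads
      da <- bb$dx
    }
  }
  grads
}

#' Train the segmenter
#'
#' Trains the encoder-decoder on aligned frames with per-pixel binary
#' masks, using the configured loss (inverse-median-frequency class
#' weights are computed from the training masks when the loss is WCE),
#' Adam under the stepped learning-rate schedule and early stopping. By
#' default every training frame must contain at least one calcification
#' pixel (lesion-only training, the second step of the two-step
#' approach); `allow_empty = TRUE` switches to all-frame training for
#' one-step comparisons. An optional layerwise fine-tuning mode unfreezes
#' one convolution block per epoch starting from the last (head) layer
#' backward.
#'
#' @param frames array `(n, n_alines, roi_depth)` of preprocessed frames.
#' @param masks binary array of the same shape.
#' @param val_frames,val_masks validation split in the same format.
#' @param config a [segmenter_config()].
#' @param train_cfg a [train_config()].
#' @param allow_empty allow frames with no positive pixel in training.
#' @param finetune_layerwise unfreeze blocks gradually from the output
#'   end.
#' @param augment apply random circular theta rolls to training frames
#'   and masks (rotational symmetry of the vessel wall).
#' @param init_params optional named list of parameter arrays (matching
#'   the names and shapes of a freshly initialized model) used to seed
#'   training, e.g. externally converted pretrained encoder weights;
#'   unnamed parameters keep their random initialization.
#' @return an `oct_segmenter` with a `history` data.frame; `weights`
#'   holds the class weights when WCE is used.
#' @export
train_segmenter <- function(frames, masks, val_frames, val_masks,
                            config = segmenter_config(),
                            train_cfg = train_config(),
                            allow_empty = FALSE,
                            finetune_layerwise = FALSE,
                            augment = TRUE, init_params = NULL) {
  n <- dim(frames)[1]
  pos <- vapply(seq_len(n), function(i) any(masks[i, , ] > 0), logical(1))
  if (!allow_empty && any(!pos))
    stop("training frames without calcification pixels at indices: ",
         paste(which(!pos), collapse = ", "), call. = FALSE)
  weights <- if (config$loss == "wce") median_freq_weights(masks) else NULL
  with_seed(train_cfg$seed, {
    model <- segnet_init(config)
    if (!is.null(init_params))
      for (nm in intersect(names(init_params), names(model$params))) {
        assert_that(length(init_params[[nm]]) == length(model$params[[nm]]),
                    sprintf("init_params[['%s']] has the wrong shape", nm))
        model$params[[nm]] <- init_params[[nm]]
      }
    state <- adam_new(model$params)
    param_order <- segnet_param_blocks(model)
    step <- 0L
    epoch_counter <- 0L
    step_fn <- function(idx, lr) {
      x <- frames_to_batch(frames, idx)
      t <- masks_to_batch(masks, idx)
      if (augment) {
        theta <- dim(x)[1]
        for (k in seq_along(idx)) {
          perm <- ((seq_len(theta) - 1L -
                      sample(0:(theta - 1L), 1)) %% theta) + 1L
          x[, , 1L, k] <- x[perm, , 1L, k]
          t[, , k] <- t[perm, , k]
        }
      }
      fw <- segnet_forward(model, x, train = TRUE)
      model$running <<- fw$model$running
      lg <- segment_loss_grad(fw$probs, t, config, weights)
      grads <- segnet_backward(model, fw$cache, lg$dlogits)
      if (finetune_layerwise) {
        open_blocks <- utils::head(param_order,
                                   max(1L, ceiling(step / 3) + 1L))
        keep <- unlist(lapply(open_blocks, function(b) b))
        for (nm in names(grads)) if (!(nm %in% keep)) grads[[nm]] <- NULL
      }
      step <<- step + 1L
      upd <- adam_step(model$params, grads, state, lr)
      model$params <<- upd$params
      state <<- upd$state
      lg$loss
    }
    val_fn <- function() {
      tot <- 0
      nb <- 0
      for (start in seq(1, dim(val_frames)[1], by = train_cfg$batch_size)) {
        idx <- start:min(start + train_cfg$batch_size - 1, dim(val_frames)[1])
        fw <- segnet_forward(model, frames_to_batch(val_frames, idx),
                             train = FALSE)
        tot <- tot + segment_loss_grad(fw$probs,
                                       masks_to_batch(val_masks, idx),
                                       config, weights)$loss * length(idx)
        nb <- nb + length(idx)
      }
      tot / nb
    }
    history <- run_training(
      n, train_cfg, step_fn, val_fn,
      get_params = function() model$params,
      set_params = function(p) model$params <<- p)
    model$history <- history
    model$weights <- weights
    model
  })
}

# Parameter names grouped by block, ordered from the output backward
# (for layerwise fine-tuning).
segnet_param_blocks <- function(model) {
  nms <- names(model$params)
  blocks <- unique(sub("_(w|b|gamma|beta)$", "", nms))
  blocks <- rev(blocks)                        # head first, enc1_1 last
  lapply(blocks, function(b) nms[startsWith(nms, paste0(b, "_"))])
}

frames_to_batch <- function(frames, idx) {
  d <- dim(frames)
  x <- array(0, c(d[2], d[3], 1L, length(idx)))
  for (k in seq_along(idx)) x[, , 1L, k] <- frames[idx[k], , ]
  x
}

masks_to_batch <- function(masks, idx) {
  d <- dim(masks)
  t <- array(0, c(d[2], d[3], length(idx)))
  for (k in seq_along(idx)) t[, , k] <- masks[idx[k], , ]
  t
}

# Loss and gradient w.r.t. the head logits for a batch.
# probs (H, W, C, N); targets (H, W, N) binary, class C = calcification.
segment_loss_grad <- function(probs, targets, config, weights = NULL) {
  d <- dim(probs)
  nc <- d[3]
  p2 <- probs[, , nc, , drop = FALSE]
  dim(p2) <- d[c(1, 2, 4)]
  if (config$loss == "wce") {
    w <- if (is.null(weights)) rep(1, nc) else weights
    npx <- prod(d[c(1, 2, 4)])
    tcls <- as.numeric(targets)                # 0/1
    pm <- cbind(1 - as.numeric(p2), as.numeric(p2))
    tgt <- tcls + 1
    loss <- wce_loss(pm, tgt, w)
    wt <- w[tgt]
    dlogits <- array(0, d)
    d2 <- wt * (pm[, 2] - tcls) / npx
    dlogits[, , 2, ] <- array(d2, d[c(1, 2, 4)])
    dlogits[, , 1, ] <- array(wt * (pm[, 1] - (1 - tcls)) / npx,
                              d[c(1, 2, 4)])
    return(list(loss = loss, dlogits = dlogits))
  }
  alpha <- if (config$loss == "dice") 0.5 else config$tversky_alpha
  beta <- if (config$loss == "dice") 0.5 else config$tversky_beta
  smooth <- 1e-6
  sc <- soft_counts(p2, targets)
  den <- sc$tp + alpha * sc$fn + beta * sc$fp + smooth
  loss <- 1 - (sc$tp + smooth) / den
  t <- as.numeric(targets)
  pv <- as.numeric(p2)
  dnum <- t
  dden <- t - alpha * t + beta * (1 - t)
  dTI <- (dnum * den - (sc$tp + smooth) * dden) / den^2
  g2 <- -dTI                                   # dL/dp2
  dz2 <- g2 * pv * (1 - pv)
  dlogits <- array(0, d)
  dlogits[, , nc, ] <- array(dz2, d[c(1, 2, 4)])
  dlogits[, , 1, ] <- array(-dz2, d[c(1, 2, 4)])
  list(loss = loss, dlogits = dlogits)
}

#' Segment the frames inside lesion intervals
#'
#' Runs the trained segmenter in inference mode over exactly the frames
#' covered by the lesion intervals and returns their per-pixel class
#' probabilities.
#'
#' @param stack preprocessed array `(n_frames, n_alines, roi_depth)`.
#' @param model a trained `oct_segmenter`.
#' @param intervals data.frame of lesion intervals; frames outside them
#'   are not processed.
#' @param batch_size inference batch size.
#' @return list with `frames` (processed frame indices) and `probs`
#'   (array `(n_sel, n_alines, roi_depth, n_classes)`; per-pixel sums are
#'   1 within 1e-6).
#' @export
segment_frames <- function(stack, model, intervals = NULL,
                           batch_size = 8L) {
  d <- dim(stack)
  sel <- if (is.null(intervals)) seq_len(d[1]) else interval_frames(intervals)
  nc <- model$config$n_classes
  probs <- array(0, c(length(sel), d[2], d[3], nc))
  if (!length(sel)) return(list(frames = integer(0), probs = probs))
  for (start in seq(1, length(sel), by = batch_size)) {
    ii <- start:min(start + batch_size - 1, length(sel))
    fw <- segnet_forward(model, frames_to_batch(stack, sel[ii]),
                         train = FALSE)
    for (k in seq_along(ii)) probs[ii[k], , , ] <- fw$probs[, , , k]
  }
  list(frames = sel, probs = probs)
}

#' @export
predict.oct_segmenter <- function(object, stack, intervals = NULL, ...) {
  segment_frames(stack, object, intervals, ...)
}
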