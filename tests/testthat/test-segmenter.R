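test_that("inverse-median-frequency weights match hand arithmetic", {
  # 90% / 10% class split present in every frame
  masks <- array(0L, c(4, 10, 10))
  masks[, , 1] <- 1L                       # 10 of 100 pixels per frame
  w <- median_freq_weights(masks)
  expect_equal(w, c(0.5 / 0.9, 0.5 / 0.1), tolerance = 1e-6)

  # balanced classes get unit weights
  bal <- array(0L, c(2, 4, 4)); bal[, 1:2, ] <- 1L
  expect_equal(median_freq_weights(bal), c(1, 1))

  # the rarer class always gets the larger weight
  set.seed(4)
  for (rep in 1:10) {
    m <- array(as.integer(runif(3 * 8 * 8) < runif(1, 0.05, 0.45)),
               c(3, 8, 8))
    if (!any(m > 0) || all(m > 0)) next
    w <- median_freq_weights(m)
    expect_gt(w[2], w[1])
  }
  expect_error(median_freq_weights(array(0L, c(2, 4, 4))), "absent")
})

test_that("weighted cross-entropy has its closed forms", {
  # one-hot prediction: zero loss up to the clamp
  probs <- rbind(c(1, 0), c(0, 1))
  expect_equal(wce_loss(probs, c(1L, 2L)), 0, tolerance = 1e-10)
  # uniform prediction, equal weights: ln 2 per pixel
  unif <- matrix(0.5, 7, 2)
  expect_equal(wce_loss(unif, rep(1L, 7)), log(2), tolerance = 1e-12)
  # hand-computed 2x2 example
  p <- rbind(c(0.8, 0.2), c(0.3, 0.7), c(0.6, 0.4), c(0.1, 0.9))
  t <- c(1L, 2L, 2L, 2L)
  w <- c(0.6, 2.5)
  byhand <- -mean(c(0.6 * log(0.8), 2.5 * log(0.7),
                    2.5 * log(0.4), 2.5 * log(0.9)))
  expect_equal(wce_loss(p, t, w), byhand, tolerance = 1e-10)
})

test_that("Tversky and Dice losses have their boundary values", {
  t <- matrix(c(1, 0, 1, 0, 0, 1), 2, 3)
  expect_equal(tversky_loss(t, t), 0, tolerance = 1e-6)
  expect_equal(dice_loss(t, t), 0, tolerance = 1e-6)
  disjoint <- 1 - t
  expect_equal(tversky_loss(disjoint, t), 1, tolerance = 1e-6)
  expect_equal(dice_loss(disjoint, t), 1, tolerance = 1e-6)
  expect_error(tversky_loss(t, t, alpha = 0), "alpha")
})

test_that("Tversky at alpha = beta = 0.5 is exactly the Dice loss", {
  set.seed(6)
  for (rep in 1:50) {
    p <- matrix(runif(40), 8, 5)
    t <- matrix(as.integer(runif(40) < 0.4), 8, 5)
    expect_equal(tversky_loss(p, t, 0.5, 0.5), dice_loss(p, t),
                 tolerance = 1e-12)
  }
})

test_that("corrupting a perfect prediction strictly increases every loss", {
  set.seed(9)
  t <- matrix(as.integer(runif(64) < 0.3), 8, 8)
  p0 <- t * 0.999 + (1 - t) * 0.001
  corrupt <- p0; corrupt[2, 3] <- 1 - corrupt[2, 3]
  expect_gt(tversky_loss(corrupt, t), tversky_loss(p0, t))
  expect_gt(dice_loss(corrupt, t), dice_loss(p0, t))
  pm0 <- cbind(1 - as.vector(p0), as.vector(p0))
  pmc <- cbind(1 - as.vector(corrupt), as.vector(corrupt))
  tgt <- as.vector(t) + 1L
  expect_gt(wce_loss(pmc, tgt), wce_loss(pm0, tgt))
})

test_that("max-unpooling restores maxima to their positions and zeros elsewhere", {
  ns <- asNamespace("octcalc")
  set.seed(13)
  x <- array(rnorm(8 * 6 * 3 * 2), c(8, 6, 3, 2))
  pl <- ns$maxpool2d_fwd(x, 2L)
  up <- array(0, dim(x))
  up[as.vector(pl$idx) + 1] <- as.vector(pl$y)
  # maxima restored at their argmax positions
  expect_equal(up[as.vector(pl$idx) + 1], as.vector(pl$y))
  # everything else is zero and the nonzero count matches the pool output
  expect_equal(sum(up != 0), sum(pl$y != 0))
  # pooled values are the true block maxima
  expect_equal(pl$y[1, 1, 1, 1], max(x[1:2, 1:2, 1, 1]))
  expect_equal(pl$y[4, 3, 2, 2], max(x[7:8, 5:6, 2, 2]))
})

test_that("segmentation probabilities are normalized and gated by intervals", {
  set.seed(15)
  cfg <- segmenter_config(stages = list(4L))
  model <- asNamespace("octcalc")$segnet_init(cfg)
  stack <- array(runif(6 * 16 * 12), c(6, 16, 12))
  iv <- data.frame(start = 2L, end = 4L)
  out <- segment_frames(stack, model, iv)
  expect_equal(out$frames, 2:4)
  expect_equal(dim(out$probs), c(3L, 16L, 12L, 2L))
  sums <- out$probs[, , , 1] + out$probs[, , , 2]
  expect_lt(max(abs(sums - 1)), 1e-6)
  # inference is deterministic
  out2 <- segment_frames(stack, model, iv)
  expect_identical(out$probs, out2$probs)
})

test_that("training rejects empty frames, stops early and is seeded", {
  set.seed(19)
  masks <- array(0L, c(6, 16, 12))
  masks[, 4:8, 3:6] <- 1L
  # a learnable signal: calcified pixels darker than surroundings
  frames <- array(runif(6 * 16 * 12, 0.5, 0.7), c(6, 16, 12))
  frames[masks == 1L] <- frames[masks == 1L] * 0.3
  bad <- masks; bad[3, , ] <- 0L
  expect_error(
    train_segmenter(frames, bad, frames, masks,
                    config = segmenter_config(stages = list(4L))),
    "indices: 3")

  cfg <- segmenter_config(stages = list(4L))
  tc <- train_config(max_epochs = 6L, patience = 3L, batch_size = 3L,
                     epoch_repeats = 2L, seed = 5L)
  m1 <- train_segmenter(frames, masks, frames, masks, cfg, tc,
                        augment = FALSE)
  m2 <- train_segmenter(frames, masks, frames, masks, cfg, tc,
                        augment = FALSE)
  expect_equal(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_lte(nrow(m1$history), 6L)
  # the training curve decreases
  expect_lt(min(m1$history$train_loss), m1$history$train_loss[1])
})
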