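test_that("window construction follows the parametric padding rules", {
  set.seed(23)
  stack <- array(runif(6 * 10 * 8), c(6, 10, 8))
  n <- 6L; na <- 10L

  # first frame: theta_t is its own last A-line
  w1 <- build_window(stack, 1L)
  expect_equal(dim(w1), c(5L, 12L, 8L))
  expect_equal(w1[3, 1, ], stack[1, na, ])
  # last frame: theta_b is its own first A-line
  wn <- build_window(stack, n)
  expect_equal(wn[3, 12, ], stack[n, 1, ])
  # interior: pads come from the neighbouring frames
  wi <- build_window(stack, 3L)
  expect_equal(wi[3, 1, ], stack[2, na, ])
  expect_equal(wi[3, 12, ], stack[4, 1, ])
  # the window is the identity on the central frame
  expect_equal(wi[3, 2:11, ], stack[3, , ])
  # depth slices are the +/- 2 neighbourhood, replicated at the edges
  expect_equal(wi[1, 2:11, ], stack[1, , ])
  expect_equal(w1[1, 2:11, ], stack[1, , ])
  expect_equal(w1[2, 2:11, ], stack[1, , ])
  expect_error(build_window(stack, 9L), "out of range")
})

test_that("theta rolls preserve window semantics", {
  ns <- asNamespace("octcalc")
  set.seed(29)
  stack <- array(runif(5 * 8 * 6), c(5, 8, 6))
  win <- build_window(stack, 3L)
  r0 <- ns$roll_window(win, 0L)
  expect_equal(r0, win)
  rk <- ns$roll_window(win, 3L)
  # inner rows are rolled circularly
  expect_equal(rk[3, 2 + ((3 + 0:7) %% 8), ], win[3, 2:9, ])
  # pads rebuilt from the rolled neighbour slices
  expect_equal(rk[3, 1, ], rk[2, 9, ])
  expect_equal(rk[3, 10, ], rk[4, 2, ])
})

test_that("frame probabilities normalize and batches permute consistently", {
  set.seed(31)
  cfg <- detector_config(conv_filters = c(2L, 3L), kernel = c(3L, 3L, 3L),
                         fc1_units = 6L)
  stack <- array(runif(7 * 14 * 12), c(7, 14, 12))
  model <- asNamespace("octcalc")$detector_init(cfg, c(5L, 16L, 12L))
  res <- classify_frames(stack, model)
  expect_equal(rowSums(res$probabilities), rep(1, 7), tolerance = 1e-6)
  expect_equal(res$labels,
               as.integer(res$probabilities[, 2] > res$probabilities[, 1]))
  # shape mismatch is reported with dimensions
  bad <- array(runif(7 * 20 * 12), c(7, 20, 12))
  expect_error(classify_frames(bad, model), "do not match")
})

test_that("a zero final layer yields uniform probabilities and 'other' labels", {
  set.seed(43)
  cfg <- detector_config(conv_filters = 2L, kernel = c(3L, 3L, 3L),
                         fc1_units = 4L)
  model <- asNamespace("octcalc")$detector_init(cfg, c(5L, 10L, 8L))
  model$params$fc2_w[] <- 0
  model$params$fc2_b[] <- 0
  stack <- array(0, c(4, 8, 8))
  res <- classify_frames(stack, model)
  expect_equal(res$probabilities,
               matrix(0.5, 4, 2), tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(res$labels, rep(0L, 4))       # tie breaks to "other"
})

test_that("the stepped learning-rate schedule follows the published values", {
  tc <- train_config()
  expect_equal(schedule_lr(tc, 1), 0.001)
  expect_equal(schedule_lr(tc, 5), 0.001)
  expect_equal(schedule_lr(tc, 6), 0.001 * 0.2)
  expect_equal(schedule_lr(tc, 11), 0.001 * 0.2^2)
})

test_that("detector training demands both classes and is seeded", {
  set.seed(37)
  stack <- array(runif(8 * 14 * 12), c(8, 14, 12))
  expect_error(
    train_detector(list(stack), list(rep(0L, 8)), list(stack),
                   list(rep(0L, 8))),
    "both classes")

  labels <- c(0L, 0L, 1L, 1L, 0L, 0L, 1L, 0L)
  cfg <- detector_config(conv_filters = 2L, kernel = c(3L, 3L, 3L),
                         fc1_units = 4L, dropout_rate = 0)
  tc <- train_config(max_epochs = 2L, patience = 2L, batch_size = 4L,
                     seed = 11L)
  m1 <- train_detector(list(stack), list(labels), list(stack), list(labels),
                       cfg, tc)
  m2 <- train_detector(list(stack), list(labels), list(stack), list(labels),
                       cfg, tc)
  expect_equal(m1$history$train_loss[1], m2$history$train_loss[1])
  expect_equal(nrow(m1$history), 2L)
})

test_that("early stopping halts after patience non-improving epochs", {
  ns <- asNamespace("octcalc")
  val_seq <- c(1.0, 0.9, 0.95, 0.96, 0.97)   # best at epoch 2
  i <- 0L
  hist <- ns$run_training(
    n_samples = 4L,
    cfg = train_config(max_epochs = 20L, patience = 3L, batch_size = 2L),
    step_fn = function(idx, lr) 0.5,
    val_fn = function() { i <<- i + 1L; val_seq[min(i, length(val_seq))] },
    get_params = function() list(), set_params = function(p) invisible(p))
  expect_equal(nrow(hist), 5L)               # 2 + patience 3
})
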