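test_that("metric formulas match the worked example and identities", {
  m <- classification_metrics(structure(
    list(TP = 8, TN = 87, FP = 3, FN = 2, granularity = "pixel"),
    class = "confusion_counts"))
  expect_equal(m$sensitivity, 0.8)
  expect_equal(m$precision, 8 / 11)
  expect_equal(m$f1, 16 / 21)

  perfect <- confusion_counts(c(1, 0, 1), c(1, 0, 1))
  expect_equal(unlist(classification_metrics(perfect)),
               c(sensitivity = 1, specificity = 1, precision = 1, f1 = 1))

  none <- confusion_counts(c(0, 0), c(0, 0))
  expect_true(is.na(classification_metrics(none)$sensitivity))
  expect_true(is.na(classification_metrics(none)$precision))
})

test_that("metrics agree with brute-force pixel comparison on random masks", {
  set.seed(17)
  for (rep in 1:100) {
    pred <- matrix(runif(96) < 0.4, 12, 8)
    truth <- matrix(runif(96) < 0.3, 12, 8)
    cc <- confusion_counts(pred, truth)
    tp <- tn <- fp <- fn <- 0L
    for (i in 1:12) for (j in 1:8) {
      if (pred[i, j] && truth[i, j]) tp <- tp + 1L
      else if (!pred[i, j] && !truth[i, j]) tn <- tn + 1L
      else if (pred[i, j]) fp <- fp + 1L
      else fn <- fn + 1L
    }
    expect_equal(c(cc$TP, cc$TN, cc$FP, cc$FN), c(tp, tn, fp, fn))
    m <- classification_metrics(cc)
    if (!is.na(m$precision) && !is.na(m$sensitivity) &&
        (m$precision + m$sensitivity) > 0)
      expect_equal(m$f1, 2 * m$precision * m$sensitivity /
                     (m$precision + m$sensitivity), tolerance = 1e-12)
  }
})

test_that("frame angle is proportional to the positive A-line count", {
  full <- matrix(1L, 448, 20)
  expect_equal(frame_angle(full), 360)
  half <- matrix(0L, 448, 20); half[1:224, 5] <- 1L
  expect_equal(frame_angle(half), 180)
  empty <- matrix(0L, 448, 20)
  expect_equal(frame_angle(empty), 0)
})

test_that("phantom lesion attributes are recovered to pixel accuracy", {
  g <- clean_phantom(depth = 6L, thickness = 12L, half_width = 10L)
  n_alines <- 64L
  masks <- array(0L, c(dim(g$truth$masks)[1], n_alines, 48L))
  for (f in seq_len(dim(masks)[1]))
    masks[f, , ] <- align_and_crop(g$truth$masks[f, , ],
                                   truth_context(g$truth, f))
  iv <- label_runs(g$truth$frame_labels)
  at <- lesion_attributes(masks, iv)
  expect_equal(nrow(at), 1L)
  # 21 A-lines (2*10+1), none under the guidewire for this geometry
  expect_equal(at$max_angle_deg, 21 * 360 / n_alines,
               tolerance = 360 / n_alines)
  expect_equal(at$mean_thickness_mm, 12 * 0.005, tolerance = 0.005)
  expect_equal(at$mean_depth_mm, 6 * 0.005, tolerance = 0.005)
  expect_equal(at$length_mm, 6 * 0.2)
  expect_equal(at$calcium_score, 0L)
})

test_that("a lesion touching the lumen has zero mean depth", {
  g <- clean_phantom(depth = 0L, thickness = 6L)
  f <- 5L
  m <- align_and_crop(g$truth$masks[f, , ], truth_context(g$truth, f))
  at <- lesion_attributes(array(m, c(1, dim(m))),
                          data.frame(start = 1L, end = 1L))
  expect_equal(at$mean_depth_mm, 0)
})

test_that("a 25-frame lesion at 0.2 mm pitch is 5 mm long", {
  masks <- array(0L, c(25, 16, 10)); masks[, 4:6, 3:5] <- 1L
  at <- lesion_attributes(masks, data.frame(start = 1L, end = 25L))
  expect_equal(at$length_mm, 5)
})

test_that("the calcium score rule matches its truth table", {
  cases <- expand.grid(angle = c(90, 190), thick = c(0.3, 0.6),
                       len = c(2, 6))
  expected <- with(cases, 2L * (angle > 180) + (thick > 0.5) + (len > 5))
  got <- mapply(calcium_score, cases$angle, cases$thick, cases$len)
  expect_equal(got, expected)
  expect_equal(calcium_score(190, 0.6, 6), 4L)
  expect_equal(calcium_score(68.5, 0.4, 6), 1L)
  expect_equal(calcium_score(180, 0.5, 5), 0L)  # strict inequalities
})

test_that("cross-validation folds split by pullback without leakage", {
  ids <- paste0("pb", 1:10)
  folds <- crossval_split(ids, k = 5L, seed = 3L)
  expect_length(folds, 5L)
  tests <- unlist(lapply(folds, `[[`, "test"))
  expect_setequal(tests, ids)
  expect_equal(anyDuplicated(tests), 0L)
  for (f in folds) {
    expect_length(f$test, 2L)
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(intersect(f$val, f$test), 0L)
    expect_setequal(c(f$train, f$val, f$test), ids)
  }
  expect_identical(crossval_split(ids, 5L, seed = 3L), folds)
  expect_error(crossval_split(ids[1:3], 5L), "fewer")
})
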