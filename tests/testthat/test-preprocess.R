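test_that("guidewire shadow is recovered within 2 A-lines", {
  g <- noisy_phantom(21L)
  truth_gw <- g$truth$guidewire_alines
  for (f in c(1L, 30L)) {
    det <- detect_guidewire(g$pullback$frames[f, , ])
    expect_gte(length(intersect(det, truth_gw)), length(truth_gw) - 2L)
    expect_lte(length(setdiff(det, truth_gw)), 2L)
  }
})

test_that("a uniformly bright frame has no guidewire shadow", {
  frame <- matrix(0.8, 64, 64)
  expect_length(detect_guidewire(frame), 0)
})

test_that("a shadow wrapping theta = 1 is found as one circular interval", {
  spec <- phantom_spec(n_frames = 2L, n_alines = 64L, n_radial = 64L,
                       guidewire_center_aline = 1L,
                       guidewire_width_alines = 9L,
                       speckle_scale = 0.15, attenuation_per_px = 0.03,
                       seed = 4L)
  g <- generate_pullback(spec)
  det <- detect_guidewire(g$pullback$frames[1, , ])
  truth_gw <- g$truth$guidewire_alines       # 61..64 and 1..5
  expect_gte(length(intersect(det, truth_gw)), length(truth_gw) - 2L)
  expect_true(any(det > 32) && any(det <= 32))  # really wraps
})

test_that("lumen indices match the rendered boundary within 2 px", {
  g <- noisy_phantom(23L)
  for (f in c(2L, 40L)) {
    frame <- g$pullback$frames[f, , ]
    gw <- detect_guidewire(frame)
    lum <- detect_lumen(frame, guidewire = gw)
    free <- setdiff(seq_len(64), union(gw, g$truth$guidewire_alines))
    err <- abs(lum[free] - g$truth$lumen_index[f, free])
    expect_gte(mean(err <= 2), 0.95)
  }
})

test_that("a constant-radius lumen is detected exactly", {
  k <- 20L
  frame <- matrix(0.02, 64, 64)
  frame[, k:(k + 2)] <- 0.85
  frame[, (k + 3):64] <- 0.5
  lum <- detect_lumen(frame)
  expect_equal(lum, rep(k, 64))
})

test_that("continuity constraint is inactive on smooth phantoms", {
  g <- clean_phantom(seed = 31L)
  frame <- g$pullback$frames[2, , ]
  gw <- g$truth$guidewire_alines
  constrained <- detect_lumen(frame, guidewire = gw, jump = 3L)
  free <- detect_lumen(frame, guidewire = gw, jump = 64L)  # per-A-line argmax
  expect_equal(constrained, free)
})

test_that("an all-dark frame raises a lumen error", {
  expect_error(detect_lumen(matrix(0.01, 32, 32)), "no lumen")
})

test_that("alignment crops to the ROI and zero shift is the identity", {
  g <- clean_phantom()
  frame <- g$pullback$frames[1, , ]
  ctx <- truth_context(g$truth, 1L)
  aligned <- align_and_crop(frame, ctx)
  expect_equal(dim(aligned), c(64L, 48L))

  id_ctx <- preproc_context(rep(1L, 64), integer(0), 48L, 64L)
  expect_equal(align_and_crop(frame, id_ctx), frame[, 1:48])
})

test_that("geometry round trip is exact for retained pixels", {
  set.seed(99)
  for (rep in 1:20) {
    g <- noisy_phantom(300L + rep)
    f <- sample(dim(g$truth$masks)[1], 1)
    ctx <- truth_context(g$truth, f)
    mask <- g$truth$masks[f, , ]
    aligned <- align_and_crop(mask, ctx)
    restored <- restore_geometry(aligned, ctx)
    # every pixel retained by the crop must return to its raw position
    retained <- restore_geometry(aligned * 0 + 1, ctx) * mask
    expect_equal(restored, retained * 1)
  }
})

test_that("ROI crop loses exactly the pixels beyond lumen + ROI depth", {
  spec <- phantom_spec(
    n_frames = 6L, n_alines = 64L, n_radial = 96L,
    lesions = data.frame(start_frame = 2L, end_frame = 6L,
                         center_aline = 20L, half_width_alines = 10L,
                         depth_px = 30L, thickness_px = 25L),
    guidewire_center_aline = 48L, guidewire_width_alines = 5L,
    speckle_scale = 0, attenuation_per_px = 0.02,
    lumen_base_px = 14L, lumen_amp_px = 3L, seed = 8L)
  g <- generate_pullback(spec)                 # lesion straddles 48 px ROI
  f <- 5L
  ctx <- truth_context(g$truth, f)
  mask <- g$truth$masks[f, , ]
  aligned <- align_and_crop(mask, ctx)
  depth <- outer(-g$truth$lumen_index[f, ], seq_len(96), `+`)
  deep <- sum(mask[depth >= 48])
  expect_equal(sum(mask) - sum(aligned), deep)
  expect_gt(deep, 0)                                # the case is exercised
})

test_that("despeckling is a normalized 7x7 Gaussian with reflect edges", {
  # constant image unchanged
  const <- matrix(0.4, 20, 20)
  expect_equal(smooth_frame(const), const)
  # impulse response equals the truncated normalized kernel
  imp <- matrix(0, 21, 21); imp[11, 11] <- 1
  sm <- smooth_frame(imp)
  k1 <- dnorm(-3:3); k1 <- k1 / sum(k1)
  expect_equal(sm[8:14, 8:14], outer(k1, k1), tolerance = 1e-12)
  expect_equal(sum(sm), 1, tolerance = 1e-12)
  # variance shrinks on speckle
  set.seed(1)
  sp <- matrix(runif(400), 20, 20)
  expect_lt(var(as.vector(smooth_frame(sp))), var(as.vector(sp)))
})

test_that("pullback preprocessing is per-frame and shape-correct", {
  g <- clean_phantom(n_frames = 6L, speckle = 0.2)
  pre <- preprocess_pullback(g$pullback, roi_depth_px = 48L)
  expect_equal(dim(pre$stack), c(6L, 64L, 48L))
  expect_length(pre$contexts, 6L)

  # permuting frames permutes outputs identically
  perm <- c(3L, 1L, 6L, 2L, 5L, 4L)
  permuted <- polar_pullback(g$pullback$frames[perm, , ])
  pre_p <- preprocess_pullback(permuted, roi_depth_px = 48L)
  expect_equal(pre_p$stack, pre$stack[perm, , ])
})

test_that("contexts serialize to JSON and back", {
  g <- clean_phantom(n_frames = 3L)
  pre <- preprocess_pullback(g$pullback, roi_depth_px = 48L)
  path <- withr::local_tempfile(fileext = ".json")
  write_contexts(pre$contexts, path)
  back <- read_contexts(path)
  expect_equal(lapply(back, unclass), lapply(pre$contexts, unclass))
})
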