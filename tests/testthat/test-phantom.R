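test_that("empty lesion list gives an all-negative pullback", {
  spec <- phantom_spec(n_frames = 5L, n_alines = 32L, n_radial = 48L,
                       seed = 3L)
  g <- generate_pullback(spec)
  expect_equal(g$truth$frame_labels, rep(0L, 5))
  expect_equal(sum(g$truth$masks), 0)
})

test_that("frame labels are positive exactly on lesion frames", {
  g <- clean_phantom()
  expect_equal(which(g$truth$frame_labels == 1L), 4:9)
  expect_equal(g$truth$frame_labels,
               as.integer(apply(g$truth$masks, 1, function(m) any(m > 0))))
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- phantom_study_spec(5L)
  a <- generate_pullback(spec)
  b <- generate_pullback(spec)
  expect_identical(a$pullback$frames, b$pullback$frames)
  expect_identical(a$truth$masks, b$truth$masks)
})

test_that("lesion validation rejects out-of-range geometry", {
  bad_frames <- data.frame(start_frame = 1L, end_frame = 99L,
                           center_aline = 10L, half_width_alines = 3L,
                           depth_px = 2L, thickness_px = 4L)
  expect_error(phantom_spec(10L, 64L, 64L, lesions = bad_frames),
               "frame interval")
  bad_thick <- data.frame(start_frame = 2L, end_frame = 4L,
                          center_aline = 10L, half_width_alines = 3L,
                          depth_px = 2L, thickness_px = 0L)
  expect_error(phantom_spec(10L, 64L, 64L, lesions = bad_thick),
               "thickness")
})

test_that("calcified regions are signal-poor relative to equally deep tissue", {
  g <- noisy_phantom(11L)
  les <- g$truth$spec$lesions
  for (k in seq_len(nrow(les))) {
    f <- les$start_frame[k] + 1L
    img <- g$pullback$frames[f, , ]
    m <- g$truth$masks[f, , ] > 0
    depth <- outer(-g$truth$lumen_index[f, ], seq_len(ncol(img)), `+`)
    rng <- range(depth[m])
    bg <- img[!m & depth >= rng[1] & depth <= rng[2]]
    bg <- bg[bg > 0.05]                 # exclude the guidewire shadow
    expect_lt(mean(img[m]), mean(bg))
  }
})

test_that("masks are zero inside the lumen and the guidewire shadow", {
  g <- noisy_phantom(13L)
  expect_equal(sum(g$truth$masks[, g$truth$guidewire_alines, ]), 0)
  for (f in which(g$truth$frame_labels == 1L)) {
    depth <- outer(-g$truth$lumen_index[f, ],
                   seq_len(dim(g$truth$masks)[3]), `+`)
    expect_equal(sum(g$truth$masks[f, , ][depth < 0]), 0)
  }
})

test_that("fixtures round-trip losslessly with verified checksums", {
  g <- clean_phantom(seed = 9L, n_frames = 4L, speckle = 0.2)
  dir <- withr::local_tempdir()
  man <- write_fixture(g$pullback, g$truth, dir)
  expect_true(file.exists(man))
  manifest <- jsonlite::read_json(man, simplifyVector = TRUE)
  expect_equal(manifest$seed, g$truth$spec$seed)
  back <- read_fixture(dir)
  expect_equal(back$pullback$frames, g$pullback$frames)
  expect_identical(back$truth$masks, g$truth$masks)
  expect_equal(back$truth$lumen_index, g$truth$lumen_index)

  # tampering must be detected
  img <- file.path(dir, "images.tiff")
  bytes <- readBin(img, "raw", file.info(img)$size)
  bytes[length(bytes) - 10] <- as.raw(bitwXor(as.integer(bytes[length(bytes) - 10]), 255L))
  writeBin(bytes, img)
  expect_error(read_fixture(dir), "checksum mismatch")
})
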