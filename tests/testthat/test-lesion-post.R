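disc_mask <- function(n, r, cx = n / 2, cy = n / 2) {
  d <- sqrt(outer((1:n - cx)^2, (1:n - cy)^2, `+`))
  matrix(as.integer(d <= r), n, n)
}

test_that("missing frames are interior empties with two-sided neighbours", {
  masks <- array(0L, c(22, 10, 10))
  iv <- data.frame(start = 10L, end = 20L)
  masks[10:20, 4:6, 4:6] <- 1L
  masks[15, , ] <- 0L
  expect_equal(find_missing(masks, iv), 15L)

  # an empty boundary frame is not reported
  masks[10, , ] <- 0L
  expect_equal(find_missing(masks, iv), 15L)

  # nothing missing when all frames are filled
  masks[15, 4:6, 4:6] <- 1L; masks[10, 4:6, 4:6] <- 1L
  expect_length(find_missing(masks, iv), 0L)
})

test_that("identical neighbours interpolate to themselves", {
  m <- disc_mask(20, 6)
  for (t in c(0.25, 0.5, 0.9))
    expect_identical(interpolate_frame(m, m, t), m)
  expect_error(interpolate_frame(m * 0L, m, 0.5), "nonempty")
})

test_that("concentric discs interpolate to the middle radius", {
  a <- disc_mask(48, 10, 24, 24)
  b <- disc_mask(48, 20, 24, 24)
  mid <- interpolate_frame(a, b, 0.5)
  # area of a disc of radius 15 +/- 1 px
  r_eff <- sqrt(sum(mid) / pi)
  expect_lt(abs(r_eff - 15), 1)
  # shape remains a disc: all positives within radius 16.5 of the centre
  d <- sqrt(outer((1:48 - 24)^2, (1:48 - 24)^2, `+`))
  expect_true(all(d[mid == 1] <= 16.5))
})

test_that("overlapping neighbours always give a nonempty interpolation", {
  set.seed(41)
  for (rep in 1:20) {
    a <- disc_mask(24, runif(1, 4, 8), runif(1, 9, 15), runif(1, 9, 15))
    b <- disc_mask(24, runif(1, 4, 8), runif(1, 9, 15), runif(1, 9, 15))
    if (!any(a & b)) next
    mid <- interpolate_frame(a, b, runif(1, 0.1, 0.9))
    expect_gt(sum(mid), 0)
    # brute-force check of the sign argument at an overlap pixel
    overlap <- which(a & b, arr.ind = TRUE)[1, ]
    expect_equal(mid[overlap[1], overlap[2]], 1L)
  }
})

test_that("filling replaces only the missing frames", {
  masks <- array(0L, c(12, 24, 24))
  iv <- data.frame(start = 3L, end = 9L)
  for (f in 3:9) masks[f, , ] <- disc_mask(24, 6)
  masks[5, , ] <- 0L
  masks[6, , ] <- 0L
  before <- masks
  out <- fill_missing_frames(masks, iv)
  expect_setequal(out$filled, c(5L, 6L))
  for (f in c(3, 4, 7, 8, 9))
    expect_identical(out$masks[f, , ], before[f, , ])
  expect_gt(sum(out$masks[5, , ]), 0)
  expect_gt(sum(out$masks[6, , ]), 0)
  expect_length(find_missing(out$masks, iv), 0L)
})
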