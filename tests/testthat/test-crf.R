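random_prob_frame <- function(h, w, conc = 1) {
  a <- matrix(rbeta(h * w, conc, conc), h, w)
  array(c(1 - a, a), c(h, w, 2))
}

test_that("zero smoothness weight reduces exactly to the unary argmax", {
  set.seed(2)
  p <- random_prob_frame(10, 10)
  params <- crf_params(weight = 0)
  out <- crf_refine(p, params)
  expect_equal(out$probs, p, tolerance = 1e-9)
  expect_equal(out$mask, matrix(as.integer(p[, , 2] > p[, , 1]), 10, 10))
  oracle <- dense_meanfield_oracle(p, params)
  expect_equal(oracle, p, tolerance = 1e-9)
})

test_that("a flipped interior pixel in a confident region is restored", {
  p <- array(0, c(15, 15, 2))
  p[, , 1] <- 0.9; p[, , 2] <- 0.1
  p[8, 8, ] <- c(0.1, 0.9)                    # the flipped pixel
  out <- crf_refine(p, crf_params())
  expect_equal(out$mask[8, 8], 0L)
  oracle <- dense_meanfield_oracle(p, crf_params())
  expect_lt(oracle[8, 8, 2], 0.5)
})

test_that("fast path agrees with the dense pairwise oracle", {
  set.seed(11)
  for (rep in 1:10) {
    p <- random_prob_frame(12, 12)
    fast <- crf_refine(p, crf_params())$probs
    dense <- dense_meanfield_oracle(p, crf_params())
    expect_lt(max(abs(fast - dense)), 1e-6)
  }
})

test_that("probabilities stay normalized through every iteration", {
  set.seed(3)
  p <- random_prob_frame(9, 14)
  for (it in c(1L, 4L, 10L)) {
    q <- crf_refine(p, crf_params(iterations = it))$probs
    expect_lt(max(abs(q[, , 1] + q[, , 2] - 1)), 1e-9)
  }
})

test_that("the dense oracle preserves symmetry and reaches a fixed point", {
  # symmetric two-pixel-wide problem stays symmetric
  p <- array(0, c(2, 1, 2))
  p[, , 1] <- 0.7; p[, , 2] <- 0.3
  q <- dense_meanfield_oracle(p, crf_params(iterations = 5L))
  expect_equal(q[1, 1, ], q[2, 1, ], tolerance = 1e-12)

  # once converged, one extra iteration changes nothing measurable
  set.seed(8)
  p <- random_prob_frame(8, 8)
  q400 <- dense_meanfield_oracle(p, crf_params(iterations = 400L))
  q401 <- dense_meanfield_oracle(p, crf_params(iterations = 401L))
  expect_lt(max(abs(q400 - q401)), 1e-9)
})

test_that("the oracle refuses oversized inputs", {
  p <- random_prob_frame(33, 8)
  expect_error(dense_meanfield_oracle(p), "32")
})

test_that("stronger smoothing does not increase isolated label islands", {
  set.seed(21)
  p <- random_prob_frame(16, 16)
  islands <- function(mask) {
    n <- 0L
    for (i in 1:16) for (j in 1:16) {
      if (!mask[i, j]) next
      nb <- c(if (i > 1) mask[i - 1, j], if (i < 16) mask[i + 1, j],
              if (j > 1) mask[i, j - 1], if (j < 16) mask[i, j + 1])
      if (!any(nb == 1)) n <- n + 1L
    }
    n
  }
  counts <- vapply(c(0, 0.25, 0.5, 1), function(w)
    islands(crf_refine(p, crf_params(weight = w))$mask), integer(1))
  expect_true(all(diff(counts) <= 0))
})
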