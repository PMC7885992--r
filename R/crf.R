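#' Fully connected CRF parameters
#'
#' Parameters of the dense pairwise CRF used to refine per-pixel class
#' probabilities: a single position-only Gaussian smoothness kernel
#' `k(i, j) = exp(-(dr^2 / 2 sigma_r^2 + dtheta^2 / 2 sigma_theta^2))`
#' with Potts label compatibility, combined with the unary potential
#' `-log p` and solved by mean-field iteration. Defaults are sigma_r 1.2,
#' sigma_theta 1.1 (pixels), smoothness weight 0.5 and 10 iterations. The
#' theta axis wraps circularly (the vessel wall is a cylinder).
#'
#' @param sigma_r,sigma_theta Gaussian standard deviations in pixels along
#'   the radial and angular axes.
#' @param weight linear-combination weight of the smoothness kernel.
#' @param iterations number of mean-field passes.
#' @param theta_circular wrap the theta axis when measuring distances.
#' @export
crf_params <- function(sigma_r = 1.2, sigma_theta = 1.1, weight = 0.5,
                       iterations = 10L, theta_circular = TRUE) {
  assert_that(sigma_r > 0 && sigma_theta > 0, "kernel sigmas must be > 0")
  assert_that(iterations >= 1, "iterations must be >= 1")
  assert_that(weight >= 0, "smoothness weight must be >= 0")
  structure(list(sigma_r = sigma_r, sigma_theta = sigma_theta,
                 weight = weight, iterations = as.integer(iterations),
                 theta_circular = isTRUE(theta_circular)),
            class = "crf_params")
}

# 1-D Gaussian kernel matrix between all index pairs; circular distance
# uses the minimal wrap distance. Entries below 1e-12 are zeroed so the
# matrices stay effectively banded.
gauss_kernel_matrix <- function(n, sigma, circular) {
  d <- abs(outer(seq_len(n), seq_len(n), `-`))
  if (circular) d <- pmin(d, n - d)
  k <- exp(-d^2 / (2 * sigma^2))
  k[k < 1e-12] <- 0
  k
}

check_probs <- function(probs) {
  assert_that(length(dim(probs)) == 3, "probs must be (theta, r, classes)")
  assert_that(all(is.finite(probs)) && min(probs) >= 0,
              "invalid probabilities")
  sums <- matrix(0, dim(probs)[1], dim(probs)[2])
  for (c in seq_len(dim(probs)[3])) sums <- sums + probs[, , c]
  assert_that(max(abs(sums - 1)) < 1e-4, "probabilities must sum to 1")
}

#' Mean-field CRF refinement of a probability map
#'
#' Refines a per-pixel class probability map with `iterations` mean-field
#' passes. Messages are computed exactly through the separable structure
#' of the position-only Gaussian kernel (a theta kernel matrix times the
#' probability image times an r kernel matrix), with the self pair
#' excluded; probabilities are renormalized after every pass. The refined
#' mask is the per-pixel argmax, with ties broken to the first
#' (non-calcification) class.
#'
#' @param probs array `(n_alines, roi_depth, n_classes)` of per-pixel
#'   class probabilities.
#' @param params a [crf_params()].
#' @return list with `probs` (refined array of the same shape) and `mask`
#'   (binary matrix, 1 where the last class -- calcification -- wins).
#' @export
crf_refine <- function(probs, params = crf_params()) {
  check_probs(probs)
  na <- dim(probs)[1]; nr <- dim(probs)[2]; nc <- dim(probs)[3]
  unary <- -log(pmax(probs, 1e-12))
  Kt <- gauss_kernel_matrix(na, params$sigma_theta, params$theta_circular)
  Kr <- gauss_kernel_matrix(nr, params$sigma_r, FALSE)
  q <- probs
  for (it in seq_len(params$iterations)) {
    msg <- array(0, dim(q))
    total <- matrix(0, na, nr)
    for (c in seq_len(nc)) {
      msg[, , c] <- Kt %*% q[, , c] %*% Kr - q[, , c]   # exclude self pair
      total <- total + msg[, , c]
    }
    energy <- array(0, dim(q))
    emin <- matrix(Inf, na, nr)
    for (c in seq_len(nc)) {
      energy[, , c] <- unary[, , c] + params$weight * (total - msg[, , c])
      emin <- pmin(emin, energy[, , c])
    }
    norm <- matrix(0, na, nr)
    for (c in seq_len(nc)) {
      q[, , c] <- exp(-(energy[, , c] - emin))
      norm <- norm + q[, , c]
    }
    for (c in seq_len(nc)) q[, , c] <- q[, , c] / norm
  }
  qmax_other <- matrix(-Inf, na, nr)
  for (c in seq_len(nc - 1)) qmax_other <- pmax(qmax_other, q[, , c])
  mask <- (q[, , nc] > qmax_other) * 1L
  list(probs = q, mask = matrix(as.integer(mask), na, nr))
}

#' Dense mean-field reference implementation
#'
#' Unaccelerated reference for [crf_refine()]: enumerates all pixel pairs,
#' builds the full `N x N` Gaussian kernel over flattened coordinates and
#' runs the identical mean-field update. Guarded to images of at most
#' 32 x 32 pixels; intended for testing only.
#'
#' @inheritParams crf_refine
#' @return refined probability array of the same shape.
#' @export
dense_meanfield_oracle <- function(probs, params = crf_params()) {
  check_probs(probs)
  na <- dim(probs)[1]; nr <- dim(probs)[2]; nc <- dim(probs)[3]
  assert_that(na <= 32 && nr <= 32,
              "dense oracle is guarded to images of at most 32 x 32")
  n <- na * nr
  coord_t <- rep(seq_len(na), times = nr)
  coord_r <- rep(seq_len(nr), each = na)
  dt <- abs(outer(coord_t, coord_t, `-`))
  if (params$theta_circular) dt <- pmin(dt, na - dt)
  dr <- abs(outer(coord_r, coord_r, `-`))
  K <- exp(-(dt^2 / (2 * params$sigma_theta^2) +
               dr^2 / (2 * params$sigma_r^2)))
  K[K < 1e-12] <- 0
  diag(K) <- 0                                  # exclude the self pair
  unary <- matrix(-log(pmax(probs, 1e-12)), n, nc)
  q <- matrix(probs, n, nc)
  for (it in seq_len(params$iterations)) {
    msg <- K %*% q
    total <- rowSums(msg)
    energy <- unary + params$weight * (total - msg)
    energy <- energy - apply(energy, 1, min)
    q <- exp(-energy)
    q <- q / rowSums(q)
  }
  array(q, c(na, nr, nc))
}

#' Apply CRF refinement to a stack of probability maps
#'
#' @param prob_stack array `(n_sel, n_alines, roi_depth, n_classes)`.
#' @param params a [crf_params()].
#' @return list with `probs` (refined stack) and `masks` (binary array
#'   `(n_sel, n_alines, roi_depth)`).
#' @export
crf_refine_stack <- function(prob_stack, params = crf_params()) {
  d <- dim(prob_stack)
  masks <- array(0L, d[1:3])
  out <- prob_stack
  for (f in seq_len(d[1])) {
    r <- crf_refine(array(prob_stack[f, , , ], d[2:4]), params)
    out[f, , , ] <- r$probs
    masks[f, , ] <- r$mask
  }
  list(probs = out, masks = masks)
}
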