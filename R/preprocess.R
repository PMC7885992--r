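#' Guidewire shadow detection
#'
#' Finds the contiguous (circularly wrapping) block of A-lines occluded by
#' the guidewire. The shadow is located by minimizing, over all candidate
#' (start, width) windows inside `width_range`, the summed below-threshold
#' margin of per-A-line tissue energy beyond the catheter radius; windows
#' whose total energy is not below `threshold_frac` times the median
#' A-line energy are rejected, and an empty interval is returned when no
#' window qualifies.
#'
#' @param frame numeric matrix `(n_alines, n_radial)`.
#' @param catheter_px radial pixels at the top of each A-line ignored as
#'   catheter rather than tissue.
#' @param width_range integer range of admissible shadow widths in A-lines.
#' @param threshold_frac shadow threshold as a fraction of the median
#'   per-A-line energy.
#' @return integer vector of occluded A-line indices (possibly wrapping
#'   theta = 1), or `integer(0)` when no shadow is found.
#' @export
detect_guidewire <- function(frame, catheter_px = 8L,
                             width_range = NULL,
                             threshold_frac = 0.35) {
  na <- nrow(frame); nr <- ncol(frame)
  assert_that(na > 0 && nr > catheter_px, "frame too small")
  if (is.null(width_range))
    width_range <- c(2L, max(3L, ceiling(na * 0.2)))
  energy <- rowSums(frame[, (catheter_px + 1):nr, drop = FALSE])
  thr <- threshold_frac * median(energy)
  margin <- energy - thr
  ext <- c(margin, margin)                    # unwrap the circle
  cm <- c(0, cumsum(ext))
  best <- 0; best_start <- NA_integer_; best_w <- NA_integer_
  for (w in seq(width_range[1], min(width_range[2], na - 1))) {
    sums <- cm[(w + 1):(na + w)] - cm[1:na]   # window starting at each theta
    i <- which.min(sums)
    if (sums[i] < best) {
      best <- sums[i]; best_start <- i; best_w <- w
    }
  }
  if (is.na(best_start)) return(integer(0))
  (best_start + seq_len(best_w) - 2L) %% na + 1L
}

#' Lumen boundary detection
#'
#' Per-A-line radial index of the first tissue pixel, found as the maximum
#' of an edge score (bright-onset filter) along each A-line, constrained to
#' be continuous in theta (|index change| <= `jump` between neighbouring
#' A-lines, circularly) via dynamic programming. Guidewire A-lines carry no
#' signal and are filled by circular linear interpolation from their
#' neighbours. This detector is a deliberately simple substitute for a
#' dedicated lumen-segmentation network, adequate for phantom data; callers
#' with externally computed lumen indices can bypass it through the
#' `lumen_override` argument of [preprocess_pullback()].
#'
#' @param frame numeric matrix `(n_alines, n_radial)`.
#' @param guidewire integer A-line indices to exclude (from
#'   [detect_guidewire()]).
#' @param jump maximum allowed index change between adjacent A-lines.
#' @param min_radius smallest admissible lumen index (catheter exclusion).
#' @return integer vector of lumen indices, one per A-line.
#' @export
detect_lumen <- function(frame, guidewire = integer(0), jump = 3L,
                         min_radius = 6L) {
  na <- nrow(frame); nr <- ncol(frame)
  assert_that(max(frame) > 0.1, "no lumen detectable: frame is dark")
  sm <- smooth_frame(frame, size = 5L, sigma = 1)
  # onset score: intensity just ahead minus intensity just behind
  ahead <- sm[, c(2:nr, nr), drop = FALSE] + sm
  behind <- sm[, c(1, 1, 1:(nr - 2)), drop = FALSE] +
    sm[, c(1, 1:(nr - 1)), drop = FALSE]
  score <- ahead - behind
  score[, seq_len(min(min_radius, nr))] <- -Inf
  if (length(guidewire)) score[guidewire, ] <- 0

  # anchor the circular chain at the most confident A-line
  free <- setdiff(seq_len(na), guidewire)
  anchor <- free[which.max(apply(score[free, , drop = FALSE], 1, max))]
  order_theta <- ((anchor:(anchor + na - 1)) - 1L) %% na + 1L

  cost <- score[order_theta[1], ]
  back <- matrix(0L, na, nr)
  offs <- -jump:jump
  for (t in 2:na) {
    shifted <- vapply(offs, function(d) {
      v <- rep(-Inf, nr)
      src <- seq_len(nr) + d
      ok <- src >= 1 & src <= nr
      v[ok] <- cost[src[ok]]
      v
    }, numeric(nr))
    pick <- max.col(shifted, ties.method = "first")
    cost <- shifted[cbind(seq_len(nr), pick)] + score[order_theta[t], ]
    back[t, ] <- seq_len(nr) + offs[pick]
  }
  path <- integer(na)
  path[na] <- which.max(cost)
  for (t in na:2) path[t - 1] <- back[t, path[t]]
  lumen <- integer(na)
  lumen[order_theta] <- path

  if (length(guidewire)) {
    lumen[guidewire] <- NA_integer_
    lumen <- fill_circular(lumen)
  }
  as.integer(lumen)
}

# Circular linear interpolation over NA runs in an integer vector.
fill_circular <- function(x) {
  n <- length(x)
  ok <- which(!is.na(x))
  assert_that(length(ok) > 0, "no valid A-lines to interpolate from")
  for (i in which(is.na(x))) {
    d_prev <- (i - ok - 1L) %% n; p <- ok[which.min(d_prev)]
    d_next <- (ok - i - 1L) %% n; q <- ok[which.min(d_next)]
    dp <- (i - p) %% n; dq <- (q - i) %% n
    x[i] <- as.integer(round((x[p] * dq + x[q] * dp) / (dp + dq)))
  }
  x
}

#' Preprocessing context
#'
#' Records the per-A-line geometry of one preprocessed frame so that
#' aligned-domain results can be mapped back to raw coordinates: lumen
#' index, the pixel shift applied to each A-line, the guidewire A-line set,
#' the ROI depth and the raw radial size.
#'
#' @param lumen_index integer vector, 1-based radial index of the first
#'   tissue pixel per A-line.
#' @param guidewire integer A-line indices zeroed as guidewire shadow.
#' @param roi_depth_px retained radial depth after cropping (200 px = 1 mm
#'   at 5 um/px).
#' @param n_radial raw radial size.
#' @export
preproc_context <- function(lumen_index, guidewire = integer(0),
                            roi_depth_px = 200L, n_radial) {
  assert_that(roi_depth_px > 0, "roi_depth_px must be > 0")
  assert_that(all(lumen_index >= 1) && all(lumen_index <= n_radial),
              "lumen_index out of radial range")
  structure(list(lumen_index = as.integer(lumen_index),
                 shift_offset = as.integer(lumen_index) - 1L,
                 guidewire = as.integer(guidewire),
                 roi_depth_px = as.integer(roi_depth_px),
                 n_radial = as.integer(n_radial)),
            class = "preproc_context")
}

#' Align A-lines to the lumen and crop the ROI
#'
#' Shifts every A-line left so that its lumen boundary lands in column 1,
#' keeps `roi_depth_px` columns (zero-padding short A-lines), and zeroes
#' guidewire A-lines. At acquisition scale this reduces a 968 x 448 frame
#' to 200 x 448 (1 mm ROI).
#'
#' @param frame numeric matrix `(n_alines, n_radial)`.
#' @param ctx a [preproc_context()].
#' @return matrix `(n_alines, roi_depth_px)`.
#' @export
align_and_crop <- function(frame, ctx) {
  na <- nrow(frame); nr <- ncol(frame)
  assert_that(length(ctx$lumen_index) == na && ctx$n_radial == nr,
              "context does not match frame dimensions")
  roi <- ctx$roi_depth_px
  out <- matrix(0, na, roi)
  for (i in seq_len(na)) {
    s <- ctx$shift_offset[i]
    keep <- min(roi, nr - s)
    if (keep > 0) out[i, seq_len(keep)] <- frame[i, s + seq_len(keep)]
  }
  if (length(ctx$guidewire)) out[ctx$guidewire, ] <- 0
  out
}

#' Restore aligned-domain masks to raw geometry
#'
#' Inverse of [align_and_crop()]: shifts every A-line right by its recorded
#' offset and zero-fills the rest, recovering the raw `(n_alines,
#' n_radial)` geometry (e.g. 200 x 448 back to 968 x 448).
#'
#' @param mask matrix `(n_alines, roi_depth_px)` in aligned coordinates.
#' @param ctx the [preproc_context()] of the same frame.
#' @return matrix `(n_alines, n_radial)`.
#' @export
restore_geometry <- function(mask, ctx) {
  na <- length(ctx$lumen_index)
  assert_that(nrow(mask) == na && ncol(mask) == ctx$roi_depth_px,
              "mask does not match context dimensions")
  out <- matrix(0, na, ctx$n_radial)
  for (i in seq_len(na)) {
    s <- ctx$shift_offset[i]
    keep <- min(ctx$roi_depth_px, ctx$n_radial - s)
    if (keep > 0) out[i, s + seq_len(keep)] <- mask[i, seq_len(keep)]
  }
  out
}

#' Gaussian despeckling
#'
#' Separable Gaussian filter (default 7 x 7, sigma 1) with reflective
#' boundary handling; the kernel is normalized to sum 1 so mean intensity
#' is preserved up to boundary effects.
#'
#' @param frame numeric matrix.
#' @param size odd kernel size.
#' @param sigma Gaussian standard deviation in pixels.
#' @return filtered matrix of the same size.
#' @export
smooth_frame <- function(frame, size = 7L, sigma = 1) {
  assert_that(size %% 2 == 1 && size >= 1, "kernel size must be odd")
  h <- (size - 1L) %/% 2L
  k <- dnorm(-h:h, sd = sigma)
  k <- k / sum(k)
  reflect_pad <- function(m, h) {
    if (h == 0) return(m)
    m[, c(h:1, seq_len(ncol(m)), ncol(m) - 0:(h - 1)), drop = FALSE]
  }
  conv_cols <- function(m) {           # filter along columns of each row
    p <- reflect_pad(m, h)
    out <- matrix(0, nrow(m), ncol(m))
    for (j in seq_len(size)) out <- out +
        k[j] * p[, (j - 1) + seq_len(ncol(m)), drop = FALSE]
    out
  }
  t(conv_cols(t(conv_cols(frame))))
}

#' Preprocess a pullback
#'
#' Applies, per frame and in order: guidewire shadow detection, lumen
#' detection, A-line alignment with ROI cropping, and Gaussian despeckling.
#' The per-frame geometric contexts are retained so downstream results can
#' be mapped back to raw coordinates.
#'
#' @param pullback a [polar_pullback()].
#' @param roi_depth_px retained radial depth after alignment.
#' @param lumen_override optional matrix `(n_frames, n_alines)` of
#'   externally supplied lumen indices that bypasses [detect_lumen()].
#' @param guidewire_override optional list of A-line index vectors
#'   bypassing [detect_guidewire()].
#' @param smooth_size,smooth_sigma despeckling filter parameters.
#' @param ... passed to [detect_guidewire()] and [detect_lumen()].
#' @return list with `stack` (array `(n_frames, n_alines, roi_depth_px)`)
#'   and `contexts` (list of [preproc_context()], one per frame).
#' @export
preprocess_pullback <- function(pullback, roi_depth_px = 200L,
                                lumen_override = NULL,
                                guidewire_override = NULL,
                                smooth_size = 7L, smooth_sigma = 1, ...) {
  d <- dim(pullback$frames)
  assert_that(d[1] >= 1, "empty pullback")
  stack <- array(0, c(d[1], d[2], roi_depth_px))
  contexts <- vector("list", d[1])
  for (f in seq_len(d[1])) {
    res <- tryCatch({
      frame <- pullback$frames[f, , ]
      gw <- if (is.null(guidewire_override)) detect_guidewire(frame, ...)
            else guidewire_override[[f]]
      lum <- if (is.null(lumen_override)) detect_lumen(frame, guidewire = gw, ...)
             else as.integer(lumen_override[f, ])
      ctx <- preproc_context(lum, gw, roi_depth_px, d[3])
      aligned <- align_and_crop(frame, ctx)
      list(frame = smooth_frame(aligned, smooth_size, smooth_sigma), ctx = ctx)
    }, error = function(e)
      stop(sprintf("preprocessing failed at frame %d: %s", f,
                   conditionMessage(e)), call. = FALSE))
    stack[f, , ] <- res$frame
    contexts[[f]] <- res$ctx
  }
  list(stack = stack, contexts = contexts)
}

#' Serialize preprocessing contexts to JSON
#'
#' @param contexts list of [preproc_context()] objects.
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
write_contexts <- function(contexts, path) {
  jsonlite::write_json(lapply(contexts, unclass), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_contexts
#' @export
read_contexts <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(if (is.data.frame(raw)) nrow(raw) else length(raw)),
         function(i) {
           x <- if (is.data.frame(raw)) lapply(raw, `[[`, i) else raw[[i]]
           preproc_context(unlist(x$lumen_index),
                           as.integer(unlist(x$guidewire)),
                           x$roi_depth_px, x$n_radial)
         })
}
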