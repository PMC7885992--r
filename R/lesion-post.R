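#' Find missing frames inside lesion intervals
#'
#' A missing frame is a frame strictly inside a lesion interval whose
#' segmentation mask is empty while nonempty masks exist on both sides
#' within the same interval -- the signature of a per-frame segmentation
#' dropout in an otherwise continuous calcification.
#'
#' @param masks binary array `(n_frames, n_alines, roi_depth)`.
#' @param intervals data.frame of lesion intervals (`start`, `end`).
#' @return integer vector of missing frame indices.
#' @export
find_missing <- function(masks, intervals) {
  missing <- integer(0)
  for (k in seq_len(nrow(intervals))) {
    fr <- intervals$start[k]:intervals$end[k]
    nonempty <- fr[vapply(fr, function(f) any(masks[f, , ] > 0), logical(1))]
    if (length(nonempty) < 2) next
    for (f in fr) {
      if (f %in% nonempty) next
      if (any(nonempty < f) && any(nonempty > f))
        missing <- c(missing, f)
    }
  }
  missing
}

# Signed Euclidean distance to the mask boundary: negative inside the
# mask, positive outside (EBImage distmap does the two half-space
# transforms).
signed_distance <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow(mask), ncol(mask))
  as.matrix(EBImage::distmap(1 - m)) - as.matrix(EBImage::distmap(m))
}

#' Shape interpolation between two masks
#'
#' Morphs between two binary masks by linear interpolation of their
#' signed Euclidean distance transforms: `s = (1 - t) sdt(prev) +
#' t sdt(next)`, thresholded at `s <= 0`. This produces a sharp binary
#' intermediate shape; identical neighbours reproduce themselves exactly
#' for any `t`.
#'
#' @param mask_prev,mask_next nonempty binary matrices of equal size.
#' @param t relative position in `(0, 1)` between the two masks.
#' @return interpolated binary matrix.
#' @export
interpolate_frame <- function(mask_prev, mask_next, t) {
  assert_that(any(mask_prev > 0) && any(mask_next > 0),
              "both neighbour masks must be nonempty")
  assert_that(t > 0 && t < 1, "t must lie strictly in (0, 1)")
  assert_that(all(dim(mask_prev) == dim(mask_next)),
              "neighbour masks differ in size")
  s <- (1 - t) * signed_distance(mask_prev) + t * signed_distance(mask_next)
  matrix(as.integer(s <= 0), nrow(mask_prev), ncol(mask_prev))
}

#' Fill missing frames by shape interpolation
#'
#' Replaces every missing frame (see [find_missing()]) by the
#' signed-distance interpolation of its nearest nonempty neighbours
#' within the same lesion interval, with `t` linear in frame position.
#' Frames that already have nonempty masks are never altered.
#'
#' @inheritParams find_missing
#' @return list with `masks` (array with missing frames filled) and
#'   `filled` (indices of the frames that were replaced).
#' @export
fill_missing_frames <- function(masks, intervals) {
  orig <- masks
  missing <- find_missing(orig, intervals)
  for (f in missing) {
    k <- which(intervals$start <= f & intervals$end >= f)[1]
    fr <- intervals$start[k]:intervals$end[k]
    nonempty <- fr[vapply(fr, function(g) any(orig[g, , ] > 0), logical(1))]
    p <- max(nonempty[nonempty < f])
    q <- min(nonempty[nonempty > f])
    t <- (f - p) / (q - p)
    masks[f, , ] <- interpolate_frame(masks[p, , ], masks[q, , ], t)
  }
  list(masks = masks, filled = missing)
}
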