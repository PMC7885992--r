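#' 1-D morphological cleanup of frame labels
#'
#' Binary opening and closing of the per-frame calcification label
#' sequence with a flat, centred structuring element (default size 5
#' frames). Opening removes isolated positive runs shorter than the
#' element; closing fills gaps shorter than the element between surviving
#' runs. The sequence is treated as zero beyond both ends, so a short run
#' touching the pullback boundary is removed and boundary gaps are never
#' filled.
#'
#' @param labels binary integer vector (1 = calcification frame).
#' @param se_size odd structuring-element size in frames.
#' @return binary integer vector of the same length.
#' @export
open_1d <- function(labels, se_size = 5L) {
  check_se(labels, se_size)
  dilate_1d(erode_1d(labels, se_size), se_size)
}

#' @rdname open_1d
#' @export
close_1d <- function(labels, se_size = 5L) {
  check_se(labels, se_size)
  # dilation reaches beyond the sequence ends, and the erosion needs those
  # values; compute on an explicitly zero-extended domain and crop back
  h <- se_size - 1L
  xp <- c(rep(0L, h), as.integer(labels), rep(0L, h))
  out <- erode_1d(dilate_1d(xp, se_size), se_size)
  out[h + seq_along(labels)]
}

check_se <- function(labels, se_size) {
  assert_that(length(labels) >= 1, "empty label sequence")
  assert_that(all(labels %in% c(0L, 1L)), "labels must be binary")
  assert_that(se_size >= 1 && se_size %% 2 == 1,
              "structuring element size must be odd and >= 1")
}

# Flat erosion/dilation; `pad` is the value assumed beyond both ends.
erode_1d <- function(x, k, pad = 0L) {
  h <- (k - 1L) %/% 2L
  out <- rep(1L, length(x))
  for (d in -h:h) out <- out & shift_pad(x, d, pad)
  as.integer(out)
}

dilate_1d <- function(x, k, pad = 0L) {
  h <- (k - 1L) %/% 2L
  out <- rep(0L, length(x))
  for (d in -h:h) out <- out | shift_pad(x, d, pad)
  as.integer(out)
}

shift_pad <- function(x, d, pad = 0L) {
  n <- length(x)
  if (d == 0) return(x)
  if (d > 0) c(x[-seq_len(min(d, n))], rep(pad, min(d, n)))[seq_len(n)]
  else c(rep(pad, min(-d, n)), x)[seq_len(n)]
}

#' Clean a frame-label sequence into lesion intervals
#'
#' Applies opening then closing (both with the same structuring element)
#' and extracts the maximal runs of surviving positives as major
#' calcification lesion intervals.
#'
#' @param labels binary integer vector of per-frame labels.
#' @param se_size structuring-element size (odd).
#' @return list with `labels` (cleaned binary vector) and `intervals`
#'   (data.frame with `start`, `end`, inclusive 1-based frame indices).
#' @export
cleanup_labels <- function(labels, se_size = 5L) {
  cleaned <- close_1d(open_1d(labels, se_size), se_size)
  list(labels = cleaned, intervals = label_runs(cleaned))
}

#' Maximal positive runs of a binary sequence
#'
#' @param labels binary integer vector.
#' @return data.frame with inclusive `start` and `end` frame indices,
#'   sorted and disjoint.
#' @export
label_runs <- function(labels) {
  r <- rle(as.integer(labels))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  pos <- r$values == 1L
  data.frame(start = starts[pos], end = ends[pos])
}

#' Expand lesion intervals to frame indices
#'
#' @param intervals data.frame with `start`/`end` columns.
#' @return sorted integer vector of all frames covered by the intervals.
#' @export
interval_frames <- function(intervals) {
  if (!nrow(intervals)) return(integer(0))
  sort(unlist(Map(seq, intervals$start, intervals$end)))
}
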