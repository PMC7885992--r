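#' Confusion counts
#'
#' Tallies true/false positives and negatives between predicted and ground
#' truth binary data at pixel or frame granularity.
#'
#' @param pred,truth binary vectors/arrays of identical shape.
#' @param granularity `"pixel"` or `"frame"` (bookkeeping only).
#' @return object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(pred, truth, granularity = c("pixel", "frame")) {
  granularity <- match.arg(granularity)
  assert_that(length(pred) == length(truth),
              "pred and truth differ in length")
  p <- as.logical(pred); t <- as.logical(truth)
  structure(list(TP = sum(p & t), TN = sum(!p & !t),
                 FP = sum(p & !t), FN = sum(!p & t),
                 granularity = granularity), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion (%s): TP=%d TN=%d FP=%d FN=%d\n",
              x$granularity, x$TP, x$TN, x$FP, x$FN))
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Sensitivity TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP)
#' and F1 = 2TP/(2TP+FP+FN). A metric whose denominator is zero is
#' reported as `NA` (undefined), never as 0.
#'
#' @param counts a [confusion_counts()] object.
#' @return named list with `sensitivity`, `specificity`, `precision`,
#'   `f1`.
#' @export
classification_metrics <- function(counts) {
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  with(counts, list(
    sensitivity = safe_div(TP, TP + FN),
    specificity = safe_div(TN, TN + FP),
    precision = safe_div(TP, TP + FP),
    f1 = safe_div(2 * TP, 2 * TP + FP + FN)))
}

#' Calcium arc angle of one frame
#'
#' Arc angle subtended by the calcification in an aligned polar mask,
#' measured catheter-centrically: the number of A-lines containing at
#' least one positive pixel times `360 / n_alines` degrees. A wrapping arc
#' counts each A-line once by construction.
#'
#' @param mask binary matrix `(n_alines, roi_depth_px)`.
#' @return angle in degrees in `[0, 360]`.
#' @export
frame_angle <- function(mask) {
  sum(rowSums(mask > 0) > 0) * 360 / nrow(mask)
}

#' Per-lesion calcium attributes
#'
#' For every lesion interval, computes the clinically used calcium
#' attributes from the aligned binary masks: maximum arc angle over the
#' lesion's frames; mean thickness (radial extent of the calcification per
#' positive A-line, last minus first positive index plus one, times the
#' radial pitch) averaged over all positive A-lines in the lesion; mean
#' depth (first positive radial index relative to the lumen, which is
#' column 1 after alignment, times the radial pitch); lesion length
#' (frame count times frame pitch); and the 0-4 calcium score.
#'
#' @param masks binary array `(n_frames, n_alines, roi_depth_px)` in
#'   aligned coordinates.
#' @param intervals data.frame of lesion intervals (`start`, `end`).
#' @param r_pitch_mm radial pixel pitch (default 0.005 mm = 5 um).
#' @param frame_pitch_mm frame pitch (default 0.2 mm).
#' @return data.frame with one row per lesion: `start`, `end`,
#'   `max_angle_deg`, `mean_thickness_mm`, `max_thickness_mm`,
#'   `mean_depth_mm`, `length_mm`, `calcium_score`.
#' @export
lesion_attributes <- function(masks, intervals, r_pitch_mm = 0.005,
                              frame_pitch_mm = 0.2) {
  if (!nrow(intervals))
    return(data.frame(start = integer(), end = integer(),
                      max_angle_deg = numeric(),
                      mean_thickness_mm = numeric(),
                      max_thickness_mm = numeric(),
                      mean_depth_mm = numeric(), length_mm = numeric(),
                      calcium_score = integer()))
  out <- lapply(seq_len(nrow(intervals)), function(k) {
    fr <- intervals$start[k]:intervals$end[k]
    angles <- numeric(length(fr))
    thick <- depth <- numeric(0)
    for (j in seq_along(fr)) {
      m <- masks[fr[j], , ] > 0
      angles[j] <- frame_angle(m)
      pos <- which(rowSums(m) > 0)
      for (i in pos) {
        idx <- which(m[i, ])
        thick <- c(thick, max(idx) - min(idx) + 1L)
        depth <- c(depth, min(idx) - 1L)
      }
    }
    assert_that(length(thick) > 0,
                sprintf("lesion %d-%d has no positive pixels",
                        intervals$start[k], intervals$end[k]))
    max_th <- max(thick) * r_pitch_mm
    len <- length(fr) * frame_pitch_mm
    ang <- max(angles)
    data.frame(start = intervals$start[k], end = intervals$end[k],
               max_angle_deg = ang,
               mean_thickness_mm = mean(thick) * r_pitch_mm,
               max_thickness_mm = max_th,
               mean_depth_mm = mean(depth) * r_pitch_mm,
               length_mm = len,
               calcium_score = calcium_score(ang, max_th, len))
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Rule-based IVOCT calcium score
#'
#' 0-4 score predicting stent under-expansion risk: +2 if the maximum arc
#' angle exceeds 180 degrees, +1 if the maximum thickness exceeds 0.5 mm,
#' +1 if the lesion length exceeds 5 mm (all strict inequalities).
#'
#' @param max_angle_deg maximum arc angle over the lesion, degrees.
#' @param max_thickness_mm maximum per-A-line thickness, mm.
#' @param length_mm lesion length, mm.
#' @return integer score in 0..4.
#' @export
calcium_score <- function(max_angle_deg, max_thickness_mm, length_mm) {
  as.integer(2L * (max_angle_deg > 180) + (max_thickness_mm > 0.5) +
               (length_mm > 5))
}

#' Cross-validation folds by pullback
#'
#' Splits pullback identifiers into `k` folds with train/validation/test
#' roles, always by pullback and never by frame. Each pullback appears in
#' the test role exactly once across folds; with `k = 5` and equal group
#' sizes this is the 80/10/10 train/validation/test layout.
#'
#' @param ids vector of pullback identifiers.
#' @param k number of folds.
#' @param seed integer seed for the shuffle.
#' @return list of `k` lists with `train`, `val`, `test` id vectors.
#' @export
crossval_split <- function(ids, k = 5L, seed = 1L) {
  assert_that(length(ids) >= k, "fewer pullbacks than folds")
  with_seed(seed, {
    shuffled <- sample(ids)
    groups <- split(shuffled, rep_len(seq_len(k), length(ids)))
    lapply(seq_len(k), function(i) {
      test <- groups[[i]]
      val <- groups[[i %% k + 1L]]
      train <- setdiff(shuffled, c(test, val))
      list(train = train, val = val, test = test)
    })
  })
}

#' Write a per-lesion attribute report
#'
#' @param attributes data.frame from [lesion_attributes()].
#' @param path output CSV file.
#' @return the path, invisibly.
#' @export
write_attributes <- function(attributes, path) {
  write.csv(attributes, path, row.names = FALSE)
  invisible(path)
}
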