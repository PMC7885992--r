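#' Run the full two-step pipeline on a pullback
#'
#' Orchestrates preprocessing, frame classification (step 1),
#' morphological cleanup of the label sequence, per-pixel segmentation of
#' the lesion frames (step 2), CRF refinement, missing-frame
#' interpolation, geometry restoration and calcium quantification. In
#' one-step mode the frame classifier is skipped and every frame is
#' segmented.
#'
#' @param pullback a [polar_pullback()].
#' @param detector trained `oct_detector` (may be `NULL` in one-step
#'   mode).
#' @param segmenter trained `oct_segmenter`.
#' @param roi_depth_px preprocessing ROI depth.
#' @param se_size structuring element of the label cleanup.
#' @param crf a [crf_params()] object, or `NULL` to skip refinement.
#' @param one_step skip step 1 and segment every frame.
#' @param truth optional `phantom_truth` for metric computation.
#' @param out_dir optional directory; when given, the bundle is written
#'   there (labels and intervals as JSON, aligned and raw-geometry masks
#'   as multi-frame TIFF, attributes as CSV, metrics as JSON, log as
#'   text).
#' @param preprocess_args list of extra arguments for
#'   [preprocess_pullback()].
#' @return list with `frame_labels`, `intervals`, `masks_aligned`,
#'   `masks_raw`, `attributes`, `metrics` (when truth given), `contexts`,
#'   `timings` and `log`.
#' @export
run_pipeline <- function(pullback, detector, segmenter,
                         roi_depth_px = 200L, se_size = 5L,
                         crf = crf_params(), one_step = FALSE,
                         truth = NULL, out_dir = NULL,
                         preprocess_args = list()) {
  d <- dim(pullback$frames)
  timings <- c()
  log_lines <- character(0)
  note <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    out
  }

  pre <- stage("preprocess", do.call(preprocess_pullback,
                                     c(list(pullback, roi_depth_px),
                                       preprocess_args)))
  note("preprocessed %d frames to (%d x %d)", d[1], d[2], roi_depth_px)

  if (one_step) {
    labels <- rep(1L, d[1])
    intervals <- data.frame(start = 1L, end = d[1])
    note("one-step mode: all %d frames forwarded to segmentation", d[1])
  } else {
    cls <- stage("detect", classify_frames(pre$stack, detector))
    cl <- stage("cleanup", cleanup_labels(cls$labels, se_size))
    labels <- cl$labels
    intervals <- cl$intervals
    note("step 1: %d/%d raw positives, %d after cleanup in %d lesion(s)",
         sum(cls$labels), d[1], sum(labels), nrow(intervals))
  }

  seg <- stage("segment", segment_frames(pre$stack, segmenter, intervals))
  note("step 2: segmented %d frame(s)", length(seg$frames))

  masks_aligned <- array(0L, c(d[1], d[2], roi_depth_px))
  if (length(seg$frames)) {
    refined <- if (is.null(crf)) {
      nc <- dim(seg$probs)[4]
      arg <- (seg$probs[, , , nc, drop = FALSE] >
                seg$probs[, , , 1, drop = FALSE]) * 1L
      list(masks = array(as.integer(arg), dim(seg$probs)[1:3]))
    } else stage("crf", crf_refine_stack(seg$probs, crf))
    masks_aligned[seg$frames, , ] <- refined$masks
    fill <- stage("interpolate", fill_missing_frames(masks_aligned, intervals))
    masks_aligned <- fill$masks
    note("filled %d missing frame(s)", length(fill$filled))
  }

  attrs <- stage("quantify", {
    live <- intervals[vapply(seq_len(nrow(intervals)), function(k)
      any(masks_aligned[intervals$start[k]:intervals$end[k], , ] > 0),
      logical(1)), , drop = FALSE]
    lesion_attributes(masks_aligned, live,
                      r_pitch_mm = pullback$r_pitch_mm,
                      frame_pitch_mm = pullback$frame_pitch_mm)
  })

  masks_raw <- stage("restore", {
    out <- array(0L, d)
    for (f in seq_len(d[1]))
      out[f, , ] <- restore_geometry(masks_aligned[f, , ],
                                     pre$contexts[[f]])
    out
  })
  note("restored masks to raw geometry (%d x %d)", d[2], d[3])

  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- stage("metrics", {
      truth_aligned <- array(0L, dim(masks_aligned))
      for (f in seq_len(d[1]))
        truth_aligned[f, , ] <-
          align_and_crop(truth$masks[f, , ], pre$contexts[[f]])
      list(frame = classification_metrics(
             confusion_counts(labels, truth$frame_labels, "frame")),
           pixel = classification_metrics(
             confusion_counts(masks_aligned, truth_aligned, "pixel")))
    })
  }

  bundle <- list(frame_labels = labels, intervals = intervals,
                 masks_aligned = masks_aligned, masks_raw = masks_raw,
                 attributes = attrs, metrics = metrics,
                 contexts = pre$contexts, timings = timings,
                 log = log_lines)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(labels = bundle$frame_labels,
                            intervals = bundle$intervals),
                       file.path(out_dir, "labels.json"),
                       auto_unbox = TRUE, digits = NA)
  write_mask_stack(bundle$masks_aligned,
                   file.path(out_dir, "masks_aligned.tiff"))
  write_mask_stack(bundle$masks_raw, file.path(out_dir, "masks_raw.tiff"))
  write_attributes(bundle$attributes, file.path(out_dir, "attributes.csv"))
  write_contexts(bundle$contexts, file.path(out_dir, "contexts.json"))
  if (!is.null(bundle$metrics))
    jsonlite::write_json(bundle$metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  writeLines(c(bundle$log,
               sprintf("%s: %.2fs", names(bundle$timings),
                       unlist(bundle$timings))),
             file.path(out_dir, "pipeline.log"))
  invisible(out_dir)
}
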