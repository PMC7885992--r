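#' Randomized phantom pullback specification for desk-scale studies
#'
#' Draws a phantom spec with two or three major calcification lesions of
#' 5-9 frames (separated by at least 6 frames and kept clear of the
#' pullback ends), angular half-widths of 6-16 A-lines, leading-edge
#' depths of 1-8 px and thicknesses of 5-16 px, plus a 6-A-line guidewire
#' shadow at a random angle. At the default 60 x 64 x 64 study geometry
#' this yields lesion prevalences of roughly 15-35% of frames. All draws
#' derive from `seed`.
#'
#' @param seed integer seed.
#' @param n_frames,n_alines,n_radial study geometry.
#' @return a [phantom_spec()].
#' @export
phantom_study_spec <- function(seed, n_frames = 60L, n_alines = 64L,
                               n_radial = 64L) {
  with_seed(seed, {
    n_les <- sample(2:3, 1)
    lens <- if (n_les == 2) sample(5:9, 2, replace = TRUE)
            else sample(5:6, 3, replace = TRUE)
    # place the lesions in order with gaps of at least 6 frames
    slack <- n_frames - 4L - sum(lens) - 6L * (n_les - 1L)
    lead <- sample(0:min(slack, 5L), 1)
    slack <- slack - lead
    gaps <- if (n_les > 1) {
      cuts <- sort(sample(0:slack, n_les - 1, replace = TRUE))
      diff(c(0, cuts))
    } else integer(0)
    starts <- integer(n_les)
    pos <- 3L + lead
    for (k in seq_len(n_les)) {
      if (k > 1) pos <- pos + lens[k - 1] + 6L + gaps[k - 1]
      starts[k] <- pos
    }
    lesions <- data.frame(
      start_frame = starts, end_frame = starts + lens - 1L,
      center_aline = sample(seq_len(n_alines), n_les, replace = TRUE),
      half_width_alines = sample(6:16, n_les, replace = TRUE),
      depth_px = sample(1:8, n_les, replace = TRUE),
      thickness_px = sample(5:16, n_les, replace = TRUE))
    phantom_spec(n_frames, n_alines, n_radial, lesions = lesions,
                 guidewire_center_aline = sample(seq_len(n_alines), 1),
                 guidewire_width_alines = 6L,
                 speckle_scale = 0.25, attenuation_per_px = 0.03,
                 seed = seed)
  })
}

# Align the ground-truth masks of a phantom with the contexts produced by
# preprocessing, so predictions and truth live in the same geometry.
align_truth_masks <- function(truth, contexts, roi_depth_px) {
  n <- dim(truth$masks)[1]
  out <- array(0L, c(n, dim(truth$masks)[2], roi_depth_px))
  for (f in seq_len(n))
    out[f, , ] <- align_and_crop(truth$masks[f, , ], contexts[[f]])
  out
}

#' Desk-scale two-step vs one-step phantom study
#'
#' Generates seeded phantom pullbacks at the 60-frame, 64 x 64 study
#' geometry, trains a small frame detector and two small segmenters (one
#' on calcification frames only -- the two-step protocol -- and one on
#' all frames for the one-step comparison), runs both pipelines on
#' held-out pullbacks and reports frame- and pixel-level metrics. The
#' train/validation/test split is by pullback.
#'
#' @param seed master seed; every random component (phantom content,
#'   weight initialization, shuffling, dropout) derives from it.
#' @param n_train,n_test training (the last training pullback serves as
#'   validation) and held-out pullback counts.
#' @param roi_depth_px preprocessing ROI depth for the study geometry.
#' @param crf [crf_params()] used at evaluation, or `NULL`.
#' @return list with `frame_metrics`, `pixel_metrics` (two-step),
#'   `pixel_metrics_onestep`, `dice`, `dice_onestep`, the trained
#'   `detector`, `segmenter`, `segmenter_onestep`, per-test-pullback
#'   `bundles`, and the held-out `test` data (pullbacks, truths,
#'   preprocessed stacks).
#' @export
run_phantom_study <- function(seed = 1L, n_train = 4L, n_test = 2L,
                              roi_depth_px = 48L, crf = crf_params()) {
  n_all <- n_train + n_test
  specs <- lapply(seq_len(n_all), function(i)
    phantom_study_spec(seed * 1000L + i))
  gen <- lapply(specs, generate_pullback)
  pre <- lapply(gen, function(g)
    preprocess_pullback(g$pullback, roi_depth_px = roi_depth_px))

  tr_idx <- seq_len(n_train - 1L)
  val_idx <- n_train
  te_idx <- n_train + seq_len(n_test)

  stacks <- lapply(pre, `[[`, "stack")
  labels <- lapply(gen, function(g) g$truth$frame_labels)

  detector <- train_detector(
    stacks[tr_idx], labels[tr_idx],
    stacks[val_idx], labels[val_idx],
    config = detector_config(conv_filters = c(4L, 8L, 8L),
                             kernel = c(3L, 3L, 3L), fc1_units = 16L,
                             dropout_rate = 0.25),
    train_cfg = train_config(max_epochs = 12L, patience = 5L,
                             batch_size = 8L, epoch_repeats = 4L,
                             seed = seed + 1L))

  aligned_truth <- lapply(seq_len(n_all), function(i)
    align_truth_masks(gen[[i]]$truth, pre[[i]]$contexts, roi_depth_px))

  gather_frames <- function(idx, lesion_only) {
    fr <- list(); mk <- list()
    for (i in idx) {
      keep <- if (lesion_only) which(labels[[i]] == 1L)
              else seq_along(labels[[i]])
      for (f in keep) {
        fr[[length(fr) + 1]] <- stacks[[i]][f, , ]
        mk[[length(mk) + 1]] <- aligned_truth[[i]][f, , ]
      }
    }
    n <- length(fr)
    d <- dim(fr[[1]])
    frames <- array(0, c(n, d[1], d[2]))
    masks <- array(0L, c(n, d[1], d[2]))
    for (k in seq_len(n)) {
      frames[k, , ] <- fr[[k]]
      masks[k, , ] <- mk[[k]]
    }
    list(frames = frames, masks = masks)
  }

  seg_cfg <- segmenter_config(stages = list(8L, 16L))
  seg_tc <- function(s, reps) train_config(max_epochs = 15L, patience = 5L,
                                           batch_size = 8L,
                                           epoch_repeats = reps, seed = s)
  tr_les <- gather_frames(tr_idx, TRUE)
  va_les <- gather_frames(val_idx, TRUE)
  segmenter <- train_segmenter(tr_les$frames, tr_les$masks,
                               va_les$frames, va_les$masks,
                               config = seg_cfg,
                               train_cfg = seg_tc(seed + 2L, 6L))

  tr_all <- gather_frames(tr_idx, FALSE)
  va_all <- gather_frames(val_idx, FALSE)
  segmenter_onestep <- train_segmenter(
    tr_all$frames, tr_all$masks, va_all$frames, va_all$masks,
    config = seg_cfg, train_cfg = seg_tc(seed + 3L, 2L),
    allow_empty = TRUE)

  eval_counts <- function(one_step) {
    fc <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    pc <- c(TP = 0, TN = 0, FP = 0, FN = 0)
    bundles <- list()
    for (i in te_idx) {
      b <- run_pipeline(gen[[i]]$pullback,
                        detector = if (one_step) NULL else detector,
                        segmenter = if (one_step) segmenter_onestep
                                    else segmenter,
                        roi_depth_px = roi_depth_px, crf = crf,
                        one_step = one_step, truth = gen[[i]]$truth)
      cf <- confusion_counts(b$frame_labels, gen[[i]]$truth$frame_labels,
                            "frame")
      cp <- confusion_counts(b$masks_aligned, aligned_truth[[i]], "pixel")
      fc <- fc + c(TP = cf$TP, TN = cf$TN, FP = cf$FP, FN = cf$FN)
      pc <- pc + c(TP = cp$TP, TN = cp$TN, FP = cp$FP, FN = cp$FN)
      bundles[[length(bundles) + 1]] <- b
    }
    as_counts <- function(v, g) structure(
      list(TP = v[["TP"]], TN = v[["TN"]], FP = v[["FP"]], FN = v[["FN"]],
           granularity = g), class = "confusion_counts")
    list(frame = as_counts(fc, "frame"), pixel = as_counts(pc, "pixel"),
         bundles = bundles)
  }

  two <- eval_counts(FALSE)
  one <- eval_counts(TRUE)
  list(frame_metrics = classification_metrics(two$frame),
       pixel_metrics = classification_metrics(two$pixel),
       pixel_metrics_onestep = classification_metrics(one$pixel),
       dice = classification_metrics(two$pixel)$f1,
       dice_onestep = classification_metrics(one$pixel)$f1,
       detector = detector, segmenter = segmenter,
       segmenter_onestep = segmenter_onestep,
       bundles = two$bundles, bundles_onestep = one$bundles,
       test = list(gen = gen[te_idx], pre = pre[te_idx],
                   aligned_truth = aligned_truth[te_idx]),
       roi_depth_px = roi_depth_px)
}

#' Reproducibility study on repeat phantom pullbacks
#'
#' Renders the same lesion geometry twice with independent speckle
#' realizations (different seeds, identical lesion list), runs the
#' measurement chain (preprocessing with automatic guidewire and lumen
#' detection, truth-mask alignment, attribute quantification) on both,
#' and reports the per-lesion attribute differences and calcium scores.
#'
#' @param seed master seed.
#' @param roi_depth_px preprocessing ROI depth.
#' @return list with `attrs_a`, `attrs_b` (per-lesion attribute tables of
#'   the two renderings) and `diffs` (absolute differences).
#' @export
reproducibility_study <- function(seed = 1L, roi_depth_px = 48L) {
  base <- phantom_study_spec(seed * 1000L + 7L)
  spec_b <- base
  spec_b$seed <- base$seed + 500000L
  out <- lapply(list(base, spec_b), function(sp) {
    g <- generate_pullback(sp)
    pre <- preprocess_pullback(g$pullback, roi_depth_px = roi_depth_px)
    masks <- align_truth_masks(g$truth, pre$contexts, roi_depth_px)
    iv <- label_runs(g$truth$frame_labels)
    lesion_attributes(masks, iv, r_pitch_mm = g$pullback$r_pitch_mm,
                      frame_pitch_mm = g$pullback$frame_pitch_mm)
  })
  cols <- c("max_angle_deg", "mean_thickness_mm", "max_thickness_mm",
            "mean_depth_mm", "length_mm", "calcium_score")
  list(attrs_a = out[[1]], attrs_b = out[[2]],
       diffs = abs(out[[1]][cols] - out[[2]][cols]))
}
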