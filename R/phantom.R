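#' Synthetic polar IVOCT phantom pullbacks
#'
#' The phantom generator renders seeded polar-domain (r, theta) pullbacks that
#' reproduce the image properties the pipeline depends on: a bright lumen
#' border whose radius varies smoothly with angle and frame, exponential
#' depth attenuation beyond the border, multiplicative gamma speckle, a dark
#' wedge-shaped guidewire shadow, and signal-poor sharply delineated
#' calcified regions that persist over consecutive frames. Pixel-level
#' ground-truth masks and per-frame labels are returned alongside the images
#' so every downstream stage can be trained and evaluated without external
#' data.
#'
#' @param n_frames number of frames in the pullback.
#' @param n_alines number of A-lines (theta axis) per frame.
#' @param n_radial number of radial samples (r axis) per A-line.
#' @param lesions data.frame with one row per calcified lesion and columns
#'   `start_frame`, `end_frame` (inclusive, 1-based), `center_aline`,
#'   `half_width_alines` (angular half-extent; the wedge wraps circularly),
#'   `depth_px` (radial offset of the leading edge below the lumen) and
#'   `thickness_px` (radial extent, >= 1).
#' @param guidewire_center_aline,guidewire_width_alines location and angular
#'   width of the guidewire shadow; width 0 disables it.
#' @param speckle_scale standard deviation of the multiplicative gamma
#'   speckle (mean 1); 0 disables speckle.
#' @param attenuation_per_px exponential intensity decay per radial pixel
#'   beyond the lumen border.
#' @param lumen_base_px,lumen_amp_px mean lumen radius and angular
#'   modulation amplitude in pixels.
#' @param seed integer seed; all randomness in the generator flows from it
#'   through one RNG stream, so a fixed seed gives byte-identical output.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(n_frames,
                         n_alines = 448L,
                         n_radial = 968L,
                         lesions = NULL,
                         guidewire_center_aline = round(n_alines * 0.25),
                         guidewire_width_alines = round(n_alines * 0.045),
                         speckle_scale = 0.25,
                         attenuation_per_px = 0.008,
                         lumen_base_px = round(n_radial * 0.2),
                         lumen_amp_px = round(n_radial * 0.05),
                         seed = 1L) {
  if (is.null(lesions)) {
    lesions <- data.frame(start_frame = integer(), end_frame = integer(),
                          center_aline = integer(),
                          half_width_alines = integer(),
                          depth_px = integer(), thickness_px = integer())
  }
  spec <- structure(list(
    n_frames = as.integer(n_frames), n_alines = as.integer(n_alines),
    n_radial = as.integer(n_radial), lesions = lesions,
    guidewire_center_aline = as.integer(guidewire_center_aline),
    guidewire_width_alines = as.integer(guidewire_width_alines),
    speckle_scale = speckle_scale,
    attenuation_per_px = attenuation_per_px,
    lumen_base_px = as.integer(lumen_base_px),
    lumen_amp_px = as.integer(lumen_amp_px),
    seed = as.integer(seed)), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  assert_that(spec$n_frames >= 1 && spec$n_alines >= 8 && spec$n_radial >= 16,
              "phantom dimensions too small")
  assert_that(spec$speckle_scale >= 0, "speckle_scale must be >= 0")
  assert_that(spec$attenuation_per_px > 0, "attenuation_per_px must be > 0")
  les <- spec$lesions
  if (nrow(les)) {
    assert_that(all(les$start_frame >= 1) && all(les$end_frame <= spec$n_frames) &&
                  all(les$start_frame <= les$end_frame),
                "lesion frame interval outside [1, n_frames]")
    assert_that(all(les$center_aline >= 1) && all(les$center_aline <= spec$n_alines) &&
                  all(les$half_width_alines >= 0) &&
                  all(2 * les$half_width_alines + 1 <= spec$n_alines),
                "lesion angular extent outside A-line range")
    assert_that(all(les$thickness_px >= 1), "lesion thickness_px must be >= 1")
    assert_that(all(les$depth_px >= 0), "lesion depth_px must be >= 0")
    assert_that(all(les$depth_px + les$thickness_px <
                      spec$n_radial - spec$lumen_base_px - spec$lumen_amp_px),
                "lesion deeper than the radial field of view")
  }
  invisible(spec)
}

#' A polar-domain pullback
#'
#' Container for a stack of polar (r, theta) frames with acquisition
#' metadata. The frame pitch default 0.2 mm follows from a pullback speed of
#' 36 mm/s at 180 frames/s; the radial pitch default 0.005 mm from 200
#' pixels spanning 1 mm.
#'
#' @param frames numeric array `(n_frames, n_alines, n_radial)`, rows of each
#'   frame are A-lines ordered by acquisition angle, intensities in `[0, 1]`.
#' @param frame_pitch_mm longitudinal distance between consecutive frames.
#' @param r_pitch_mm radial pixel pitch.
#' @export
polar_pullback <- function(frames, frame_pitch_mm = 0.2, r_pitch_mm = 0.005) {
  assert_that(length(dim(frames)) == 3, "frames must be a 3D array")
  assert_that(frame_pitch_mm > 0 && r_pitch_mm > 0, "pitches must be > 0")
  assert_that(min(frames) >= 0, "intensities must be >= 0")
  structure(list(frames = frames, frame_pitch_mm = frame_pitch_mm,
                 r_pitch_mm = r_pitch_mm), class = "polar_pullback")
}

#' @export
print.polar_pullback <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("polar_pullback: %d frames x %d A-lines x %d radial px (frame pitch %g mm, r pitch %g mm)\n",
              d[1], d[2], d[3], x$frame_pitch_mm, x$r_pitch_mm))
  invisible(x)
}

#' @export
dim.polar_pullback <- function(x) dim(x$frames)

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", globalenv())
  on.exit(if (had) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# Circular sequence of A-line indices centred at `center` (1-based).
wrap_alines <- function(center, half_width, n) {
  ((center - half_width - 1):(center + half_width - 1)) %% n + 1L
}

# Intensity model shared by the renderer: clean (speckle-free) tissue
# profile as a function of depth d = r - lumen (in pixels).
tissue_profile <- function(d, att) {
  ifelse(d < 0, 0.03, ifelse(d < 2, 0.85, 0.6 * exp(-att * (d - 2))))
}

#' Generate a phantom pullback with ground truth
#'
#' Renders the pullback described by a [phantom_spec()]. Calcified regions
#' are rendered as signal-poor areas at 0.3 x the local background with a
#' 1-px bright leading edge (only when the lesion is at least 3 px thick),
#' giving the sharply delineated low-intensity appearance of calcium.
#' Intensities are quantized to 16 bits so that fixture round trips through
#' TIFF are lossless.
#'
#' @param spec a [phantom_spec()].
#' @return a list with components `pullback` (a [polar_pullback()]) and
#'   `truth` (class `phantom_truth`: `frame_labels`, binary `masks` of the
#'   same shape as the frames, per-frame per-A-line `lumen_index`, the
#'   guidewire A-line set, and the generating spec).
#' @export
generate_pullback <- function(spec) {
  validate_phantom_spec(spec)
  nf <- spec$n_frames; na <- spec$n_alines; nr <- spec$n_radial
  with_seed(spec$seed, {
    theta <- seq_len(na)
    phi1 <- runif(1, 0, 2 * pi); phi2 <- runif(1, 0, 2 * pi)
    amp2 <- spec$lumen_amp_px * runif(1, 0.2, 0.5)
    drift <- cumsum(rnorm(nf, 0, 0.3))
    drift <- drift - mean(drift)
    gw <- if (spec$guidewire_width_alines > 0)
      wrap_alines(spec$guidewire_center_aline,
                  (spec$guidewire_width_alines - 1L) %/% 2L, na)
    else integer(0)

    frames <- array(0, c(nf, na, nr))
    masks <- array(0L, c(nf, na, nr))
    lumen_index <- matrix(0L, nf, na)
    shape <- if (spec$speckle_scale > 0) 1 / spec$speckle_scale^2 else Inf
    r_idx <- seq_len(nr)

    for (f in seq_len(nf)) {
      lum <- spec$lumen_base_px +
        spec$lumen_amp_px * sin(2 * pi * theta / na + phi1) +
        amp2 * sin(4 * pi * theta / na + phi2) + drift[f]
      lum <- pmax(4L, as.integer(round(lum)))
      lumen_index[f, ] <- lum
      dmat <- outer(-lum, r_idx, `+`)            # depth = r - lumen
      img <- tissue_profile(dmat, spec$attenuation_per_px)

      les <- spec$lesions
      if (nrow(les)) for (k in seq_len(nrow(les))) {
        if (f < les$start_frame[k] || f > les$end_frame[k]) next
        al <- wrap_alines(les$center_aline[k], les$half_width_alines[k], na)
        al <- setdiff(al, gw)                    # no calcium in the shadow
        if (!length(al)) next
        d0 <- les$depth_px[k]; th <- les$thickness_px[k]
        sel <- dmat[al, , drop = FALSE]
        inside <- sel >= d0 & sel < d0 + th
        border <- th >= 3 & sel == d0
        sub <- img[al, , drop = FALSE]
        sub[inside] <- 0.3 * sub[inside]
        if (any(border)) sub[border] <- pmin(1, sub[border] / 0.3 * 1.2)
        img[al, ] <- sub
        mm <- masks[f, , ]
        msub <- mm[al, , drop = FALSE]
        msub[inside] <- 1L
        mm[al, ] <- msub
        masks[f, , ] <- mm
      }

      if (length(gw)) {
        shadow <- img[gw, , drop = FALSE]
        shadow[, r_idx > 6] <- 0.015
        img[gw, ] <- shadow
        masks[f, gw, ] <- 0L
      }

      if (is.finite(shape)) {
        noise <- matrix(rgamma(na * nr, shape = shape, rate = shape), na, nr)
        img <- img * noise
      }
      frames[f, , ] <- pmin(pmax(img, 0), 1)
    }
    frames <- round(frames * 65535) / 65535     # 16-bit grid, lossless TIFF
    labels <- as.integer(apply(masks, 1, function(m) any(m > 0)))
    truth <- structure(list(frame_labels = labels, masks = masks,
                            lumen_index = lumen_index,
                            guidewire_alines = gw, spec = spec),
                       class = "phantom_truth")
    list(pullback = polar_pullback(frames), truth = truth)
  })
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %d frames, %d calcification frames, %d guidewire A-lines\n",
              length(x$frame_labels), sum(x$frame_labels),
              length(x$guidewire_alines)))
  invisible(x)
}

#' Write and read phantom fixtures
#'
#' `write_fixture()` stores a phantom pullback and its truth as a pair of
#' multi-frame TIFF stacks (16-bit images, 8-bit masks) plus a JSON manifest
#' holding the generating spec, seed, truth vectors and MD5 checksums.
#' `read_fixture()` loads it back, verifying checksums first.
#'
#' @param pullback,truth as returned by [generate_pullback()].
#' @param directory output directory, created if needed.
#' @return `write_fixture()` the manifest path; `read_fixture()` a list with
#'   `pullback` and `truth` identical to what was written.
#' @export
write_fixture <- function(pullback, truth, directory) {
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(directory, "images.tiff")
  msk_path <- file.path(directory, "masks.tiff")
  write_stack(pullback$frames, img_path, bits = 16L)
  write_stack(truth$masks, msk_path, bits = 8L)
  manifest <- list(
    spec = truth$spec[setdiff(names(truth$spec), "lesions")],
    lesions = truth$spec$lesions,
    seed = truth$spec$seed,
    frame_pitch_mm = pullback$frame_pitch_mm,
    r_pitch_mm = pullback$r_pitch_mm,
    frame_labels = truth$frame_labels,
    lumen_index = truth$lumen_index,
    guidewire_alines = truth$guidewire_alines,
    md5 = list(images = unname(tools::md5sum(img_path)),
               masks = unname(tools::md5sum(msk_path))))
  man_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  man_path
}

#' @rdname write_fixture
#' @export
read_fixture <- function(directory) {
  man_path <- file.path(directory, "manifest.json")
  assert_that(file.exists(man_path), paste("no manifest at", man_path))
  man <- jsonlite::read_json(man_path, simplifyVector = TRUE)
  img_path <- file.path(directory, "images.tiff")
  msk_path <- file.path(directory, "masks.tiff")
  for (p in c(images = img_path, masks = msk_path)) {
    key <- if (identical(p, img_path)) "images" else "masks"
    assert_that(identical(unname(tools::md5sum(p)), man$md5[[key]]),
                paste("checksum mismatch for", p))
  }
  frames <- read_stack(img_path)
  masks_num <- read_stack(msk_path)
  masks <- array(as.integer(round(masks_num)), dim(masks_num))
  sp <- man$spec
  spec <- phantom_spec(sp$n_frames, sp$n_alines, sp$n_radial,
                       lesions = as.data.frame(man$lesions),
                       guidewire_center_aline = sp$guidewire_center_aline,
                       guidewire_width_alines = sp$guidewire_width_alines,
                       speckle_scale = sp$speckle_scale,
                       attenuation_per_px = sp$attenuation_per_px,
                       lumen_base_px = sp$lumen_base_px,
                       lumen_amp_px = sp$lumen_amp_px, seed = sp$seed)
  truth <- structure(list(
    frame_labels = as.integer(man$frame_labels), masks = masks,
    lumen_index = matrix(as.integer(man$lumen_index),
                         nrow = sp$n_frames, ncol = sp$n_alines),
    guidewire_alines = as.integer(man$guidewire_alines), spec = spec),
    class = "phantom_truth")
  list(pullback = polar_pullback(frames, man$frame_pitch_mm, man$r_pitch_mm),
       truth = truth)
}
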