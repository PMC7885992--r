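#' Multi-frame TIFF stack I/O
#'
#' Thin wrappers over the tiff package for the `(n_frames, n_alines,
#' n_radial)` arrays used throughout: each frame is stored as one grayscale
#' TIFF directory with A-lines as image rows.
#'
#' @param stack numeric array `(n_frames, rows, cols)` with values in
#'   `[0, 1]`.
#' @param path output file.
#' @param bits bits per sample, 8 or 16.
#' @return `write_stack()` the path invisibly; `read_stack()` the array.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  assert_that(length(dim(stack)) == 3, "stack must be a 3D array")
  assert_that(bits %in% c(8L, 16L), "bits must be 8 or 16")
  assert_that(min(stack) >= 0 && max(stack) <= 1,
              "stack values must lie in [0, 1]")
  storage.mode(stack) <- "double"
  frames <- lapply(seq_len(dim(stack)[1]), function(f) stack[f, , ])
  ok <- try(tiff::writeTIFF(frames, path, bits.per.sample = bits,
                            compression = "none"), silent = TRUE)
  if (inherits(ok, "try-error"))
    stop("failed to write TIFF stack: ", path, call. = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @export
read_stack <- function(path) {
  assert_that(file.exists(path), paste("no such file:", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  out <- array(0, c(length(frames), nrow(frames[[1]]), ncol(frames[[1]])))
  for (f in seq_along(frames)) out[f, , ] <- frames[[f]]
  out
}

# Read/write binary mask stacks (stored 8-bit, values 0/1).
write_mask_stack <- function(masks, path) {
  write_stack(array(as.numeric(masks > 0), dim(masks)), path, bits = 8L)
}

read_mask_stack <- function(path) {
  m <- read_stack(path)
  array(as.integer(m > 0.5), dim(m))
}
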