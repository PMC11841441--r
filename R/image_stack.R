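#' Multi-frame image stack with physical metadata
#'
#' The common carrier for every image pipeline in the package: a stack of
#' grayscale frames together with the pixel size and (for time series) the
#' frame interval. Frames are stored as a numeric `rows x cols x n_frames`
#' array with intensities in `[0, 1]` (the 16-bit grid `k/65535` when written
#' by the synthetic generators). Pixel coordinates throughout the package are
#' 1-based `(row, col)`.
#'
#' @param frames numeric array `rows x cols x n_frames`, or a matrix for a
#'   single frame, intensities in `[0, 1]`.
#' @param pixel_size physical size of one pixel, micrometres per pixel (> 0).
#' @param frame_interval time between consecutive frames in seconds, or `NA`
#'   for stacks that are not a time series (e.g. multi-channel snapshots).
#' @param channels optional character vector naming the frames when the third
#'   dimension indexes channels rather than time (e.g.
#'   `c("live", "dead", "nuclei")`).
#' @param metadata optional named list of extra metadata; stored verbatim and
#'   round-tripped through the JSON sidecar.
#'
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(frames, pixel_size, frame_interval = NA_real_,
                        channels = NULL, metadata = list()) {
  if (is.matrix(frames)) frames <- array(frames, dim = c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L) {
    stopf("frames must be a rows x cols x n_frames array")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || is.na(pixel_size) ||
      pixel_size <= 0) {
    stopf("pixel_size must be a single positive number (micrometres/pixel)")
  }
  if (!is.null(channels) && length(channels) != dim(frames)[3L]) {
    stopf("channels must name every frame (%d given, %d frames)",
          length(channels), dim(frames)[3L])
  }
  structure(
    list(frames = frames, pixel_size = pixel_size,
         frame_interval = frame_interval, channels = channels,
         metadata = metadata),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d x %d px, %d frame(s), %.3g um/px", d[1L], d[2L],
              d[3L], x$pixel_size))
  if (!is.na(x$frame_interval)) cat(sprintf(", dt = %.3g s", x$frame_interval))
  if (!is.null(x$channels)) cat(" [", paste(x$channels, collapse = ", "), "]")
  cat("\n")
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3L]

get_frame <- function(stack, i) stack$frames[, , i]

#' Write an image stack as multi-page TIFF plus JSON sidecar
#'
#' Pixels go to a 16-bit multi-page TIFF; pixel size, frame interval, channel
#' names and any extra metadata go to `<path>.json` next to it, so a stack
#' round-trips losslessly with [read_image_stack()].
#'
#' @param stack an [image_stack()].
#' @param path output TIFF file path (the sidecar is written at `paste0(path, ".json")`).
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  pages <- lapply(seq_len(n_frames(stack)), function(i) get_frame(stack, i))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  side <- list(
    pixel_size = stack$pixel_size,
    frame_interval = stack$frame_interval,
    channels = stack$channels,
    metadata = stack$metadata
  )
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF file path; the JSON sidecar `<path>.json` must exist and
#'   carry at least `pixel_size`.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("missing metadata sidecar: %s", sidecar)
  side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(side$pixel_size)) {
    stopf("malformed metadata in %s: missing required field 'pixel_size'", sidecar)
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  frames <- array(0, dim = c(dim(pages[[1L]])[1:2], length(pages)))
  for (i in seq_along(pages)) frames[, , i] <- pages[[i]]
  fi <- side$frame_interval
  if (is.null(fi)) fi <- NA_real_
  image_stack(frames, pixel_size = side$pixel_size, frame_interval = fi,
              channels = side$channels,
              metadata = if (is.null(side$metadata)) list() else side$metadata)
}

# mean intensity inside a circular ROI, centred at (row, col) px, radius px
roi_mean_disk <- function(frame, center, radius) {
  d <- dim(frame)
  if (center[1L] - radius < 1 || center[1L] + radius > d[1L] ||
      center[2L] - radius < 1 || center[2L] + radius > d[2L]) {
    stopf("ROI (center %.1f,%.1f radius %.1f px) extends outside the %dx%d image",
          center[1L], center[2L], radius, d[1L], d[2L])
  }
  rows <- matrix(seq_len(d[1L]), d[1L], d[2L])
  cols <- matrix(seq_len(d[2L]), d[1L], d[2L], byrow = TRUE)
  mean(frame[(rows - center[1L])^2 + (cols - center[2L])^2 <= radius^2])
}

# mean intensity inside a rectangular ROI given as list(rows = i1:i2, cols = j1:j2)
roi_mean_rect <- function(frame, roi) {
  mean(frame[roi$rows, roi$cols])
}
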