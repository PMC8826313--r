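# Image stacks: the raw reflectance movies and reference images.

#' Construct an image stack
#'
#' A stack holds a reflectance movie as a 3-D array indexed
#' `[frame, row, col]` in arbitrary camera units, together with the
#' acquisition metadata the pipeline needs. Pixel coordinates are 0-based
#' `(row, col)` with row increasing downward; physical distances are
#' obtained through `pixel_scale` (micrometers per pixel). When both
#' per-frame timestamps and a nominal frame rate are available, the
#' timestamps are authoritative.
#'
#' @param frames 3-D numeric array `[frame, row, col]`.
#' @param frame_rate nominal acquisition rate, Hz.
#' @param timestamps per-frame times in seconds, strictly increasing;
#'   defaults to `(0:(n-1))/frame_rate`.
#' @param wavelength_tag `"red"` (signal acquisition) or `"green"`
#'   (vasculature reference).
#' @param pixel_scale micrometers per pixel.
#' @return an object of class `image_stack`.
#' @export
image_stack <- function(frames, frame_rate, timestamps = NULL,
                        wavelength_tag = c("red", "green"),
                        pixel_scale = 6) {
  wavelength_tag <- match.arg(wavelength_tag)
  if (length(dim(frames)) != 3)
    isi_stop("isimap_stack_error", "frames must be a 3-D array [frame, row, col]")
  if (!is.numeric(frame_rate) || length(frame_rate) != 1 || frame_rate <= 0)
    isi_stop("isimap_config_error", "missing or invalid frame_rate (must be a positive scalar)")
  n <- dim(frames)[1]
  if (is.null(timestamps)) timestamps <- (seq_len(n) - 1) / frame_rate
  if (length(timestamps) != n)
    isi_stop("isimap_stack_error",
             "frame count (%d) does not match timestamp count (%d)", n, length(timestamps))
  if (n > 1 && any(diff(timestamps) <= 0))
    isi_stop("isimap_stack_error", "timestamps must be strictly increasing")
  if (pixel_scale <= 0)
    isi_stop("isimap_stack_error", "pixel_scale must be positive")
  structure(list(frames = frames, frame_rate = frame_rate,
                 timestamps = as.numeric(timestamps),
                 wavelength_tag = wavelength_tag,
                 pixel_scale = pixel_scale),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frames of %d x %d px, %.3g Hz, %s light, %.3g um/px\n",
              d[1], d[2], d[3], x$frame_rate, x$wavelength_tag, x$pixel_scale))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[1]

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Frames are written one per TIFF page. Integer-valued data (camera
#' counts) are stored losslessly as 16-bit samples; other data are stored
#' as 32-bit float after an affine rescale into `[0, 1]` whose offset and
#' scale are recorded in the sidecar. The sidecar (`<path>.json`) carries
#' frame rate, pixel scale, wavelength tag, timestamps, and the encoding.
#'
#' @param stack an `image_stack`.
#' @param path output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  fr <- stack$frames
  is_int <- all(is.finite(fr)) && all(fr == round(fr)) && min(fr) >= 0 && max(fr) <= 65535
  meta <- list(frame_rate = stack$frame_rate,
               pixel_scale = stack$pixel_scale,
               wavelength_tag = stack$wavelength_tag,
               timestamps = stack$timestamps)
  if (is_int) {
    pages <- lapply(seq_len(dim(fr)[1]), function(i) fr[i, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
    meta$encoding <- list(kind = "uint16", offset = 0, scale = 1)
  } else {
    lo <- min(fr, na.rm = TRUE); hi <- max(fr, na.rm = TRUE)
    scale <- if (hi > lo) hi - lo else 1
    pages <- lapply(seq_len(dim(fr)[1]), function(i) (fr[i, , ] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    meta$encoding <- list(kind = "float", offset = lo, scale = scale)
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()]
#'
#' @param path path to the multi-page TIFF; `<path>.json` must exist and
#'   carry at least the frame rate.
#' @return an `image_stack`.
#' @export
read_stack <- function(path) {
  if (!file.exists(path))
    isi_stop("isimap_read_error", "stack file not found: %s", path)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    isi_stop("isimap_config_error", "missing sidecar metadata file: %s", side)
  meta <- jsonlite::fromJSON(side)
  if (is.null(meta$frame_rate))
    isi_stop("isimap_config_error", "sidecar is missing required field 'frame_rate'")
  enc <- meta$encoding %||% list(kind = "uint16", offset = 0, scale = 1)
  # as.is recovers raw 16-bit counts; float pages are already stored on
  # [0, 1] and must not be rescaled by the bit depth
  pages <- tiff::readTIFF(path, all = TRUE, as.is = (enc$kind == "uint16"))
  if (!is.list(pages)) pages <- list(pages)
  h <- nrow(pages[[1]]); w <- ncol(pages[[1]])
  fr <- array(0, dim = c(length(pages), h, w))
  for (i in seq_along(pages)) {
    p <- pages[[i]]
    fr[i, , ] <- if (enc$kind == "uint16") p else p * enc$scale + enc$offset
  }
  image_stack(fr, frame_rate = meta$frame_rate,
              timestamps = meta$timestamps,
              wavelength_tag = meta$wavelength_tag %||% "red",
              pixel_scale = meta$pixel_scale %||% 6)
}

#' Write a single image (e.g. vasculature reference) to TIFF
#'
#' @param img numeric matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  lo <- min(img, na.rm = TRUE); hi <- max(img, na.rm = TRUE)
  scale <- if (hi > lo) hi - lo else 1
  tiff::writeTIFF((img - lo) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(list(encoding = list(kind = "float", offset = lo, scale = scale)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a single image written by [write_image()]
#' @param path TIFF path.
#' @return numeric matrix.
#' @export
read_image <- function(path) {
  if (!file.exists(path))
    isi_stop("isimap_read_error", "image file not found: %s", path)
  p <- tiff::readTIFF(path)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    enc <- jsonlite::fromJSON(side)$encoding
    p <- p * enc$scale + enc$offset
  }
  p
}
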