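# Preprocessing: reflectance -> absorbance, and rigid translation
# registration of blocks to the vasculature reference.

#' Convert reflectance to absorbance change (modified Beer-Lambert law)
#'
#' Computes `dA(x, y, t) = log10(Ia(x, y, t) / I0(x, y))` where `I0` is
#' the per-pixel mean over the baseline window (by default the first 5 s
#' of the stack, before stimulus onset). With this sign convention the
#' stimulus-evoked reflectance decrease appears as negative `dA`; set
#' `conventional_sign = TRUE` for `-log10`, the chemist's absorbance.
#'
#' @param stack an [image_stack()].
#' @param baseline_window length-2 numeric, seconds (relative to the
#'   first timestamp) over which to average the baseline.
#' @param frames optional integer vector restricting the output to a
#'   frame range (e.g. one trial); default all frames.
#' @param conventional_sign flip the sign to `-log10(Ia/I0)`.
#' @return a list of class `absorbance_stack`: `delta_a` (3-D array),
#'   `i0` (matrix), `frame_rate`, `timestamps`, `frames` (the source
#'   frame indices), `sign` and `n_masked` (pixels with non-positive
#'   baseline, set to `NaN`).
#' @export
compute_absorbance <- function(stack, baseline_window = c(0, 5), frames = NULL,
                               conventional_sign = FALSE) {
  ts <- stack$timestamps - stack$timestamps[1]
  base_idx <- which(ts >= baseline_window[1] & ts < baseline_window[2])
  if (!length(base_idx))
    isi_stop("isimap_baseline_error",
             "baseline window [%g, %g) s contains no frames",
             baseline_window[1], baseline_window[2])
  i0 <- apply(stack$frames[base_idx, , , drop = FALSE], c(2, 3), mean)
  bad <- !(i0 > 0)
  if (any(bad)) {
    isi_warn("%d pixel(s) with non-positive baseline masked to NaN", sum(bad))
    i0[bad] <- NA_real_
  }
  if (is.null(frames)) frames <- seq_len(n_frames(stack))
  da <- sweep(log10(stack$frames[frames, , , drop = FALSE]), c(2, 3), log10(i0), `-`)
  if (conventional_sign) da <- -da
  structure(list(delta_a = da, i0 = i0, frame_rate = stack$frame_rate,
                 pixel_scale = stack$pixel_scale,
                 timestamps = stack$timestamps[frames], frames = frames,
                 sign = if (conventional_sign) "-log10(Ia/I0)" else "log10(Ia/I0)",
                 n_masked = sum(bad)),
            class = "absorbance_stack")
}

#' @export
print.absorbance_stack <- function(x, ...) {
  d <- dim(x$delta_a)
  cat(sprintf("<absorbance_stack> %d frames of %d x %d px, sign %s\n",
              d[1], d[2], d[3], x$sign))
  invisible(x)
}

# normalized cross-correlation of two equal-size images at one integer
# shift (moving shifted by (dy, dx) relative to reference), over the
# overlap region
ncc_at_shift <- function(moving, reference, dy, dx) {
  H <- nrow(reference); W <- ncol(reference)
  ry <- max(1, 1 + dy):min(H, H + dy); if (length(ry) < 1) return(NA_real_)
  rx <- max(1, 1 + dx):min(W, W + dx)
  my <- ry - dy; mx <- rx - dx
  a <- reference[ry, rx]; b <- moving[my, mx]
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(NA_real_)
  sum(a * b) / den
}

#' Register an image to a reference by integer-pixel translation
#'
#' Searches shifts within `max_shift` pixels for the translation that
#' maximizes the normalized cross-correlation over the overlap region.
#' No rotation or scaling is applied. Shifts with less than 50% overlap
#' are not considered.
#'
#' @param moving,reference numeric matrices at the same pixel scale.
#' @param max_shift search radius, pixels.
#' @param min_peak correlation floor; below it the block is flagged as an
#'   alignment failure rather than silently mis-registered.
#' @return a list: `shift = c(dy, dx)` (add to moving-image coordinates
#'   to land in reference coordinates), `peak` correlation, `ok` flag,
#'   and `registered` (the moving image resampled into the reference
#'   frame, `NA` where uncovered).
#' @export
register_translate <- function(moving, reference, max_shift = 15, min_peak = 0.2) {
  if (!all(dim(moving) == dim(reference)))
    isi_stop("isimap_align_error", "images must have equal dimensions")
  H <- nrow(reference); W <- ncol(reference)
  shifts <- expand.grid(dy = -max_shift:max_shift, dx = -max_shift:max_shift)
  keep <- (H - abs(shifts$dy)) * (W - abs(shifts$dx)) >= 0.5 * H * W
  shifts <- shifts[keep, ]
  cc <- mapply(function(dy, dx) ncc_at_shift(moving, reference, dy, dx),
               shifts$dy, shifts$dx)
  best <- which.max(cc)
  shift <- c(dy = shifts$dy[best], dx = shifts$dx[best])
  peak <- cc[best]
  ok <- is.finite(peak) && peak >= min_peak
  if (!ok)
    isi_warn("registration peak %.3f below floor %.3f: block flagged for exclusion",
             peak, min_peak)
  list(shift = shift, peak = peak, ok = ok,
       registered = apply_shift(moving, shift))
}

#' Apply an integer translation to an image or map
#'
#' @param img numeric matrix.
#' @param shift `c(dy, dx)`; the content moves down/right for positive
#'   values, exposing `NA` at the opposite border.
#' @return shifted matrix, same size.
#' @export
apply_shift <- function(img, shift) {
  dy <- round(shift[1]); dx <- round(shift[2])
  H <- nrow(img); W <- ncol(img)
  out <- matrix(NA_real_, H, W)
  ry <- max(1, 1 + dy):min(H, H + dy)
  rx <- max(1, 1 + dx):min(W, W + dx)
  out[ry, rx] <- img[ry - dy, rx - dx, drop = FALSE]
  out
}
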