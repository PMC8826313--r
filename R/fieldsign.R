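# Visual field sign: smoothing, gradient-angle sign maps, segmentation of
# signed cortical areas, and binned contour centroids.

# separable 1-D Gaussian kernel, truncated at 6 sigma so the discarded
# mass (~2e-9 at sigma = 4) is negligible against the tolerances used
gauss_kernel <- function(sigma) {
  r <- ceiling(6 * sigma)
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  k / sum(k)
}

# 1-D convolution along rows (dim = 1) or columns (dim = 2) with zero
# padding, vectorized as a sum of shifted copies
conv_sep <- function(m, k, dim) {
  r <- (length(k) - 1) / 2
  out <- matrix(0, nrow(m), ncol(m))
  for (o in -r:r) {
    w <- k[o + r + 1]
    n <- if (dim == 1) nrow(m) else ncol(m)
    lo <- max(1, 1 - o); hi <- min(n, n - o)
    if (lo > hi) next  # shift larger than the map: no overlap
    src <- lo:hi
    if (dim == 1) {
      out[src + o, ] <- out[src + o, ] + w * m[src, ]
    } else {
      out[, src + o] <- out[, src + o] + w * m[, src]
    }
  }
  out
}

#' NaN-aware Gaussian smoothing of a map
#'
#' 2-D Gaussian filtering in which `NaN` pixels contribute no kernel
#' mass: the smoothed value is the weighted mean of the *finite*
#' neighbours (normalized convolution). `sigma = 0` is the identity.
#' Borders are renormalized the same way, so a constant map is exactly
#' unchanged.
#'
#' @param map numeric matrix, a [retinotopic_map()], or a [vfs_map].
#' @param sigma Gaussian SD in pixels.
#' @return same type as the input, smoothed.
#' @export
smooth_map <- function(map, sigma) {
  if (inherits(map, "retinotopic_map")) {
    map$values <- smooth_map(map$values, sigma); return(map)
  }
  if (inherits(map, "phase_map")) {
    # complex-field smoothing: real and imaginary parts separately, which
    # is an amplitude-weighted phase average (noise pixels carry little
    # amplitude and therefore little weight)
    z <- matrix(complex(real = smooth_map(Re(map$z), sigma),
                        imaginary = smooth_map(Im(map$z), sigma)),
                nrow(map$z), ncol(map$z))
    map$z <- z; return(map)
  }
  if (inherits(map, "vfs_map")) {
    map$s <- smooth_map(map$s, sigma); return(map)
  }
  if (sigma < 0) isi_stop("isimap_config_error", "sigma must be non-negative")
  if (sigma == 0) return(map)
  k <- gauss_kernel(sigma)
  finite <- is.finite(map)
  m0 <- map; m0[!finite] <- 0
  num <- conv_sep(conv_sep(m0, k, 1), k, 2)
  den <- conv_sep(conv_sep(finite * 1, k, 1), k, 2)
  out <- num / den
  out[!finite | den == 0] <- NaN
  out
}

# gradient by central differences, falling back to one-sided where a
# neighbour is missing (border or NaN); returns list(dr, dc)
map_gradient <- function(m) {
  down <- apply_shift(m, c(-1, 0))   # value at row + 1
  up <- apply_shift(m, c(1, 0))      # value at row - 1
  right <- apply_shift(m, c(0, -1))
  left <- apply_shift(m, c(0, 1))
  g1 <- function(plus, minus) {
    ok_p <- is.finite(plus); ok_m <- is.finite(minus)
    d <- (plus - minus) / 2
    d[ok_p & !ok_m] <- (plus - m)[ok_p & !ok_m]
    d[!ok_p & ok_m] <- (m - minus)[!ok_p & ok_m]
    d[!ok_p & !ok_m] <- NaN
    d[!is.finite(m)] <- NaN
    d
  }
  list(dr = g1(down, up), dc = g1(right, left))
}

#' Compute the visual field sign map
#'
#' Both retinotopic maps are smoothed at `sigma`, gradient direction
#' angles are taken in image coordinates (`theta = atan2(d/drow,
#' d/dcol)`; row increases downward, column rightward), and the field
#' sign is the sine of the angle between the azimuth and elevation
#' gradients:
#' `S = sin(theta_az - theta_el) in [-1, 1]`. `S` flips sign across
#' borders where the retinotopic representation mirrors, which is what
#' delineates V1 and the higher visual areas.
#'
#' @param azimuth,elevation [retinotopic_map()]s of the two axes, same
#'   shape and pixel scale.
#' @param sigma Gaussian smoothing width in pixels (3-5 px is the
#'   useful range at 6 um/px).
#' @param post_sigma Gaussian smoothing of the sign map itself. Where the
#'   retinotopy is coherent `S` is locally constant and unaffected; where
#'   it is noise-driven the per-pixel signs are incoherent and average
#'   toward 0, so this suppresses spurious sign patches outside visual
#'   cortex. 0 disables it.
#' @return an object of class `vfs_map`: `s` (matrix in `[-1, 1]`,
#'   `NaN` where either source is `NaN` or a gradient vanishes),
#'   `sigma`, `pixel_scale`, `n_trials`.
#' @export
visual_field_sign <- function(azimuth, elevation, sigma = 4, post_sigma = 4) {
  if (!identical(dim(azimuth$values), dim(elevation$values)))
    isi_stop("isimap_fieldsign_error", "azimuth and elevation maps differ in shape")
  az <- smooth_map(azimuth$values, sigma)
  el <- smooth_map(elevation$values, sigma)
  if (!any(is.finite(az) & is.finite(el)))
    isi_stop("isimap_fieldsign_error", "maps have no jointly finite pixels")
  ga <- map_gradient(az); ge <- map_gradient(el)
  na <- sqrt(ga$dr^2 + ga$dc^2); ne <- sqrt(ge$dr^2 + ge$dc^2)
  s <- (ga$dr * ge$dc - ga$dc * ge$dr) / (na * ne)
  s[na == 0 | ne == 0] <- NaN
  s <- smooth_map(s, post_sigma)
  structure(list(s = s, sigma = sigma, pixel_scale = azimuth$pixel_scale,
                 n_trials = azimuth$n_trials + elevation$n_trials),
            class = "vfs_map")
}

#' @export
print.vfs_map <- function(x, ...) {
  cat(sprintf("<vfs_map> %d x %d px, sigma %g px, %d trial(s)\n",
              nrow(x$s), ncol(x$s), x$sigma, x$n_trials))
  invisible(x)
}

# label 4-connected components of a logical mask; returns an integer
# matrix (0 = background)
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      idx <- queue
      queue <- integer(0)
      for (d in list(-1L, 1L, -H, H)) {
        nb <- idx + d
        # stay on the grid; +/-1 moves must not wrap across column ends
        ok <- nb >= 1L & nb <= H * W
        if (abs(d) == 1L) ok <- ok & ((idx - 1L) %/% H == (nb - 1L) %/% H)
        nb <- nb[ok]
        nb <- nb[mask[nb] & lab[nb] == 0L]
        if (length(nb)) { lab[nb] <- cur; queue <- c(queue, nb) }
      }
      queue <- unique(queue)
    }
  }
  lab
}

# fill interior holes of a logical mask (background components that do
# not touch the image border)
fill_holes <- function(mask) {
  bg <- label_components(!mask)
  H <- nrow(mask); W <- ncol(mask)
  border_labels <- unique(c(bg[1, ], bg[H, ], bg[, 1], bg[, W]))
  mask | (bg != 0L & !(bg %in% border_labels))
}

#' Segment signed cortical areas from a field-sign map
#'
#' Thresholds `|S|`, splits the surviving pixels into 4-connected
#' components of uniform sign, drops components smaller than `min_size`,
#' and fills interior holes. The recipe and all its parameters are
#' exposed because area definition from a VFS map is ultimately a
#' user-controlled step.
#'
#' @param vfs a [visual_field_sign()] map.
#' @param threshold minimum `|S|` for a pixel to seed an area, in (0, 1).
#' @param min_size minimum component size in pixels.
#' @return a list of area labels, each a list with `name` (`"A1"`, ...,
#'   ordered by size), `sign`, `mask`, `area_px`, `centroid_px`
#'   (0-based `(row, col)`), and `centroid_um`. An empty list is a valid
#'   result.
#' @export
segment_areas <- function(vfs, threshold = 0.3, min_size = 100) {
  if (threshold <= 0 || threshold >= 1)
    isi_stop("isimap_config_error", "threshold must lie in (0, 1)")
  s <- vfs$s
  out <- list()
  for (sgn in c(1, -1)) {
    cand <- is.finite(s) & (sgn * s >= threshold)
    lab <- label_components(cand)
    if (!max(lab)) next
    for (l in seq_len(max(lab))) {
      m <- lab == l
      if (sum(m) < min_size) next
      m <- fill_holes(m)
      idx <- which(m, arr.ind = TRUE)
      cpx <- c(row = mean(idx[, 1]) - 1, col = mean(idx[, 2]) - 1)
      out[[length(out) + 1]] <- list(sign = sgn, mask = m, area_px = sum(m),
                                     centroid_px = cpx,
                                     centroid_um = cpx * vfs$pixel_scale)
    }
  }
  if (length(out)) {
    out <- out[order(-vapply(out, `[[`, 0, "area_px"))]
    for (i in seq_along(out)) out[[i]]$name <- paste0("A", i)
  }
  out
}

#' Match segmented areas to reference masks by overlap
#'
#' Pairs each reference mask with the segmented area that covers the
#' largest fraction of it (Dice-style overlap on the reference side).
#'
#' @param segments result of [segment_areas()].
#' @param reference_masks named list of logical matrices.
#' @param min_overlap minimum covered fraction of the reference mask for
#'   a match; below it the row reports `NA`.
#' @return a `data.frame`: `reference, segment, overlap, sign` (one row
#'   per reference mask; `segment`/`sign` are `NA` when unmatched).
#' @export
match_segments <- function(segments, reference_masks, min_overlap = 0.25) {
  rows <- lapply(names(reference_masks), function(nm) {
    ref <- reference_masks[[nm]]
    ov <- vapply(segments, function(sg) sum(sg$mask & ref) / sum(ref), numeric(1))
    if (length(ov) && max(ov) >= min_overlap) {
      k <- which.max(ov)
      data.frame(reference = nm, segment = segments[[k]]$name,
                 overlap = ov[k], sign = segments[[k]]$sign)
    } else data.frame(reference = nm, segment = NA_character_,
                      overlap = if (length(ov)) max(ov) else 0, sign = NA_real_)
  })
  do.call(rbind, rows)
}

#' Bin a retinotopic map into contour sections and their centroids
#'
#' Degree values are rounded half-up to the nearest multiple of `bin`
#' (10 degrees by default); each bin's centroid is the mean pixel
#' position of its members. Bins with fewer than 5 pixels are flagged
#' unreliable.
#'
#' @param map a [retinotopic_map()].
#' @param bin bin width, degrees.
#' @param mask optional logical matrix (e.g. an area mask from
#'   [segment_areas()]) restricting the analysis.
#' @return a `data.frame` (class `contour_set`): `bin_deg, n_px, row,
#'   col` (0-based pixel centroids), `row_um, col_um`, `reliable`.
#' @export
contours_and_centroids <- function(map, bin = 10, mask = NULL) {
  if (bin <= 0) isi_stop("isimap_config_error", "bin width must be positive")
  v <- map$values
  if (!is.null(mask)) v[!mask] <- NaN
  ok <- which(is.finite(v), arr.ind = TRUE)
  if (!nrow(ok))
    return(structure(data.frame(bin_deg = numeric(0), n_px = integer(0),
                                row = numeric(0), col = numeric(0),
                                row_um = numeric(0), col_um = numeric(0),
                                reliable = logical(0)),
                     class = c("contour_set", "data.frame"), bin = bin))
  bins <- round_half_up(v[ok] / bin) * bin
  agg <- tapply(seq_len(nrow(ok)), bins, function(i) {
    c(n = length(i), row = mean(ok[i, 1]) - 1, col = mean(ok[i, 2]) - 1)
  })
  m <- do.call(rbind, agg)
  res <- data.frame(bin_deg = as.numeric(names(agg)), n_px = as.integer(m[, "n"]),
                    row = m[, "row"], col = m[, "col"],
                    row_um = m[, "row"] * map$pixel_scale,
                    col_um = m[, "col"] * map$pixel_scale,
                    reliable = m[, "n"] >= 5)
  res <- res[order(res$bin_deg), ]
  rownames(res) <- NULL
  structure(res, class = c("contour_set", "data.frame"), bin = bin)
}
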