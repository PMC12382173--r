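#' Voxel label codes for the wash-out map
#'
#' `0` neutral, `1` wash-out (signal higher at the early timepoint),
#' `2` late enhancement (signal higher at the late timepoint).
#' @export
WASHOUT_LABELS <- c(NEUTRAL = 0L, WASHOUT = 1L, LATE_ENHANCEMENT = 2L)

#' Compute the signed wash-out percentage map
#'
#' For co-registered, intensity-normalized early/late volumes the map is
#' `percent = 100 * (early - late) / early` wherever the early signal is
#' positive, and 0 elsewhere. Positive values are wash-out (rapid contrast
#' clearance between 5 and 25 min), negative values late enhancement.
#' Voxels are labeled wash-out when `percent > epsilon`, late-enhancing
#' when `percent < -epsilon`, and neutral inside the dead-band, which
#' absorbs residual noise and normalization error.
#'
#' @param early_n,late_n normalized [volume3d()]s on a common grid.
#' @param epsilon classification dead-band in percent (>= 0; default 5).
#' @param provenance optional list recorded on the result (transform,
#'   normalization report, input ids).
#' @return An object of class `washout_map`: `percent` (3-D array),
#'   `labels` (integer 3-D array, see [WASHOUT_LABELS]), `epsilon`,
#'   `affine`, `provenance`.
#' @export
compute_map <- function(early_n, late_n, epsilon = 5, provenance = list()) {
  if (!same_grid(early_n, late_n))
    stop("early and late volumes must share grid and affine")
  if (!is.numeric(epsilon) || epsilon < 0)
    stop("epsilon must be a non-negative percentage")
  e <- early_n$values
  l <- late_n$values
  percent <- array(0, dim = dim(e))
  pos <- is.finite(e) & is.finite(l) & e > 0
  percent[pos] <- 100 * (e[pos] - l[pos]) / e[pos]
  labels <- array(WASHOUT_LABELS[["NEUTRAL"]], dim = dim(e))
  labels[percent > epsilon] <- WASHOUT_LABELS[["WASHOUT"]]
  labels[percent < -epsilon] <- WASHOUT_LABELS[["LATE_ENHANCEMENT"]]
  structure(list(percent = percent, labels = labels, epsilon = epsilon,
                 affine = early_n$affine, provenance = provenance),
            class = "washout_map")
}

#' @export
print.washout_map <- function(x, ...) {
  n <- tabulate(x$labels + 1L, nbins = 3L)
  cat(sprintf(paste0("<washout_map> %s voxels | wash-out %d, ",
                     "late-enhancement %d, neutral %d (epsilon = %g%%)\n"),
              paste(dim(x$percent), collapse = "x"), n[2], n[3], n[1],
              x$epsilon))
  invisible(x)
}

#' Red-green overlay of a wash-out map on a grayscale background
#'
#' Red encodes wash-out, green late enhancement, with a symmetric color
#' scale saturating at `saturation` percent; neutral voxels show the
#' plain grayscale background.
#'
#' @param map a [washout_map()][compute_map()].
#' @param background a [volume3d()] on the same grid (typically the early
#'   acquisition).
#' @param saturation percent value mapped to full color intensity.
#' @param alpha blend weight of the color layer over the background.
#' @return A 4-D array `dim x 3` of RGB values in `[0, 1]`.
#' @export
render_overlay <- function(map, background, saturation = 50, alpha = 0.6) {
  stopifnot(inherits(map, "washout_map"))
  if (!identical(dim(map$percent), dim(background$values)))
    stop("background grid does not match map")
  bg <- background$values
  rng <- range(bg, finite = TRUE)
  g <- if (diff(rng) > 0) (bg - rng[1]) / diff(rng) else bg * 0
  p <- map$percent
  red_w <- pmin(1, pmax(0, p) / saturation)
  grn_w <- pmin(1, pmax(0, -p) / saturation)
  red_w[map$labels != WASHOUT_LABELS[["WASHOUT"]]] <- 0
  grn_w[map$labels != WASHOUT_LABELS[["LATE_ENHANCEMENT"]]] <- 0
  w <- alpha * pmax(red_w, grn_w)
  out <- array(0, dim = c(dim(g), 3))
  out[, , , 1] <- g * (1 - w) + w * red_w
  out[, , , 2] <- g * (1 - w) + w * grn_w
  out[, , , 3] <- g * (1 - w)
  out
}

#' Write a QC montage of axial overlay slices as PNG
#'
#' @param map a [washout_map()][compute_map()].
#' @param background a [volume3d()] on the same grid.
#' @param path output PNG path.
#' @param slices axial slice indices (default: 6 evenly spaced).
#' @inheritParams render_overlay
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(map, background, path, slices = NULL,
                              saturation = 50, alpha = 0.6) {
  rgb <- render_overlay(map, background, saturation, alpha)
  d <- dim(map$percent)
  if (is.null(slices))
    slices <- unique(round(seq(d[3] * 0.2, d[3] * 0.8, length.out = 6)))
  tiles <- lapply(slices, function(k) {
    sl <- rgb[, , k, , drop = FALSE]
    # image row = y, flipped for radiological-style display
    aperm(sl[, rev(seq_len(d[2])), 1, , drop = TRUE], c(2, 1, 3))
  })
  montage <- do.call(abind3, tiles)
  png::writePNG(montage, path)
  invisible(path)
}

# minimal column-wise binding of equal-height RGB arrays
abind3 <- function(...) {
  parts <- list(...)
  h <- dim(parts[[1]])[1]
  out <- array(0, dim = c(h, sum(vapply(parts, function(p) dim(p)[2], 0L)), 3))
  at <- 0L
  for (p in parts) {
    w <- dim(p)[2]
    out[, at + seq_len(w), ] <- p
    at <- at + w
  }
  out
}

#' Write the percent and label maps as NIfTI
#'
#' @param map a [washout_map()][compute_map()].
#' @param percent_path,labels_path output NIfTI paths (either may be
#'   `NULL` to skip).
#' @return Invisibly, the paths written.
#' @export
write_map <- function(map, percent_path = NULL, labels_path = NULL) {
  if (!is.null(percent_path))
    write_volume(volume3d(map$percent, affine = map$affine), percent_path)
  if (!is.null(labels_path))
    write_volume(volume3d(map$labels + 0, affine = map$affine), labels_path)
  invisible(c(percent_path, labels_path))
}
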