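#' 3-D scalar volume with voxel-to-world affine
#'
#' Lightweight container for an image volume: a numeric 3-D array plus a
#' 4x4 affine mapping 0-based voxel indices to world coordinates in mm
#' (RAS+ convention). Acquisition metadata (subject id, acquisition time in
#' minutes post-injection) travels in `meta`.
#'
#' @param values numeric 3-D array of voxel values.
#' @param spacing voxel spacing in mm per axis (length 3), used when
#'   `affine` is not given.
#' @param origin world coordinate (mm) of voxel (0, 0, 0), used when
#'   `affine` is not given.
#' @param affine optional 4x4 voxel-to-world matrix; overrides
#'   `spacing`/`origin`.
#' @param meta named list of metadata (e.g. `subject`, `time_min`).
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                     affine = NULL, meta = list()) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3-D array")
  if (is.null(affine)) {
    stopifnot(length(spacing) == 3L, all(spacing > 0), length(origin) == 3L)
    affine <- diag(c(spacing, 1))
    affine[1:3, 4] <- origin
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L)) || abs(det(affine)) < 1e-12)
    stop("`affine` must be an invertible 4x4 matrix")
  if (any(voxel_spacing_from_affine(affine) <= 0))
    stop("voxel spacing must be strictly positive on all axes")
  structure(list(values = values, affine = affine, meta = meta),
            class = "volume3d")
}

voxel_spacing_from_affine <- function(affine) {
  sqrt(colSums(affine[1:3, 1:3]^2))
}

#' @export
dim.volume3d <- function(x) dim(x$values)

#' @export
print.volume3d <- function(x, ...) {
  d <- dim(x$values)
  sp <- signif(voxel_spacing(x), 4)
  cat(sprintf("<volume3d> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(sp, collapse = " x ")))
  cat(sprintf("  range [%.4g, %.4g]", min(x$values), max(x$values)))
  if (length(x$meta)) {
    tags <- paste(names(x$meta), unlist(lapply(x$meta, format)),
                  sep = "=", collapse = ", ")
    cat("  |", tags)
  }
  cat("\n")
  invisible(x)
}

#' Voxel spacing and voxel volume
#'
#' @param vol a [volume3d()].
#' @return `voxel_spacing()`: spacing in mm per axis; `voxel_volume()`: the
#'   volume of one voxel in mm^3.
#' @export
voxel_spacing <- function(vol) voxel_spacing_from_affine(vol$affine)

#' @rdname voxel_spacing
#' @export
voxel_volume <- function(vol) abs(det(vol$affine[1:3, 1:3]))

#' World coordinates of all voxel centers
#'
#' @param vol a [volume3d()].
#' @return A list of three arrays (`x`, `y`, `z`), each with the volume's
#'   dimensions, giving the world coordinate (mm) of every voxel center.
#' @export
voxel_world_coords <- function(vol) {
  d <- dim(vol$values)
  i <- seq_len(d[1]) - 1
  j <- seq_len(d[2]) - 1
  k <- seq_len(d[3]) - 1
  A <- vol$affine
  list(
    x = outer(outer(A[1, 1] * i, A[1, 2] * j, "+"), A[1, 3] * k, "+") + A[1, 4],
    y = outer(outer(A[2, 1] * i, A[2, 2] * j, "+"), A[2, 3] * k, "+") + A[2, 4],
    z = outer(outer(A[3, 1] * i, A[3, 2] * j, "+"), A[3, 3] * k, "+") + A[3, 4]
  )
}

#' World-space center of a volume's field of view
#' @param vol a [volume3d()].
#' @return length-3 world coordinate (mm) of the grid center.
#' @export
volume_center <- function(vol) {
  d <- dim(vol$values)
  drop(vol$affine %*% c((d - 1) / 2, 1))[1:3]
}

same_grid <- function(a, b, tol = 1e-4) {
  identical(dim(a$values), dim(b$values)) &&
    max(abs(a$affine - b$affine)) < tol
}

#' Read and write volumes as NIfTI-1
#'
#' Thin wrappers around \pkg{RNifti}: the NIfTI sform/qform is honored on
#' read and written on write, so world coordinates round-trip.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol a [volume3d()].
#' @param meta named list stored on the returned object (read only).
#' @return `read_volume()`: a [volume3d()]; `write_volume()`: `path`,
#'   invisibly.
#' @export
read_volume <- function(path, meta = list()) {
  img <- RNifti::readNifti(path)
  aff <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  vals <- array(as.numeric(img), dim = dim(img))
  volume3d(vals, affine = aff, meta = meta)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Gaussian smoothing of a volume (separable, reflect padding)
#'
#' @param vol a [volume3d()].
#' @param sigma_vox Gaussian standard deviation in voxels (scalar or per
#'   axis).
#' @return A smoothed [volume3d()] on the same grid.
#' @export
smooth_volume <- function(vol, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  vals <- vol$values
  d <- dim(vals)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- dnorm(seq(-half, half), sd = s)
    kern <- kern / sum(kern)
    vals <- array(conv1d_axis_cpp(as.numeric(vals), as.integer(d),
                                  kern, ax - 1L), dim = d)
  }
  volume3d(vals, affine = vol$affine, meta = vol$meta)
}

#' Downsample a volume by an integer factor
#'
#' Smooths with a Gaussian matched to the decimation factor, then keeps
#' every `factor`-th voxel. The affine is updated so world coordinates of
#' retained voxels are unchanged.
#'
#' @param vol a [volume3d()].
#' @param factor integer decimation factor (1 returns the input).
#' @return A [volume3d()] on the coarser grid.
#' @export
downsample_volume <- function(vol, factor) {
  factor <- as.integer(factor)
  if (factor <= 1L) return(vol)
  sm <- smooth_volume(vol, sigma_vox = factor / 2)
  d <- dim(vol$values)
  idx <- lapply(d, function(n) seq(1L, n, by = factor))
  vals <- sm$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  aff <- vol$affine
  aff[, 1:3] <- aff[, 1:3] * factor
  volume3d(vals, affine = aff, meta = vol$meta)
}

#' Mirror a mask or volume across the midsagittal plane of its grid
#'
#' The phantom brain is left-right symmetric about the grid's first-axis
#' midplane, so contralateral correspondence is an index flip.
#'
#' @param x a 3-D array (mask or values).
#' @return The array flipped along the first axis.
#' @export
mirror_lr <- function(x) {
  x[rev(seq_len(dim(x)[1])), , , drop = FALSE]
}
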