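#' 6-DOF rigid transform (rotation + translation about a center)
#'
#' World-space rigid transform used both to apply simulated inter-scan
#' motion and to report registration results. The forward map is
#' `T(x) = R (x - c) + c + t` with `R = Rz Ry Rx` built from extrinsic
#' Euler angles in degrees.
#'
#' @param rotation rotation angles about the x, y, z world axes (degrees).
#' @param translation translation along x, y, z (mm).
#' @param center center of rotation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                            center = c(0, 0, 0)) {
  stopifnot(length(rotation) == 3L, length(translation) == 3L,
            length(center) == 3L)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation),
                 center = as.numeric(center)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s | trans (mm): %s\n",
              paste(signif(x$rotation, 4), collapse = ", "),
              paste(signif(x$translation, 4), collapse = ", ")))
  invisible(x)
}

rot3 <- function(angles_deg) {
  a <- angles_deg * pi / 180
  cx <- cos(a[1]); sx <- sin(a[1])
  cy <- cos(a[2]); sy <- sin(a[2])
  cz <- cos(a[3]); sz <- sin(a[3])
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Convert a rigid transform to / from a 4x4 homogeneous matrix
#'
#' @param transform a [rigid_transform()].
#' @param m a 4x4 homogeneous rigid matrix.
#' @param center rotation center to use when re-expressing `m` as
#'   angles + translation.
#' @return `rigid_matrix()`: a 4x4 matrix; `rigid_from_matrix()`: a
#'   [rigid_transform()].
#' @export
rigid_matrix <- function(transform) {
  R <- rot3(transform$rotation)
  c0 <- transform$center
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- c0 + transform$translation - R %*% c0
  M
}

#' @rdname rigid_matrix
#' @export
rigid_from_matrix <- function(m, center = c(0, 0, 0)) {
  R <- m[1:3, 1:3]
  # Euler extraction for R = Rz(g) Ry(b) Rx(a); valid for |b| < 90 deg
  b <- -asin(max(-1, min(1, R[3, 1])))
  a <- atan2(R[3, 2], R[3, 3])
  g <- atan2(R[2, 1], R[1, 1])
  rot <- c(a, b, g) * 180 / pi
  t <- m[1:3, 4] - center + R %*% center
  rigid_transform(rotation = rot, translation = as.numeric(t), center = center)
}

#' Compose, invert and apply rigid transforms
#'
#' `compose_rigid(a, b)` returns the transform equivalent to applying `b`
#' first, then `a`. `invert_rigid` returns the exact inverse (expressed
#' about the same center). `apply_rigid` maps world points (rows of an
#' n x 3 matrix) through the forward transform.
#'
#' @param a,b,transform [rigid_transform()] objects.
#' @param points n x 3 matrix of world coordinates (mm).
#' @return A [rigid_transform()], or for `apply_rigid` an n x 3 matrix.
#' @export
compose_rigid <- function(a, b) {
  rigid_from_matrix(rigid_matrix(a) %*% rigid_matrix(b), center = a$center)
}

#' @rdname compose_rigid
#' @export
invert_rigid <- function(transform) {
  rigid_from_matrix(solve(rigid_matrix(transform)),
                    center = transform$center)
}

#' @rdname compose_rigid
#' @export
apply_rigid <- function(transform, points) {
  points <- matrix(points, ncol = 3)
  M <- rigid_matrix(transform)
  t(M[1:3, 1:3] %*% t(points) + M[1:3, 4])
}

#' Resample a volume through a rigid transform onto a target grid
#'
#' The returned volume lives on the grid of `target`; its value at world
#' point `x` is `moving` sampled at `transform^{-1}(x)` (i.e. `transform`
#' is the forward map carrying the moving image's content onto the target
#' frame, FLIRT-style).
#'
#' @param moving a [volume3d()] to resample.
#' @param target a [volume3d()] defining the output grid.
#' @param transform a [rigid_transform()] (forward, moving-to-target).
#' @param interp `"trilinear"` (default) or `"nearest"`.
#' @param fill value for samples outside the moving volume (default `NA`).
#' @return A [volume3d()] on the target grid.
#' @export
resample_volume <- function(moving, target, transform = rigid_transform(),
                            interp = c("trilinear", "nearest"), fill = NA_real_) {
  interp <- match.arg(interp)
  # output voxel -> world -> (pull back) -> moving world -> moving voxel
  M <- solve(moving$affine) %*% solve(rigid_matrix(transform)) %*% target$affine
  d_in <- dim(moving$values)
  d_out <- dim(target$values)
  vals <- resample_affine_cpp(as.numeric(moving$values), as.integer(d_in),
                              as.integer(d_out), M[1:3, , drop = FALSE],
                              fill, interp == "nearest")
  volume3d(array(vals, dim = d_out), affine = target$affine,
           meta = moving$meta)
}
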