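#' Threshold-based brain mask
#'
#' Simple foreground mask: voxels above `frac` times the 99th percentile
#' of positive intensities. Adequate for skull-free phantoms and
#' pre-stripped clinical volumes; no morphology is attempted.
#'
#' @param vol a [volume3d()].
#' @param frac threshold as a fraction of the robust maximum.
#' @return Logical 3-D array.
#' @export
brain_mask <- function(vol, frac = 0.2) {
  pos <- vol$values[vol$values > 0]
  if (!length(pos)) return(array(FALSE, dim = dim(vol$values)))
  vol$values > frac * quantile(pos, 0.99)
}

ncc_metric <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 32) return(-1)
  av <- a[ok]; bv <- b[ok]
  if (sd(av) == 0 || sd(bv) == 0) return(-1)
  cor(av, bv)
}

mi_metric <- function(a, b, bins = 32L) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 32) return(-1)
  av <- a[ok]; bv <- b[ok]
  cut_idx <- function(x) {
    r <- range(x)
    if (r[1] == r[2]) return(rep(1L, length(x)))
    pmin(bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * bins))
  }
  ia <- cut_idx(av); ib <- cut_idx(bv)
  h <- tabulate((ia - 1L) * bins + ib, nbins = bins * bins) / length(av)
  dim(h) <- c(bins, bins)
  px <- colSums(h); py <- rowSums(h)
  nz <- h > 0
  sum(h[nz] * log(h[nz] / (rep(px, each = bins) * py)[nz]))
}

fov_overlaps <- function(a, b) {
  corners <- function(v) {
    d <- dim(v$values)
    idx <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                 c(0, d[3] - 1)))
    t(v$affine %*% t(cbind(idx, 1)))[, 1:3]
  }
  ca <- corners(a); cb <- corners(b)
  all(apply(ca, 2, min) <= apply(cb, 2, max) + 1e-9) &&
    all(apply(cb, 2, min) <= apply(ca, 2, max) + 1e-9)
}

#' Rigid co-registration of the late onto the early acquisition
#'
#' 6-DOF (three rotations, three translations) multi-resolution
#' registration. At each pyramid level the metric -- normalized
#' cross-correlation by default, mutual information as an option -- is
#' maximized by Nelder-Mead over the transform parameters, warm-started
#' from the previous (coarser) level. The returned transform is the
#' forward map carrying the moving image onto the fixed frame; the
#' resampled volume is the moving image pulled through it onto the fixed
#' grid with trilinear interpolation.
#'
#' @param fixed,moving [volume3d()]s with overlapping fields of view and
#'   at least 16 voxels per axis.
#' @param metric `"ncc"` (default) or `"mi"`.
#' @param levels integer downsampling factors, coarse to fine.
#' @param maxit Nelder-Mead iteration cap per level (recycled across
#'   levels; the default spends most iterations on the cheap coarse
#'   levels and only refines at full resolution).
#' @param init optional [rigid_transform()] initial guess.
#' @param min_metric final-metric floor below which the result is flagged
#'   as non-converged (NCC scale; ignored for MI).
#' @return A list of class `rigid_registration`: `transform`
#'   ([rigid_transform()], forward moving-to-fixed), `resampled`
#'   ([volume3d()] on the fixed grid), `metric_trace` (final metric per
#'   level), `metric`, and `converged`.
#' @export
register_rigid <- function(fixed, moving, metric = c("ncc", "mi"),
                           levels = c(4, 2, 1), maxit = c(400, 400, 150),
                           init = NULL, min_metric = 0.5) {
  metric <- match.arg(metric)
  if (any(dim(fixed$values) < 16) || any(dim(moving$values) < 16))
    stop("registration requires at least 16 voxels per axis")
  if (!fov_overlaps(fixed, moving))
    stop("fields of view do not overlap in world space")
  mfun <- if (metric == "ncc") ncc_metric else mi_metric
  center <- volume_center(fixed)
  par <- if (is.null(init)) rep(0, 6) else
    c(init$rotation, init$translation)
  maxit <- rep_len(maxit, length(levels))
  trace <- numeric(0)
  for (li in seq_along(levels)) {
    f <- levels[li]
    # light smoothing at full resolution flattens trilinear-interpolation
    # ripple in the metric; coarser levels are smoothed by the pyramid
    fx <- if (f == 1) smooth_volume(fixed, 0.7) else
      downsample_volume(fixed, f)
    mv <- if (f == 1) smooth_volume(moving, 0.7) else
      downsample_volume(moving, f)
    objective <- function(p) {
      tr <- rigid_transform(p[1:3], p[4:6], center)
      res <- resample_volume(mv, fx, tr, fill = NA_real_)
      -mfun(fx$values, res$values)
    }
    # two warm-started runs per level: restarting rebuilds the simplex
    # around the current optimum, guarding against premature collapse
    for (rep in 1:2) {
      opt <- optim(par, objective, method = "Nelder-Mead",
                   control = list(maxit = maxit[li], reltol = 1e-10))
      par <- opt$par
    }
    trace <- c(trace, -opt$value)
  }
  transform <- rigid_transform(par[1:3], par[4:6], center)
  resampled <- resample_volume(moving, fixed, transform, fill = NA_real_)
  # cross-level metric values are only comparable for NCC; MI shifts with
  # resolution and bin occupancy
  converged <- TRUE
  if (metric == "ncc") {
    converged <- tail(trace, 1) >= min_metric &&
      !(length(trace) > 1 && tail(trace, 1) < trace[1] - 0.05)
  }
  if (!converged)
    warning("registration may not have converged (final metric ",
            signif(tail(trace, 1), 4), ")")
  structure(list(transform = transform, resampled = resampled,
                 metric_trace = trace, metric = metric,
                 converged = converged),
            class = "rigid_registration")
}

#' Intensity normalization of a co-registered pair
#'
#' Fits a linear map (gain + offset) from the registered late volume to
#' the fixed early volume over a reference set of normal-appearing brain
#' voxels: the brain mask minus the top 2\% of fixed intensities and
#' minus any supplied lesion mask, so true enhancement change is not
#' fitted away. The gain is estimated by orthogonal (total
#' least-squares) regression -- both acquisitions carry comparable noise,
#' and ordinary regression of one on the other would attenuate the gain
#' -- and the offset then matches the medians, so the median paired
#' difference over the reference set is exactly zero. Both volumes are
#' finally scaled so the reference-set median of the fixed volume equals
#' `nominal`.
#'
#' @param fixed the early [volume3d()].
#' @param registered the late volume resampled onto the fixed grid.
#' @param mask logical brain mask (default: [brain_mask()] of `fixed`).
#' @param lesion_mask optional logical mask of known lesions to exclude
#'   from the reference set.
#' @param nominal reference level the fixed median is scaled to.
#' @return A list: `fixed_n`, `late_n` (normalized [volume3d()]s) and
#'   `report` with `gain`, `offset`, reference-set size and the median
#'   absolute paired difference before/after.
#' @export
normalize_pair <- function(fixed, registered, mask = NULL,
                           lesion_mask = NULL, nominal = 1) {
  if (!same_grid(fixed, registered))
    stop("`registered` must live on the fixed grid")
  if (is.null(mask)) mask <- brain_mask(fixed)
  if (!any(mask)) stop("brain mask is empty")
  ref <- mask & is.finite(registered$values) & is.finite(fixed$values)
  hi <- quantile(fixed$values[ref], 0.98)
  ref <- ref & fixed$values <= hi
  if (!is.null(lesion_mask)) ref <- ref & !lesion_mask
  n_ref <- sum(ref)
  if (n_ref < 1000)
    stop("reference set has ", n_ref, " voxels (< 1000); ",
         "normalization would be unreliable")
  fv <- fixed$values[ref]
  rv <- registered$values[ref]
  sxx <- var(rv); syy <- var(fv); sxy <- cov(rv, fv)
  if (sxx < 1e-12)
    stop("reference set has no intensity variation")
  gain <- if (abs(sxy) < 1e-12) 1 else
    (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  offset <- median(fv - gain * rv)
  pre_mad <- median(abs(rv - fv))
  scale_to <- nominal / median(fv)
  fixed_n <- volume3d(fixed$values * scale_to, affine = fixed$affine,
                      meta = fixed$meta)
  late_vals <- (offset + gain * registered$values) * scale_to
  late_vals[!is.finite(late_vals)] <- 0
  late_n <- volume3d(late_vals, affine = fixed$affine,
                     meta = registered$meta)
  post_mad <- median(abs(late_n$values[ref] - fixed_n$values[ref]))
  list(fixed_n = fixed_n, late_n = late_n,
       report = list(gain = gain, offset = offset, n_reference = n_ref,
                     scale_to_nominal = scale_to,
                     median_abs_diff_pre = pre_mad * scale_to,
                     median_abs_diff_post = post_mad))
}
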