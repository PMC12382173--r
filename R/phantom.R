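#' Contrast enhancement kinetic profile
#'
#' Gamma-variate-style enhancement time-curve for a tissue compartment:
#' `E(t) = amplitude * (t/t_peak)^a * exp(a * (1 - t/t_peak))` with shape
#' `a = t_peak * sqrt(rise_rate * decay_rate)`. The curve is unimodal,
#' zero at `t = 0`, and normalized so `E(t_peak) = amplitude`.
#' High-grade glioma tissue peaks early (about 3-8 min post-injection);
#' metastases and slowly filling compartments peak late (about 15 min or
#' beyond), which is the contrast the wash-out map exploits.
#'
#' @param amplitude peak enhancement above baseline (arbitrary signal
#'   units), >= 0.
#' @param t_peak time of peak enhancement (minutes), > 0.
#' @param rise_rate uptake shape parameter (1/min), > 0.
#' @param decay_rate clearance shape parameter (1/min), > 0.
#' @return An object of class `kinetic_profile`.
#' @export
kinetic_profile <- function(amplitude, t_peak, rise_rate = 0.4,
                            decay_rate = 0.4) {
  stopifnot(amplitude >= 0, t_peak > 0, rise_rate > 0, decay_rate > 0)
  structure(list(amplitude = amplitude, t_peak = t_peak,
                 rise_rate = rise_rate, decay_rate = decay_rate,
                 shape = t_peak * sqrt(rise_rate * decay_rate)),
            class = "kinetic_profile")
}

#' Evaluate an enhancement curve
#'
#' @param profile a [kinetic_profile()].
#' @param t time(s) in minutes post-injection, >= 0.
#' @return Enhancement `E(t)` in signal units (vectorized over `t`).
#' @export
enhancement_at <- function(profile, t) {
  if (any(t < 0)) stop("time must be non-negative")
  a <- profile$shape
  u <- t / profile$t_peak
  e <- profile$amplitude * u^a * exp(a * (1 - u))
  e[t == 0] <- 0
  e
}

#' Canonical tissue kinetic archetypes
#'
#' `glioblastoma`: early peak (5 min) with rapid clearance, so the 5-min
#' signal exceeds the 25-min signal (wash-out). `metastasis`: late peak
#' (15 min) with slow clearance (late enhancement). `slow_fill`: very late
#' peak (25 min), used for slowly accumulating lesion compartments.
#'
#' @param archetype one of `"glioblastoma"`, `"metastasis"`, `"slow_fill"`.
#' @param amplitude peak enhancement (signal units).
#' @return A [kinetic_profile()].
#' @export
kinetic_archetype <- function(archetype = c("glioblastoma", "metastasis",
                                            "slow_fill"),
                              amplitude = 60) {
  archetype <- match.arg(archetype)
  switch(archetype,
    glioblastoma = kinetic_profile(amplitude, t_peak = 5,
                                   rise_rate = 0.5, decay_rate = 0.5),
    metastasis   = kinetic_profile(amplitude, t_peak = 15,
                                   rise_rate = 0.25, decay_rate = 0.25),
    slow_fill    = kinetic_profile(amplitude, t_peak = 25,
                                   rise_rate = 0.12, decay_rate = 0.12))
}

#' Spherical lesion component for the phantom
#'
#' A lesion is a list of spherical components; later components override
#' earlier ones where they overlap, so a two-compartment lesion is an
#' outer sphere (e.g. slowly enhancing rim) with an inner sphere (e.g.
#' rapidly washing-out core) on top. `profile = NULL` marks a
#' non-enhancing (necrotic) component.
#'
#' @param center world coordinates of the sphere center (mm).
#' @param radius sphere radius (mm), > 0.
#' @param profile a [kinetic_profile()] or `NULL` for necrosis.
#' @return A `lesion_component` list.
#' @export
lesion_component <- function(center, radius, profile) {
  stopifnot(length(center) == 3L, radius > 0)
  if (!is.null(profile) && !inherits(profile, "kinetic_profile"))
    stop("`profile` must be a kinetic_profile or NULL")
  structure(list(center = as.numeric(center), radius = radius,
                 profile = profile), class = "lesion_component")
}

#' Default two-compartment lesion
#'
#' Two tangent spheres along the x axis: one rapidly washing-out
#' compartment and one slowly enhancing (late) compartment, sized so the
#' wash-out compartment holds `washout_fraction` of the total lesion
#' volume, which equals the volume of a single sphere of the given
#' equivalent `radius`. Compact compartments mimic the mixed wash-out /
#' late-enhancement architecture of enhancing brain tumors while staying
#' robust to voxelization.
#'
#' @param center lesion reference point (mm, world coordinates): the
#'   tangent point between the two compartments.
#' @param radius equivalent radius of the total lesion volume (mm).
#' @param washout_fraction volume fraction of the washing-out
#'   compartment, in `(0, 1)`.
#' @param amplitude peak enhancement of both compartments (signal units).
#' @return A list of two [lesion_component()]s.
#' @export
two_compartment_lesion <- function(center, radius = 14,
                                   washout_fraction = 0.6, amplitude = 60) {
  stopifnot(washout_fraction > 0, washout_fraction < 1)
  r_w <- radius * washout_fraction^(1 / 3)
  r_l <- radius * (1 - washout_fraction)^(1 / 3)
  list(lesion_component(center + c(r_w, 0, 0), r_w,
                        kinetic_archetype("glioblastoma", amplitude)),
       lesion_component(center - c(r_l, 0, 0), r_l,
                        kinetic_archetype("slow_fill", amplitude)))
}

#' Phantom specification
#'
#' Defines the synthetic dual-timepoint acquisition: grid geometry, a
#' left-right symmetric ellipsoidal brain with simple internal structure,
#' lesions with compartment-wise enhancement kinetics, the two nominal
#' acquisition times (5 and 25 min), rigid inter-scan motion applied to
#' the late acquisition, additive Gaussian noise and a smooth
#' multiplicative bias field on the late acquisition.
#'
#' @param grid_shape voxel counts per axis (all >= 16).
#' @param voxel_size_mm voxel spacing per axis (mm).
#' @param lesions list of lesions; each lesion is a list of
#'   [lesion_component()]s (a single component may be given bare).
#' @param acquisition_times_min early/late sample times (minutes),
#'   strictly increasing.
#' @param motion a [rigid_transform()]: the forward motion applied to the
#'   patient between the two acquisitions (identity by default). Its
#'   center defaults to the grid center when left at the origin.
#' @param noise_sigma additive Gaussian noise SD (signal units; baseline
#'   brain signal is 100, so `noise_sigma = 2` is 2\% noise).
#' @param bias_amplitude peak relative amplitude of the smooth
#'   multiplicative bias field on the late acquisition (0.1 = +/-10\%).
#' @param rician if `TRUE`, noise is applied as Rician magnitude noise
#'   instead of additive Gaussian.
#' @param seed RNG seed controlling noise and bias reproducibility.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(96, 96, 72),
                         voxel_size_mm = c(1.5, 1.5, 1.5),
                         lesions = NULL,
                         acquisition_times_min = c(5, 25),
                         motion = rigid_transform(),
                         noise_sigma = 0,
                         bias_amplitude = 0,
                         rician = FALSE,
                         seed = 1L) {
  grid_shape <- as.integer(rep_len(grid_shape, 3L))
  voxel_size_mm <- rep_len(voxel_size_mm, 3L)
  if (any(grid_shape < 16L)) stop("grid_shape must be >= 16 on every axis")
  if (any(voxel_size_mm <= 0)) stop("voxel sizes must be positive")
  if (length(acquisition_times_min) != 2L ||
      diff(acquisition_times_min) <= 0)
    stop("acquisition_times_min must be two strictly increasing times")
  if (noise_sigma < 0 || bias_amplitude < 0)
    stop("noise_sigma and bias_amplitude must be non-negative")
  fov <- grid_shape * voxel_size_mm
  # center on the voxel grid so the index mirror is an exact world-space
  # reflection (contralateral correspondence is then exact)
  center <- (grid_shape - 1) / 2 * voxel_size_mm
  if (is.null(lesions))
    lesions <- list(two_compartment_lesion(center + c(24, 4, 2)))
  # allow a bare component in place of a single-component lesion
  lesions <- lapply(lesions, function(l)
    if (inherits(l, "lesion_component")) list(l) else l)
  if (all(motion$center == 0)) motion$center <- center
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 lesions = lesions,
                 acquisition_times_min = acquisition_times_min,
                 motion = motion, noise_sigma = noise_sigma,
                 bias_amplitude = bias_amplitude, rician = rician,
                 seed = as.integer(seed),
                 fov_mm = fov, center_mm = center,
                 # distinct axis ratios: no rotational symmetry to trap
                 # the registration
                 brain_semiaxes_mm = pmin(fov / 2 - 2 * voxel_size_mm,
                                          c(0.43, 0.475, 0.45) * fov),
                 baseline = 100),
            class = "phantom_spec")
}

ellipsoid_mask <- function(coords, center, semiaxes) {
  ((coords$x - center[1]) / semiaxes[1])^2 +
    ((coords$y - center[2]) / semiaxes[2])^2 +
    ((coords$z - center[3]) / semiaxes[3])^2 <= 1
}

sphere_mask <- function(coords, center, radius) {
  (coords$x - center[1])^2 + (coords$y - center[2])^2 +
    (coords$z - center[3])^2 <= radius^2
}

# Baseline (pre-enhancement) brain signal: left-right symmetric ellipsoid
# at 100 with two mirrored "ventricles" at 55, a mild gradient, and a
# smooth deterministic sinusoidal modulation standing in for internal
# anatomy -- it anchors the rotational degrees of freedom during
# registration. Background air is 0.
phantom_baseline <- function(spec, coords) {
  b <- array(0, dim = spec$grid_shape)
  brain <- ellipsoid_mask(coords, spec$center_mm, spec$brain_semiaxes_mm)
  b[brain] <- spec$baseline
  for (s in c(-1, 1)) {
    vent <- ellipsoid_mask(coords,
                           spec$center_mm + c(s * 14, 6, 8),
                           c(8, 20, 11))
    b[vent & brain] <- 55
  }
  cc <- spec$center_mm
  grad <- 1 + 0.06 * (coords$z - cc[3]) / spec$fov_mm[3] +
    0.04 * (coords$y - cc[2]) / spec$fov_mm[2]
  tex <- 0.08 * sin((coords$x - cc[1]) / 9) *
    sin((coords$y - cc[2]) / 11) * sin((coords$z - cc[3]) / 7)
  b * (grad + tex)
}

# Per-voxel enhancement at time t (noiseless), honoring component override
# order within each lesion.
phantom_enhancement <- function(spec, coords, t) {
  e <- array(0, dim = spec$grid_shape)
  for (lesion in spec$lesions) {
    for (comp in lesion) {
      m <- sphere_mask(coords, comp$center, comp$radius)
      e[m] <- if (is.null(comp$profile)) 0 else
        enhancement_at(comp$profile, t)
    }
  }
  e
}

# Smooth multiplicative bias field: trilinear interpolation of a coarse
# 3x3x3 random grid, scaled so its maximum absolute relative deviation
# equals `amplitude`.
phantom_bias_field <- function(spec) {
  if (spec$bias_amplitude == 0) return(array(1, dim = spec$grid_shape))
  coarse <- array(rnorm(27), dim = c(3, 3, 3))
  coarse <- coarse - mean(coarse)
  d <- spec$grid_shape
  # map output voxel (0-based) onto the coarse grid's 0..2 index range
  M <- diag(c(2 / (d[1] - 1), 2 / (d[2] - 1), 2 / (d[3] - 1)))
  M <- cbind(M, c(0, 0, 0))
  field <- array(resample_affine_cpp(as.numeric(coarse), c(3L, 3L, 3L),
                                     as.integer(d), M, 0, FALSE), dim = d)
  1 + spec$bias_amplitude * field / max(abs(field))
}

add_noise <- function(vals, sigma, rician) {
  if (sigma <= 0) return(vals)
  if (rician) {
    sqrt((vals + rnorm(length(vals), sd = sigma))^2 +
           rnorm(length(vals), sd = sigma)^2)
  } else {
    vals + array(rnorm(length(vals), sd = sigma), dim = dim(vals))
  }
}

#' Render the dual-timepoint phantom
#'
#' Produces the early (5-min) and late (25-min) post-contrast volumes and
#' the ground truth. The late acquisition is moved through the spec's
#' rigid motion (content forward-warped, trilinear), multiplied by the
#' bias field, and both volumes receive independent noise. Truth masks are
#' computed from the noiseless curves on the early grid: an enhancing
#' voxel is wash-out iff `E(t1) > E(t2)` and late-enhancing iff
#' `E(t2) > E(t1)`.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements `early`, `late` ([volume3d()]s) and
#'   `truth` (class `phantom_truth`): masks `washout_mask`, `late_mask`,
#'   `enhancing_mask`, `brain_mask`; `true_volumes_mm3` per lesion and
#'   compartment; `true_transform` (the applied motion); and the spec.
#' @export
render_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  aff <- diag(c(spec$voxel_size_mm, 1))
  grid <- volume3d(array(0, dim = spec$grid_shape), affine = aff)
  coords <- voxel_world_coords(grid)
  brain <- ellipsoid_mask(coords, spec$center_mm, spec$brain_semiaxes_mm)
  for (lesion in spec$lesions) {
    for (comp in lesion) {
      inside <- sphere_mask(coords, comp$center, comp$radius)
      if (any(inside & !brain))
        stop("lesion component extends outside the brain mask")
    }
  }
  t12 <- spec$acquisition_times_min
  base <- phantom_baseline(spec, coords)
  e1 <- phantom_enhancement(spec, coords, t12[1])
  e2 <- phantom_enhancement(spec, coords, t12[2])
  vvol <- prod(spec$voxel_size_mm)

  enh <- (e1 > 0) | (e2 > 0)
  washout <- enh & (e1 > e2)
  late <- enh & (e2 > e1)

  early_vals <- base + e1
  late_clean <- volume3d(base + e2, affine = aff)
  ident <- isTRUE(all.equal(rigid_matrix(spec$motion), diag(4),
                            tolerance = 1e-12))
  late_vals <- if (ident) late_clean$values else
    resample_volume(late_clean, grid, spec$motion, fill = 0)$values
  bias <- phantom_bias_field(spec)
  late_vals <- late_vals * bias
  early_vals <- add_noise(early_vals, spec$noise_sigma, spec$rician)
  late_vals <- add_noise(late_vals, spec$noise_sigma, spec$rician)

  per_lesion <- lapply(seq_along(spec$lesions), function(i) {
    lesion_enh <- array(FALSE, dim = spec$grid_shape)
    for (comp in spec$lesions[[i]])
      lesion_enh <- lesion_enh |
        (sphere_mask(coords, comp$center, comp$radius) & enh)
    c(washout = sum(lesion_enh & washout) * vvol,
      late = sum(lesion_enh & late) * vvol,
      enhancing = sum(lesion_enh) * vvol)
  })
  truth <- structure(list(
    washout_mask = washout, late_mask = late, enhancing_mask = enh,
    brain_mask = brain,
    true_volumes_mm3 = do.call(rbind, per_lesion),
    true_transform = spec$motion,
    mirror_axis = 1L,
    spec = spec), class = "phantom_truth")

  meta1 <- list(subject = "phantom", time_min = t12[1])
  meta2 <- list(subject = "phantom", time_min = t12[2])
  list(early = volume3d(early_vals, affine = aff, meta = meta1),
       late = volume3d(late_vals, affine = aff, meta = meta2),
       truth = truth)
}

#' Render ancillary rCBV and ADC maps for a phantom
#'
#' Full-grid parameter maps with configurable tumor-to-contralateral
#' value ratios: inside the truth enhancing mask the map takes the tumor
#' value, elsewhere in the brain the background value, and air is zero.
#' The contralateral mirror of the tumor thus sits at the background
#' value, so the downstream ROI ratio recovers `tumor / background`.
#'
#' @param spec the [phantom_spec()] used to render the phantom.
#' @param truth the matching `phantom_truth`.
#' @param rcbv_tumor,rcbv_background rCBV values for tumor and normal
#'   brain (ratio defaults to 3.0).
#' @param adc_tumor,adc_background ADC values (ratio defaults to 1.4).
#' @param noise_frac multiplicative Gaussian noise fraction (0.01 = 1\%).
#' @return A list with [volume3d()]s `rcbv` and `adc`.
#' @export
render_ancillary_maps <- function(spec, truth,
                                  rcbv_tumor = 3.0, rcbv_background = 1.0,
                                  adc_tumor = 1.4, adc_background = 1.0,
                                  noise_frac = 0) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(truth, "phantom_truth"))
  set.seed(spec$seed + 1L)
  aff <- diag(c(spec$voxel_size_mm, 1))
  mk <- function(tumor, background) {
    vals <- array(0, dim = spec$grid_shape)
    vals[truth$brain_mask] <- background
    vals[truth$enhancing_mask] <- tumor
    if (noise_frac > 0)
      vals <- vals * (1 + array(rnorm(length(vals), sd = noise_frac),
                                dim = dim(vals)))
    volume3d(vals, affine = aff)
  }
  list(rcbv = mk(rcbv_tumor, rcbv_background),
       adc = mk(adc_tumor, adc_background))
}
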