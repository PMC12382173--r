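# ---- lesion tracing ---------------------------------------------------

# 2-D multi-seed flood fill (4-connectivity) within a logical matrix,
# implemented as iterated vectorized dilation-and-mask.
flood2d <- function(band_mask, seeds) {
  comp <- matrix(FALSE, nrow(band_mask), ncol(band_mask))
  comp[seeds] <- band_mask[seeds]
  if (!any(comp)) return(comp)
  repeat {
    grown <- comp
    grown[-1, ] <- grown[-1, ] | comp[-nrow(comp), ]
    grown[-nrow(comp), ] <- grown[-nrow(comp), ] | comp[-1, ]
    grown[, -1] <- grown[, -1] | comp[, -ncol(comp)]
    grown[, -ncol(comp)] <- grown[, -ncol(comp)] | comp[, -1]
    grown <- grown & band_mask
    if (identical(grown, comp)) return(comp)
    comp <- grown
  }
}

#' Semi-automatic lesion tracing (level-trace analog)
#'
#' Emulates slice-by-slice semi-automatic level tracing: on the seed's
#' axial slice the 2-D connected component (4-connectivity) of voxels
#' whose intensity lies within `band` and which contains the seed is
#' taken; the trace is then propagated to contiguous neighboring slices,
#' keeping the in-band components that overlap the previous slice's
#' region, until no overlap remains. Deterministic given its inputs.
#'
#' @param vol a [volume3d()] (typically the early acquisition or the
#'   percent map magnitude).
#' @param seed length-3 integer voxel index (1-based) inside the lesion.
#' @param band numeric `c(lower, upper)` intensity bounds; must contain
#'   the seed's intensity.
#' @return Logical 3-D lesion mask.
#' @export
trace_lesion <- function(vol, seed, band) {
  d <- dim(vol$values)
  seed <- as.integer(seed)
  if (length(seed) != 3L || any(seed < 1L) || any(seed > d))
    stop("seed voxel is outside the grid")
  v <- vol$values[seed[1], seed[2], seed[3]]
  if (v < band[1] || v > band[2])
    stop("seed intensity ", signif(v, 4), " is outside the band [",
         band[1], ", ", band[2], "]")
  in_band <- vol$values >= band[1] & vol$values <= band[2]
  mask <- array(FALSE, dim = d)
  k0 <- seed[3]
  mask[, , k0] <- flood2d(in_band[, , k0],
                          matrix(seed[1:2], ncol = 2))
  for (dir in c(1L, -1L)) {
    prev <- mask[, , k0]
    k <- k0 + dir
    while (k >= 1L && k <= d[3]) {
      seeds <- which(prev & in_band[, , k], arr.ind = TRUE)
      if (!nrow(seeds)) break
      comp <- flood2d(in_band[, , k], seeds)
      mask[, , k] <- comp
      prev <- comp
      k <- k + dir
    }
  }
  if (!any(mask)) stop("lesion trace is empty")
  mask
}

# ---- compartment volumes and ratios -----------------------------------

#' Compartment volumes of a lesion under a wash-out map
#'
#' @param lesion_mask logical 3-D mask of the lesion.
#' @param map a [washout_map()][compute_map()] on the same grid.
#' @param voxel_volume_mm3 voxel volume (mm^3); defaults to the map's
#'   affine determinant.
#' @return Named numeric: `v_washout`, `v_late`, `v_enhancing` (mm^3).
#' @export
compartment_volumes <- function(lesion_mask, map,
                                voxel_volume_mm3 = NULL) {
  stopifnot(inherits(map, "washout_map"))
  if (!identical(dim(lesion_mask), dim(map$labels)))
    stop("lesion mask grid does not match map")
  if (!any(lesion_mask)) stop("lesion mask is empty")
  if (is.null(voxel_volume_mm3))
    voxel_volume_mm3 <- abs(det(map$affine[1:3, 1:3]))
  lab <- map$labels[lesion_mask]
  c(v_washout = sum(lab == WASHOUT_LABELS[["WASHOUT"]]) * voxel_volume_mm3,
    v_late = sum(lab == WASHOUT_LABELS[["LATE_ENHANCEMENT"]]) *
      voxel_volume_mm3,
    v_enhancing = sum(lab != WASHOUT_LABELS[["NEUTRAL"]]) *
      voxel_volume_mm3)
}

#' Wash-out ratio
#'
#' `v_washout / (v_washout + v_late)`: the fraction of the classified
#' (non-neutral) lesion volume that washes out. Returns `NA` when both
#' volumes are zero (ratio undefined; callers flag it).
#'
#' @param v_washout,v_late compartment volumes (mm^3), >= 0.
#' @return The ratio in `[0, 1]`, or `NA_real_` when undefined.
#' @export
washout_ratio <- function(v_washout, v_late) {
  if (v_washout < 0 || v_late < 0) stop("volumes must be non-negative")
  if (v_washout + v_late == 0) return(NA_real_)
  v_washout / (v_washout + v_late)
}

#' rCBV ratio from three tumor ROIs and a contralateral ROI
#'
#' The enhancing tumor's relative cerebral blood volume is measured in
#' three different slices; the rCBV ratio is the mean of the three
#' per-slice ROI means divided by the contralateral normal-brain ROI
#' mean.
#'
#' @param rcbv_map a [volume3d()] rCBV map.
#' @param tumor_rois list of exactly 3 logical masks, each confined to a
#'   single, distinct axial slice.
#' @param contralateral_roi logical mask of contralateral normal brain.
#' @return The rCBV ratio (dimensionless).
#' @export
rcbv_ratio <- function(rcbv_map, tumor_rois, contralateral_roi) {
  if (length(tumor_rois) != 3L)
    stop("exactly three tumor ROIs (on distinct slices) are required")
  slices <- vapply(tumor_rois, function(m) {
    if (!any(m)) stop("empty tumor ROI")
    ks <- unique(which(m, arr.ind = TRUE)[, 3])
    if (length(ks) != 1L) stop("each tumor ROI must lie in a single slice")
    ks
  }, 0L)
  if (anyDuplicated(slices)) stop("tumor ROIs must be on distinct slices")
  if (!any(contralateral_roi)) stop("contralateral ROI is empty")
  contra <- mean(rcbv_map$values[contralateral_roi])
  if (contra <= 0) stop("contralateral mean must be positive")
  slice_means <- vapply(tumor_rois,
                        function(m) mean(rcbv_map$values[m]), 0)
  mean(slice_means) / contra
}

#' ADC ratio of solid tumor to contralateral hemisphere
#'
#' @param adc_map a [volume3d()] ADC map.
#' @param tumor_roi,contralateral_roi nonempty logical masks.
#' @return Tumor ROI mean divided by contralateral ROI mean.
#' @export
adc_ratio <- function(adc_map, tumor_roi, contralateral_roi) {
  if (!any(tumor_roi) || !any(contralateral_roi))
    stop("ROIs must be nonempty")
  contra <- mean(adc_map$values[contralateral_roi])
  if (contra <= 0) stop("contralateral mean must be positive")
  mean(adc_map$values[tumor_roi]) / contra
}

#' Automated phantom ROI placement
#'
#' Picks the `k` axial slices where the lesion mask has the largest
#' area (for the per-slice rCBV ROIs) and mirrors the full lesion mask
#' across the midsagittal plane for the contralateral ROI. On clinical
#' data ROIs are user-supplied; this automation exists for phantoms,
#' whose brains are symmetric by construction.
#'
#' @param lesion_mask logical 3-D lesion mask.
#' @param k number of slice ROIs (default 3).
#' @return A list: `tumor_rois` (list of k single-slice masks),
#'   `tumor_roi` (full mask), `contralateral_roi` (mirrored mask).
#' @export
auto_rois <- function(lesion_mask, k = 3L) {
  areas <- apply(lesion_mask, 3, sum)
  ks <- order(areas, decreasing = TRUE)[seq_len(k)]
  if (any(areas[ks] == 0)) stop("lesion spans fewer than ", k, " slices")
  rois <- lapply(ks, function(kk) {
    m <- array(FALSE, dim = dim(lesion_mask))
    m[, , kk] <- lesion_mask[, , kk]
    m
  })
  list(tumor_rois = rois, tumor_roi = lesion_mask,
       contralateral_roi = mirror_lr(lesion_mask))
}

# ---- lesion measurement rows and filters ------------------------------

#' Measure one lesion into a measurement row
#'
#' @param lesion_id identifier string.
#' @param lesion_mask logical lesion mask.
#' @param map a [washout_map()][compute_map()].
#' @param rcbv_map,adc_map optional [volume3d()] maps; when supplied,
#'   ROIs default to [auto_rois()] placement.
#' @param group group label (`"glioblastoma"`, `"metastasis"`, or
#'   `"unknown"`).
#' @param spacing_mm voxel spacing used for bounding-box extents;
#'   defaults to the map affine.
#' @return One-row data.frame with the fixed measurement schema:
#'   volumes (mm^3), ratios, bounding extents and flags.
#' @export
measure_lesion <- function(lesion_id, lesion_mask, map,
                           rcbv_map = NULL, adc_map = NULL,
                           group = "unknown", spacing_mm = NULL) {
  if (is.null(spacing_mm))
    spacing_mm <- voxel_spacing_from_affine(map$affine)
  vols <- compartment_volumes(lesion_mask, map)
  wr <- washout_ratio(vols[["v_washout"]], vols[["v_late"]])
  idx <- which(lesion_mask, arr.ind = TRUE)
  extents <- vapply(1:3, function(a)
    (diff(range(idx[, a])) + 1) * spacing_mm[a], 0)
  rr <- ar <- NA_real_
  if (!is.null(rcbv_map) || !is.null(adc_map)) {
    rois <- auto_rois(lesion_mask)
    if (!is.null(rcbv_map))
      rr <- rcbv_ratio(rcbv_map, rois$tumor_rois, rois$contralateral_roi)
    if (!is.null(adc_map))
      ar <- adc_ratio(adc_map, rois$tumor_roi, rois$contralateral_roi)
  }
  data.frame(lesion_id = lesion_id, group = group,
             v_washout_mm3 = unname(vols[["v_washout"]]),
             v_late_mm3 = unname(vols[["v_late"]]),
             v_enhancing_mm3 = unname(vols[["v_enhancing"]]),
             washout_ratio = wr, rcbv_ratio = rr, adc_ratio = ar,
             extent_x_mm = extents[1], extent_y_mm = extents[2],
             extent_z_mm = extents[3],
             ratio_undefined = is.na(wr))
}

#' Apply the study's lesion size filters
#'
#' Flags lesions whose bounding box is smaller than 3 mm on any axis
#' (`below_min_size`; the minimum-size rule, boundary-inclusive: exactly
#' 3 mm is retained) and lesions with enhancing volume below 1 cm^3
#' (`below_1cm3`). The primary analysis drops only `below_min_size`
#' lesions; the small-tumor sensitivity analysis additionally drops
#' `below_1cm3` lesions.
#'
#' @param measurements data.frame with `extent_x_mm`, `extent_y_mm`,
#'   `extent_z_mm` and `v_enhancing_mm3` columns.
#' @param min_extent_mm minimum bounding-box extent (default 3).
#' @param min_volume_mm3 small-tumor threshold (default 1000).
#' @return The table with logical `below_min_size` and `below_1cm3`
#'   columns added.
#' @export
size_filters <- function(measurements, min_extent_mm = 3,
                         min_volume_mm3 = 1000) {
  ext <- as.matrix(measurements[, c("extent_x_mm", "extent_y_mm",
                                    "extent_z_mm")])
  measurements$below_min_size <- apply(ext < min_extent_mm, 1, any)
  measurements$below_1cm3 <- measurements$v_enhancing_mm3 < min_volume_mm3
  measurements
}

#' @rdname size_filters
#' @param exclude_below_1cm3 if `TRUE`, also drop sub-1-cm^3 lesions.
#' @export
filter_lesions <- function(measurements, exclude_below_1cm3 = FALSE) {
  if (is.null(measurements$below_min_size))
    measurements <- size_filters(measurements)
  keep <- !measurements$below_min_size
  if (exclude_below_1cm3) keep <- keep & !measurements$below_1cm3
  measurements[keep, , drop = FALSE]
}

#' Average two raters' scalar measurements
#'
#' Measurements performed independently by two raters are combined by
#' the arithmetic mean per lesion and measure; the per-rater table is
#' kept for ICC computation.
#'
#' @param rater1,rater2 measurement data.frames with identical
#'   `lesion_id` ordering.
#' @param measures character vector of numeric columns to average.
#' @return `rater1` with the named columns replaced by per-lesion means.
#' @export
average_raters <- function(rater1, rater2,
                           measures = c("washout_ratio", "rcbv_ratio",
                                        "adc_ratio")) {
  stopifnot(identical(rater1$lesion_id, rater2$lesion_id))
  out <- rater1
  for (m in intersect(measures, names(rater1)))
    out[[m]] <- (rater1[[m]] + rater2[[m]]) / 2
  out
}
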