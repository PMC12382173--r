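test_that("level tracing recovers a uniform sphere exactly", {
  sph <- sphere_volume()
  seed <- round(dim(sph$vol$values) / 2)
  mask <- trace_lesion(sph$vol, seed, band = c(1, 3))
  expect_identical(mask, sph$mask)
})

test_that("tracing respects the band and slice connectivity", {
  sph <- sphere_volume()
  seed <- round(dim(sph$vol$values) / 2)
  expect_error(trace_lesion(sph$vol, seed, band = c(3, 4)),
               "outside the band")
  expect_error(trace_lesion(sph$vol, c(500, 1, 1), band = c(1, 3)),
               "outside the grid")
  # two disjoint spheres: only the seeded one is traced
  two <- sphere_volume()
  far <- sphere_volume(center = c(8, 8, 8), radius = 4)
  two$vol$values <- pmax(two$vol$values, far$vol$values)
  mask <- trace_lesion(two$vol, seed, band = c(1, 3))
  expect_identical(mask, two$mask)
  expect_false(any(mask & far$mask))
})

test_that("compartment volumes count labeled voxels times voxel volume", {
  labels <- array(0L, dim = c(10, 10, 5))
  labels[1:4, , 1] <- 1L           # 40 wash-out voxels in the lesion
  labels[5:6, , 1] <- 2L           # 20 late voxels
  m <- structure(list(percent = array(0, dim = dim(labels)),
                      labels = labels, epsilon = 5, affine = diag(4),
                      provenance = list()), class = "washout_map")
  lesion <- array(FALSE, dim = dim(labels))
  lesion[, , 1] <- TRUE
  v <- compartment_volumes(lesion, m, voxel_volume_mm3 = 1)
  expect_equal(unname(v), c(40, 20, 60))
  # all-neutral lesion: zero volumes, undefined ratio
  lesion2 <- array(FALSE, dim = dim(labels))
  lesion2[, , 3] <- TRUE
  v2 <- compartment_volumes(lesion2, m, voxel_volume_mm3 = 1)
  expect_equal(unname(v2), c(0, 0, 0))
  expect_true(is.na(washout_ratio(v2[["v_washout"]], v2[["v_late"]])))
  expect_error(compartment_volumes(lesion & FALSE, m), "empty")
})

test_that("wash-out ratio arithmetic, boundaries and scale invariance", {
  # group-mean volumes: ratio of means differs from the mean of ratios
  expect_equal(washout_ratio(3836, 9156), 3836 / (3836 + 9156))
  expect_equal(washout_ratio(3836, 9156), 0.2953, tolerance = 5e-4)
  expect_equal(washout_ratio(10, 0), 1)
  expect_equal(washout_ratio(0, 10), 0)
  expect_error(washout_ratio(-1, 5), "non-negative")
  set.seed(10)
  for (i in 1:20) {
    vw <- runif(1, 0, 1e4); vl <- runif(1, 0, 1e4); cc <- runif(1, 0.1, 50)
    expect_equal(washout_ratio(vw, vl), washout_ratio(cc * vw, cc * vl))
  }
})

test_that("size filters apply the 3 mm and 1 cm^3 rules boundary-inclusively", {
  rows <- data.frame(
    lesion_id = c("tiny", "at_boundary", "small_vol", "big"),
    extent_x_mm = c(2, 3, 5, 20), extent_y_mm = c(5, 3, 5, 20),
    extent_z_mm = c(5, 3, 5, 20),
    v_enhancing_mm3 = c(50, 27, 999, 8000))
  out <- size_filters(rows)
  expect_equal(out$below_min_size, c(TRUE, FALSE, FALSE, FALSE))
  expect_equal(out$below_1cm3, c(TRUE, TRUE, TRUE, FALSE))
  prim <- filter_lesions(out)
  expect_setequal(prim$lesion_id, c("at_boundary", "small_vol", "big"))
  sens <- filter_lesions(out, exclude_below_1cm3 = TRUE)
  expect_equal(sens$lesion_id, "big")
})

test_that("rCBV ratio averages three slice ROIs against contralateral", {
  vals <- array(1, dim = c(20, 20, 9))
  mk_roi <- function(k, value) {
    m <- array(FALSE, dim = dim(vals))
    m[14:16, 9:11, k] <- TRUE
    vals[m] <<- value
    m
  }
  r1 <- mk_roi(3, 3.0); r2 <- mk_roi(4, 3.5); r3 <- mk_roi(5, 4.0)
  contra <- array(FALSE, dim = dim(vals)); contra[4:6, 9:11, 3:5] <- TRUE
  vol <- volume3d(vals)
  expect_equal(rcbv_ratio(vol, list(r1, r2, r3), contra), 3.5)
  # tumor identical to contralateral gives 1
  vals2 <- array(2, dim = c(20, 20, 9))
  expect_equal(rcbv_ratio(volume3d(vals2), list(r1, r2, r3), contra), 1)
  expect_error(rcbv_ratio(vol, list(r1, r2), contra), "exactly three")
  r_dup <- r1
  expect_error(rcbv_ratio(vol, list(r1, r_dup, r3), contra),
               "distinct slices")
  expect_error(rcbv_ratio(vol, list(r1, r2, r3),
                          array(FALSE, dim = dim(vals))), "empty")
})

test_that("ADC ratio is the tumor/contralateral ROI mean quotient", {
  vals <- array(1, dim = c(10, 10, 4))
  tum <- array(FALSE, dim = dim(vals)); tum[7:8, 4:6, 2] <- TRUE
  con <- array(FALSE, dim = dim(vals)); con[3:4, 4:6, 2] <- TRUE
  vals[tum] <- 1.41
  expect_equal(adc_ratio(volume3d(vals), tum, con), 1.41)
  vals0 <- vals; vals0[con] <- 0
  expect_error(adc_ratio(volume3d(vals0), tum, con), "positive")
})

test_that("measure_lesion summarizes a phantom lesion against truth", {
  sp <- small_spec()
  ph <- render_phantom(sp)
  nm <- normalize_pair(ph$early, ph$late, mask = ph$truth$brain_mask,
                       lesion_mask = ph$truth$enhancing_mask)
  m <- compute_map(nm$fixed_n, nm$late_n, epsilon = 0)
  maps <- render_ancillary_maps(sp, ph$truth)
  row <- measure_lesion("L1", ph$truth$enhancing_mask, m,
                        rcbv_map = maps$rcbv, adc_map = maps$adc,
                        group = "glioblastoma")
  tv <- ph$truth$true_volumes_mm3
  expect_equal(row$v_washout_mm3, unname(tv[1, "washout"]))
  expect_equal(row$v_late_mm3, unname(tv[1, "late"]))
  expect_equal(row$washout_ratio,
               tv[1, "washout"] / (tv[1, "washout"] + tv[1, "late"]),
               ignore_attr = TRUE)
  expect_equal(row$rcbv_ratio, 3.0)
  expect_equal(row$adc_ratio, 1.4)
})

test_that("rater averaging is the arithmetic mean of scalar measures", {
  r1 <- data.frame(lesion_id = c("a", "b"), washout_ratio = c(0.4, 0.2),
                   rcbv_ratio = c(3, 2), adc_ratio = c(1.2, 1.5))
  r2 <- data.frame(lesion_id = c("a", "b"), washout_ratio = c(0.6, 0.3),
                   rcbv_ratio = c(4, 3), adc_ratio = c(1.4, 1.3))
  avg <- average_raters(r1, r2)
  expect_equal(avg$washout_ratio, c(0.5, 0.25))
  expect_equal(avg$rcbv_ratio, c(3.5, 2.5))
  r3 <- r2; r3$lesion_id <- c("b", "a")
  expect_error(average_raters(r1, r3))
})
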