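test_that("rigid transforms compose, invert and round-trip exactly", {
  set.seed(2)
  for (i in 1:20) {
    t1 <- rigid_transform(runif(3, -15, 15), runif(3, -10, 10),
                          center = runif(3, 0, 100))
    ti <- invert_rigid(t1)
    res <- compose_rigid(ti, t1)
    expect_lt(max(abs(res$rotation)), 1e-10)
    expect_lt(max(abs(res$translation)), 1e-9)
    p <- matrix(runif(15, 0, 100), ncol = 3)
    expect_equal(apply_rigid(ti, apply_rigid(t1, p)), p)
    # identity is the neutral element
    expect_equal(rigid_matrix(compose_rigid(t1, rigid_transform())),
                 rigid_matrix(t1))
  }
})

test_that("volume resampling round-trips within interpolation tolerance", {
  # smooth field: trilinear interpolation error is second order, so the
  # there-and-back residual must be small everywhere
  grid <- volume3d(array(0, dim = c(40, 40, 30)), spacing = c(2, 2, 2))
  cw <- voxel_world_coords(grid)
  r2 <- (cw$x - 40)^2 + (cw$y - 40)^2 + (cw$z - 30)^2
  grid$values <- 100 * exp(-r2 / (2 * 20^2))
  tr <- rigid_transform(c(4, -3, 5), c(3.5, -2.5, 1.5),
                        center = c(40, 40, 30))
  fwd <- resample_volume(grid, grid, tr, fill = 0)
  back <- resample_volume(fwd, grid, invert_rigid(tr), fill = 0)
  interior <- r2 < 25^2
  err <- abs(back$values[interior] - grid$values[interior])
  expect_lt(max(err), 1)
  expect_lt(median(err), 0.25)
})

test_that("self-registration returns the identity transform", {
  sp <- small_spec()
  ph <- render_phantom(sp)
  reg <- register_rigid(ph$early, ph$early, levels = c(4, 2))
  expect_lt(max(abs(reg$transform$rotation)), 1e-3)
  expect_lt(max(abs(reg$transform$translation)), 1e-3)
  expect_true(reg$converged)
  # metric trace is high everywhere for a perfect pair
  expect_true(all(reg$metric_trace > 0.99))
})

test_that("a known pure translation is recovered with opposite sign", {
  sp <- small_spec(motion = rigid_transform(translation = c(3, -2, 1)))
  ph <- render_phantom(sp)
  reg <- register_rigid(ph$early, ph$late)
  expect_equal(reg$transform$translation, c(-3, 2, -1), tolerance = 0.5 / 3)
  expect_lt(max(abs(reg$transform$rotation)), 0.5)
})

test_that("mutual information metric also recovers a known shift", {
  sp <- small_spec(motion = rigid_transform(translation = c(4, 0, -2)))
  ph <- render_phantom(sp)
  reg <- register_rigid(ph$early, ph$late, metric = "mi")
  expect_equal(reg$transform$translation, c(-4, 0, 2), tolerance = 0.5 / 4)
})

test_that("disjoint fields of view raise a registration error", {
  a <- volume3d(array(rnorm(16^3), dim = c(16, 16, 16)),
                spacing = c(1, 1, 1))
  b <- volume3d(array(rnorm(16^3), dim = c(16, 16, 16)),
                spacing = c(1, 1, 1), origin = c(500, 500, 500))
  expect_error(register_rigid(a, b), "overlap")
  expect_error(register_rigid(volume3d(array(0, c(8, 8, 8))), a),
               "16 voxels")
})

test_that("normalization of an identical pair is the identity map", {
  sp <- small_spec()
  ph <- render_phantom(sp)
  nm <- normalize_pair(ph$early, ph$early, mask = ph$truth$brain_mask)
  expect_equal(nm$report$gain, 1, tolerance = 1e-6)
  expect_equal(nm$report$offset, 0, tolerance = 1e-6)
  expect_equal(nm$fixed_n$values, nm$late_n$values, tolerance = 1e-9)
})

test_that("an exact linear intensity relation is inverted exactly", {
  sp <- small_spec()
  ph <- render_phantom(sp)
  scaled <- volume3d(2 * ph$early$values + 5, affine = ph$early$affine)
  nm <- normalize_pair(ph$early, scaled, mask = ph$truth$brain_mask)
  expect_equal(nm$report$gain, 0.5, tolerance = 1e-9)
  expect_equal(nm$report$offset, -2.5, tolerance = 1e-6)
  expect_equal(nm$late_n$values, nm$fixed_n$values, tolerance = 1e-9)
})

test_that("normalization reduces the paired difference under a bias field", {
  sp <- small_spec(bias_amplitude = 0.1, seed = 3)
  ph <- render_phantom(sp)
  nm <- normalize_pair(ph$early, ph$late, mask = ph$truth$brain_mask,
                       lesion_mask = ph$truth$enhancing_mask)
  expect_lt(nm$report$median_abs_diff_post, nm$report$median_abs_diff_pre)
})

test_that("normalization is idempotent and needs a real reference set", {
  sp <- small_spec(noise_sigma = 2, seed = 4)
  ph <- render_phantom(sp)
  nm <- normalize_pair(ph$early, ph$late, mask = ph$truth$brain_mask,
                       lesion_mask = ph$truth$enhancing_mask)
  nm2 <- normalize_pair(nm$fixed_n, nm$late_n, mask = ph$truth$brain_mask,
                        lesion_mask = ph$truth$enhancing_mask)
  expect_equal(nm2$report$gain, 1, tolerance = 1e-3)
  tiny <- ph$truth$brain_mask & FALSE
  tiny[1:5, 1:5, 1:5] <- TRUE
  expect_error(normalize_pair(ph$early, ph$late, mask = tiny), "< 1000")
})

test_that("volumes round-trip through NIfTI with their affine", {
  sp <- small_spec()
  ph <- render_phantom(sp)
  f <- tempfile(fileext = ".nii.gz")
  on.exit(unlink(f))
  write_volume(ph$early, f)
  back <- read_volume(f)
  expect_equal(back$values, ph$early$values, tolerance = 1e-6)
  expect_equal(back$affine, ph$early$affine, tolerance = 1e-6)
})
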