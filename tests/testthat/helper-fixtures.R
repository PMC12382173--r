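# Shared fixtures, all generated in code.

# Compact phantom for unit tests: smaller grid and lesion keep single
# tests fast while exercising the same code paths as the default spec.
small_spec <- function(..., lesion_radius = 9,
                       lesion_offset = c(15, 2, 0)) {
  grid <- c(48, 48, 36)
  center <- (grid - 1) / 2 * 2
  phantom_spec(grid_shape = grid, voxel_size_mm = 2,
               lesions = list(two_compartment_lesion(
                 center + lesion_offset, radius = lesion_radius)),
               ...)
}

# Tie-aware AUC by explicit pair enumeration (independent oracle for the
# rank-based implementation).
auc_brute <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}

# ICC(2,k) from aov() mean squares (independent oracle for the direct
# sums-of-squares implementation).
icc2k_aov <- function(x) {
  long <- data.frame(value = as.vector(x),
                     subject = factor(rep(seq_len(nrow(x)), ncol(x))),
                     rater = factor(rep(seq_len(ncol(x)), each = nrow(x))))
  ms <- summary(stats::aov(value ~ subject + rater, data = long))[[1]][
    , "Mean Sq"]
  msb <- ms[1]; msj <- ms[2]; mse <- ms[3]
  unname((msb - mse) / (msb + (msj - mse) / nrow(x)))
}

# Uniform-intensity sphere in an empty volume, for tracing tests.
sphere_volume <- function(dims = c(32, 32, 24), center = dims / 2,
                          radius = 6, value = 2, spacing = 1) {
  vol <- volume3d(array(0, dim = dims), spacing = rep(spacing, 3))
  cw <- voxel_world_coords(vol)
  m <- (cw$x - center[1] * spacing)^2 + (cw$y - center[2] * spacing)^2 +
    (cw$z - center[3] * spacing)^2 <= (radius * spacing)^2
  vol$values[m] <- value
  list(vol = vol, mask = m)
}
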