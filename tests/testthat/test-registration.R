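# fast config for the small smooth test volumes
fast_reg_config <- function(...) {
  registration_config(pyramid_levels = 2L, translation_bound_mm = 12,
                      coarse_step_mm = 6, rotation_bound_deg = 10,
                      coarse_step_deg = 5, smoothing_sigma_mm = 2,
                      maxit = 120L, ...)
}

test_that("mutual information is invariant under monotone intensity rescaling", {
  set.seed(51)
  a <- rgamma(5000, 2); b <- a + rnorm(5000, sd = 0.3)
  mi0 <- mutual_information(a, b, 32)
  expect_gt(mi0, 0)
  expect_equal(mutual_information(2 * a + 3, b, 32), mi0, tolerance = 1e-12)
  expect_equal(mutual_information(a, 10 * b - 1, 32), mi0, tolerance = 1e-12)
  expect_error(mutual_information(rep(1, 100), a[1:100]), "degenerate")
})

test_that("self-registration returns the identity", {
  vol <- tiny_blob_volume()
  T <- mi_rigid_register(vol, vol, fast_reg_config())
  expect_lt(max(abs(T$translation_mm)), 0.2)
  expect_lt(max(abs(T$rotation_deg)), 0.2)
})

test_that("pure translations are recovered to sub-voxel accuracy", {
  vol <- tiny_blob_volume()
  vs <- attr(vol, "voxel_size_mm")
  d_true <- c(3 * vs[1], 0, 0)   # 3 voxels along x
  Ttrue <- rigid_transform(translation_mm = d_true)
  moving <- apply_transform(vol, invert_transform(Ttrue))

  # oracle: exhaustive integer-voxel-shift MI grid search
  fvals <- as.numeric(vol)
  best <- c(NA, -Inf)
  for (s in -5:5) {
    shifted <- apply_transform(moving,
                               rigid_transform(translation_mm = c(s * vs[1], 0, 0)),
                               "nearest")
    keep <- fvals > stats::quantile(fvals, 0.5)
    mi <- mutual_information(fvals[keep], as.numeric(shifted)[keep], 32)
    if (mi > best[2]) best <- c(s, mi)
  }
  expect_equal(best[1], 3)

  T <- mi_rigid_register(moving, vol, fast_reg_config())
  expect_lt(sqrt(sum((T$translation_mm - d_true)^2)), 0.5 * vs[1])
  expect_lt(max(abs(T$rotation_deg)), 0.5)
})

test_that("axial rotations are recovered within a degree", {
  vol <- tiny_blob_volume()
  Ttrue <- rigid_transform(rotation_deg = c(5, 0, 0))
  moving <- apply_transform(vol, invert_transform(Ttrue))

  # oracle: exhaustive 0.5-degree MI sweep over the axial rotation
  fvals <- as.numeric(vol)
  keep <- fvals > stats::quantile(fvals, 0.5)
  sweep_angles <- seq(-10, 10, by = 0.5)
  mis <- vapply(sweep_angles, function(ang) {
    r <- apply_transform(moving, rigid_transform(rotation_deg = c(ang, 0, 0)))
    mutual_information(fvals[keep], as.numeric(r)[keep], 32)
  }, 0)
  expect_equal(sweep_angles[which.max(mis)], 5, tolerance = 0.51)

  T <- mi_rigid_register(moving, vol, fast_reg_config())
  expect_lt(abs(T$rotation_deg[1] - 5), 1)
})

test_that("degenerate images are rejected", {
  flat <- image_volume(array(1, c(32, 32, 8)), 3, role = "recon")
  vol <- tiny_blob_volume()
  expect_error(mi_rigid_register(flat, flat, fast_reg_config()), "degenerate")
  expect_error(mi_rigid_register(vol, flat, fast_reg_config()), "degenerate")
})
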