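test_that("forward projection is linear and vanishes on zero images", {
  g <- tiny_geometry()
  z <- image_volume(array(0, c(32, 32, 8)), 3, role = "activity")
  expect_true(all(unclass(forward_project(z, g)) == 0))

  x <- tiny_blob_volume()
  set.seed(41)
  y <- image_volume(array(runif(32 * 32 * 8), c(32, 32, 8)), 3, role = "activity")
  fp <- function(v) unclass(forward_project(v, g))
  lin <- fp(image_volume(2.5 * unclass(x) + 0.7 * unclass(y), 3, role = "activity"))
  expect_equal(lin, 2.5 * fp(x) + 0.7 * fp(y), tolerance = 1e-10)
  expect_true(all(fp(x) >= 0))
})

test_that("central ray through a uniform disk integrates to its diameter", {
  g <- tiny_geometry()
  disk <- disk_volume(32, 3, radius_mm = 30)
  g1 <- scanner_geometry(n_angles = g$n_angles, n_radial_bins = g$n_radial_bins,
                         n_slices = 1L, radial_spacing_mm = 3,
                         slice_spacing_mm = 3, tof_sigma_mm = 0)
  fp <- unclass(forward_project(disk, g1))
  central <- fp[(seq_len(g1$n_angles) - 1) * g1$n_radial_bins +
                  (g1$n_radial_bins + 1) / 2 + 0.5, 1]
  # chord through the centre = 2R, within discretisation tolerance
  expect_true(all(abs(central - 60) / 60 < 0.08))
})

test_that("back projection is the exact adjoint of forward projection", {
  g <- tiny_geometry()
  set.seed(42)
  x <- image_volume(array(runif(32 * 32 * 8), c(32, 32, 8)), 3, role = "activity")
  y <- matrix(runif(g$n_angles * g$n_radial_bins * g$n_slices),
              g$n_angles * g$n_radial_bins, g$n_slices)
  lhs <- sum(unclass(forward_project(x, g)) * y)
  rhs <- sum(unclass(back_project(sinogram_set(y, g, check_counts = FALSE), x, g)) *
               unclass(x))
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("event binning conserves counts and hits the right cells", {
  g <- tiny_geometry()
  ev <- tibble::tibble(
    t_s = c(0.5, 1.5, 2.5, 3.5, 4.5),
    angle_idx = c(1L, 5L, 5L, 12L, 30L),
    r_idx = c(3L, 7L, 7L, 20L, 32L),
    slice_idx = c(1L, 2L, 2L, 8L, 4L),
    pos_x_mm = 0, pos_y_mm = 0, pos_z_mm = 0)
  s <- bin_events(ev, c(0, 5), g)
  expect_equal(sum(s), 5)
  a <- as.array(s)  # (slice, angle, radial)
  expect_equal(a[1, 1, 3], 1)
  expect_equal(a[2, 5, 7], 2)
  expect_equal(a[8, 12, 20], 1)
  expect_equal(a[4, 30, 32], 1)
  expect_equal(sum(unclass(bin_events(ev, c(10, 20), g))), 0)
  expect_equal(sum(unclass(bin_events(ev, c(0, 2), g))), 2)
})

test_that("attenuation factors follow the Beer-Lambert closed form", {
  g1 <- scanner_geometry(n_angles = 4L, n_radial_bins = 64L, n_slices = 1L,
                         radial_spacing_mm = 2.5, slice_spacing_mm = 2.5)
  # slab: uniform mu = 0.0096/mm over a 100 mm thickness along y, spanning x
  a <- array(0, c(64, 64, 1))
  ys <- (seq_len(64) - 32.5) * 2.5
  a[, abs(ys) <= 50, 1] <- 0.0096
  mu <- image_volume(a, 2.5, role = "mu_map")
  zero_mu <- image_volume(array(0, c(64, 64, 1)), 2.5, role = "mu_map")
  expect_true(all(attenuation_factors(zero_mu, g1) == 1))
  fac <- attenuation_factors(mu, g1)
  # the angle-0 view integrates along y: rays through the slab see exp(-0.96)
  central <- fac[32, 1]
  expect_equal(central, exp(-0.96), tolerance = 0.01)
  # factors shrink monotonically as mu scales up
  fac2 <- attenuation_factors(image_volume(2 * a, 2.5, role = "mu_map"), g1)
  expect_true(all(fac2 <= fac + 1e-12))
  expect_true(all(fac > 0 & fac <= 1))
})
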