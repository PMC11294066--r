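test_that("degenerate sources behave as expected", {
  g <- tiny_geometry()
  zero <- image_volume(array(0, c(32, 32, 8)), 3, role = "activity")
  tr <- make_trajectory(list(), 10)
  expect_identical(nrow(simulate_events(zero, NULL, tr, g, 1000, seed = 1)), 0L)
  expect_error(simulate_events(tiny_blob_volume(), NULL, tr, g, -5), "positive")

  # point source, no TOF blur, no motion, no attenuation: all positions
  # fall inside the source voxel
  a <- array(0, c(32, 32, 8)); a[16, 20, 4] <- 1
  src <- image_volume(a, 3, role = "activity")
  p <- voxel_centers(src)[16 + 19 * 32 + 3 * 32 * 32, ]
  ev <- simulate_events(src, NULL, tr, g, 2000, seed = 2)
  expect_gt(nrow(ev), 0)
  pos <- cbind(ev$pos_x_mm, ev$pos_y_mm, ev$pos_z_mm)
  expect_true(all(abs(sweep(pos, 2, p)) <= 1.5 + 1e-12))
})

test_that("event totals follow Poisson statistics of the requested rate", {
  g <- tiny_geometry()
  vol <- tiny_blob_volume()
  tr <- make_trajectory(list(), 20)
  ev <- simulate_events(vol, NULL, tr, g, 2000, seed = 3)
  lam <- 2000 * 20
  expect_gte(nrow(ev), qpois(0.005, lam))
  expect_lte(nrow(ev), qpois(0.995, lam))
  expect_true(!is.unsorted(ev$t_s))
  expect_true(all(ev$r_idx >= 1 & ev$r_idx <= g$n_radial_bins))
  expect_true(all(ev$slice_idx >= 1 & ev$slice_idx <= g$n_slices))
})

test_that("same seed reproduces the stream exactly; seeds differ otherwise", {
  g <- tiny_geometry(tof_sigma_mm = 10)
  vol <- tiny_blob_volume()
  tr <- make_trajectory(list(list(time_s = 5, translation_mm = c(5, 0, 0),
                                  rotation_deg = c(0, 0, 0))), 10)
  e1 <- simulate_events(vol, NULL, tr, g, 3000, seed = 42)
  e2 <- simulate_events(vol, NULL, tr, g, 3000, seed = 42)
  e3 <- simulate_events(vol, NULL, tr, g, 3000, seed = 43)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
})

test_that("translating the source shifts mean event positions accordingly", {
  g <- tiny_geometry()
  a <- array(0, c(32, 32, 8)); a[12:20, 12:20, 3:6] <- 1
  vol <- image_volume(a, 3, role = "activity")
  tr0 <- make_trajectory(list(), 20)
  tr1 <- make_trajectory(list(list(time_s = 0.5, translation_mm = c(6, -3, 0),
                                   rotation_deg = c(0, 0, 0))), 20)
  e0 <- simulate_events(vol, NULL, tr0, g, 3000, seed = 5)
  e1 <- simulate_events(vol, NULL, tr1, g, 3000, seed = 5)
  e1 <- e1[e1$t_s >= 0.5, ]
  d <- c(mean(e1$pos_x_mm) - mean(e0$pos_x_mm),
         mean(e1$pos_y_mm) - mean(e0$pos_y_mm),
         mean(e1$pos_z_mm) - mean(e0$pos_z_mm))
  # Monte-Carlo tolerance: ~3 SE of the mean position
  se <- 3 * sd(e0$pos_x_mm) / sqrt(nrow(e0))
  expect_true(all(abs(d - c(6, -3, 0)) < 3 * se + 0.3))
})

test_that("attenuation thinning reduces counts by the survival factors", {
  g <- tiny_geometry()
  vol <- tiny_blob_volume()
  mu <- image_volume(array(0.0096 * (unclass(vol) > 0.01), dim(vol)), 3,
                     role = "mu_map")
  tr <- make_trajectory(list(), 20)
  e_free <- simulate_events(vol, NULL, tr, g, 3000, seed = 6)
  e_att <- simulate_events(vol, mu, tr, g, 3000, seed = 6)
  expect_lt(nrow(e_att), nrow(e_free))
  expect_gt(nrow(e_att), 0.2 * nrow(e_free))
})
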