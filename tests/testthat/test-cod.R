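test_that("per-bin COD equals the hand-computed mean of event positions", {
  ev <- tibble::tibble(
    t_s = c(0.1, 0.4, 0.9, 1.2, 1.5, 1.8),
    angle_idx = 1L, r_idx = 1L, slice_idx = 1L,
    pos_x_mm = c(1, 2, 3, 10, 20, 30),
    pos_y_mm = c(-1, 0, 1, 5, 5, 5),
    pos_z_mm = c(0, 0, 0, 1, 2, 3))
  tr <- compute_cod_trace(ev, 3)
  expect_equal(tr$n_events, c(3L, 3L, 0L))
  expect_equal(tr$cod_x_mm[1:2], c(mean(c(1, 2, 3)), mean(c(10, 20, 30))))
  expect_equal(tr$cod_y_mm[1:2], c(0, 5))
  expect_true(is.na(tr$cod_x_mm[3]))
})

test_that("COD is translation-equivariant", {
  set.seed(31)
  ev <- tibble::tibble(
    t_s = runif(500, 0, 5), angle_idx = 1L, r_idx = 1L, slice_idx = 1L,
    pos_x_mm = rnorm(500), pos_y_mm = rnorm(500), pos_z_mm = rnorm(500))
  d <- c(7.5, -2.25, 11)
  ev2 <- dplyr::mutate(ev, pos_x_mm = pos_x_mm + d[1],
                       pos_y_mm = pos_y_mm + d[2], pos_z_mm = pos_z_mm + d[3])
  t1 <- compute_cod_trace(ev, 5)
  t2 <- compute_cod_trace(ev2, 5)
  expect_equal(t2$cod_x_mm - t1$cod_x_mm, rep(d[1], 5))
  expect_equal(t2$cod_y_mm - t1$cod_y_mm, rep(d[2], 5))
  expect_equal(t2$cod_z_mm - t1$cod_z_mm, rep(d[3], 5))
})

test_that("statistical noise follows the root-n law", {
  set.seed(32)
  n <- 4000
  ev <- tibble::tibble(
    t_s = runif(n, 0, 4), angle_idx = 1L, r_idx = 1L, slice_idx = 1L,
    pos_x_mm = rnorm(n, sd = 30), pos_y_mm = rnorm(n, sd = 30),
    pos_z_mm = rnorm(n, sd = 30))
  tr <- estimate_stat_noise(compute_cod_trace(ev, 4), ev)
  # doubling counts scales sigma by 1/sqrt(2): compare two bins directly
  expect_equal(tr$sigma_x_mm[1] / tr$sigma_x_mm[2],
               sqrt(tr$n_events[2] / tr$n_events[1]))
  # stationary stream: empirical COD scatter matches the estimate within 50%
  # (only 4 bins here; the tight Monte-Carlo check lives in the acceptance
  # suite with 10,000 bins)
  expect_lt(abs(sd(tr$cod_x_mm) / mean(tr$sigma_x_mm) - 1), 0.9)
})

test_that("detector finds injected steps and stays quiet on constant traces", {
  # constant COD: no detections
  flat <- simulate_cod_trace(100, events_per_bin = 1000,
                             per_event_sd_mm = c(30, 30, 30), seed = 33)
  flat$cod_x_mm <- 0; flat$cod_y_mm <- 0; flat$cod_z_mm <- 0
  expect_length(detect_motion(flat), 0L)

  # 10-sigma step at bin 61 (t = 60 s): exactly one detection within [59, 62]
  sd_bin <- 30 / sqrt(1000)
  stepped <- simulate_cod_trace(120, events_per_bin = 1000,
                                per_event_sd_mm = c(30, 30, 30),
                                steps = data.frame(bin = 61, dx = 10 * sd_bin,
                                                   dy = 0, dz = 0),
                                seed = 34)
  mt <- detect_motion(stepped)
  expect_length(mt, 1L)
  expect_gte(mt, 59); expect_lte(mt, 62)
})

test_that("short traces and empty bins are handled gracefully", {
  short <- simulate_cod_trace(2, seed = 35)
  expect_warning(mt <- detect_motion(short), "shorter than 3")
  expect_length(mt, 0L)

  tr <- simulate_cod_trace(50, seed = 36)
  tr$n_events[25] <- 0L
  tr$cod_x_mm[25] <- NA; tr$cod_y_mm[25] <- NA; tr$cod_z_mm[25] <- NA
  tr$sigma_x_mm[25] <- NA; tr$sigma_y_mm[25] <- NA; tr$sigma_z_mm[25] <- NA
  expect_warning(detect_motion(tr), "bridged")
})

test_that("MFF segmentation applies the 5-s rejection rule exactly", {
  s0 <- segment_mffs(numeric(0), 180)
  expect_equal(nrow(s0$mffs), 1L)
  expect_equal(s0$rejected_s, 0)

  s1 <- segment_mffs(c(10, 13), 180)
  expect_equal(s1$mffs$t_start_s, c(0, 13))
  expect_equal(s1$mffs$t_end_s, c(10, 180))
  expect_equal(s1$rejected_s, 3)

  s2 <- segment_mffs(2, 180)
  expect_equal(nrow(s2$mffs), 1L)
  expect_equal(s2$mffs$t_start_s, 2)
  expect_equal(s2$rejected_s, 2)

  expect_error(segment_mffs(c(1, 3), 4), "no usable MFF")
  expect_error(segment_mffs(200, 180), "inside")
})

test_that("retained plus rejected duration always equals the scan length", {
  set.seed(37)
  for (rep in 1:25) {
    k <- sample(0:8, 1)
    mts <- sort(sample(seq(1, 179), k))
    seg <- tryCatch(segment_mffs(mts, 180), error = function(e) NULL)
    if (is.null(seg)) next
    expect_equal(sum(seg$mffs$t_end_s - seg$mffs$t_start_s) + seg$rejected_s, 180)
    expect_true(all(seg$mffs$t_end_s - seg$mffs$t_start_s >= 5))
  }
})
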