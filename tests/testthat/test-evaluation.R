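# small label volume with all 13 phantom codes laid out in stripes
toy_roiset <- function(gm_mask = NULL) {
  lab <- array(0L, c(13, 4, 2))
  for (code in 0:12) lab[code + 1, , ] <- code
  roi_set(image_volume(lab, 3, role = "labels"), gm_mask = gm_mask)
}

test_that("the SUVR gray-matter mask thresholds against the cerebellum mean", {
  rs <- toy_roiset()
  # uniform image: every ratio is exactly 1.0 and the strict threshold
  # leaves the mask empty
  uni <- image_volume(array(2, c(13, 4, 2)), 3, role = "recon")
  expect_true(all(gm_mask_from_suvr(uni, rs) == 0))

  # image at 2x the cerebellum mean inside GM, 0.5x outside: mask == GM
  img <- array(1.0, c(13, 4, 2))
  img[3:13, , ] <- 4.0   # GM codes 2..12 live in rows 3..13
  img[5, , ] <- 2.0      # cerebellum row defines the reference mean
  vol <- image_volume(img, 3, role = "recon")
  mask <- gm_mask_from_suvr(vol, rs)
  expect_equal(unclass(mask), (img > 2) * 1, ignore_attr = TRUE)

  # hand-built ratios: cerebellum mean 2 -> mask = voxels strictly above 2
  img2 <- img; img2[7, , ] <- 2.0  # one GM region exactly at the threshold
  mask2 <- gm_mask_from_suvr(image_volume(img2, 3, role = "recon"), rs)
  expect_equal(sum(mask2[7, , ]), 0)

  # zero cerebellum mean is an error
  img3 <- img; img3[5, , ] <- 0
  expect_error(gm_mask_from_suvr(image_volume(img3, 3, role = "recon"), rs),
               "cerebellum")
})

test_that("regional SUV means match hand computation and scale invariance", {
  rs <- toy_roiset()
  uni <- image_volume(array(7.5, c(13, 4, 2)), 3, role = "recon")
  rep1 <- roi_suv_mean(uni, rs)
  expect_equal(rep1$suv_mean, rep(7.5, 11))
  expect_setequal(rep1$region, gm_region_names())

  set.seed(61)
  img <- image_volume(array(runif(13 * 4 * 2), c(13, 4, 2)), 3, role = "recon")
  rep2 <- roi_suv_mean(img, rs)
  for (code in c(2L, 7L, 12L)) {
    rg <- petmoco:::phantom_label_table()$region[code + 1]
    expect_equal(rep2$suv_mean[rep2$region == rg], mean(img[code + 1, , ]))
  }
  # SUV scaling leaves percent differences unchanged
  rep2s <- roi_suv_mean(img, rs, scaling = list(dose_MBq = 250, weight_kg = 70))
  pc_raw <- percent_change(rep2, rep1)
  uni_s <- roi_suv_mean(uni, rs, scaling = list(dose_MBq = 250, weight_kg = 70))
  pc_scl <- percent_change(rep2s, uni_s)
  expect_equal(pc_scl$percent_change, pc_raw$percent_change)
})

test_that("percent changes and their summaries are exact", {
  rs <- toy_roiset()
  set.seed(62)
  img <- image_volume(array(runif(13 * 4 * 2, 1, 2), c(13, 4, 2)), 3, role = "recon")
  ref <- roi_suv_mean(img, rs)
  expect_equal(percent_change(ref, ref)$percent_change, rep(0, 11))
  shr <- ref; shr$suv_mean <- 0.9 * shr$suv_mean
  pc <- percent_change(shr, ref)
  expect_equal(pc$percent_change, rep(-10, 11), tolerance = 1e-12)

  vals <- seq(-16, 4, by = 2)  # 11 hand-set region changes
  test <- ref; test$suv_mean <- ref$suv_mean * (1 + vals / 100)
  pc2 <- percent_change(test, ref)
  expect_equal(sort(pc2$percent_change), sort(as.numeric(vals)))
  expect_equal(attr(pc2, "mean_pct"), mean(vals))
  expect_equal(attr(pc2, "sd_pct"), sd(vals))
})

test_that("the 5% frontal-lobe rule classifies motion, boundary inclusive", {
  rs <- toy_roiset()
  base <- roi_suv_mean(image_volume(array(3, c(13, 4, 2)), 3, role = "recon"), rs)
  bump_frontal <- function(pct) {
    r <- base
    r$suv_mean[r$region == "frontal"] <- 3 * (1 + pct / 100)
    r
  }
  expect_equal(as.character(classify_motion(base, base)), "small")
  expect_equal(as.character(classify_motion(bump_frontal(12.9), base)), "large")
  expect_equal(as.character(classify_motion(bump_frontal(5.0), base)), "large")
  expect_equal(as.character(classify_motion(bump_frontal(4.99), base)), "small")
  expect_equal(as.character(classify_motion(bump_frontal(-6), base)), "large")
  # monotone in the magnitude of the frontal change
  cls <- vapply(c(0, 2, 4.9, 5, 8, 20),
                function(p) as.character(classify_motion(bump_frontal(p), base)), "")
  expect_identical(cls, c("small", "small", "small", "large", "large", "large"))
})

test_that("motion distances match closed forms for translations and rotations", {
  ph <- std_phantom()
  rs <- roi_set(ph$labels)
  seg <- segment_mffs(60, 180)
  # identity everywhere: zero distance
  d0 <- hm_distance(list(rigid_transform(), rigid_transform()), seg, rs)
  expect_true(all(d0$by_region$mean_mm == 0))
  expect_true(all(d0$by_region$max_mm == 0))

  # pure translation (3,4,0): every region moves exactly 5 mm
  Tt <- rigid_transform(translation_mm = c(3, 4, 0))
  dt <- hm_distance(list(rigid_transform(), Tt), seg, rs)
  expect_equal(dt$by_region$max_mm, rep(5, 11), tolerance = 1e-12)
  # duration weighting: 60 s at 0 mm, 120 s at 5 mm
  expect_equal(dt$by_region$mean_mm, rep(5 * 120 / 180, 11), tolerance = 1e-12)
  # per-minute split: minute 1 still, minutes 2-3 moved
  pm <- tidyr::pivot_wider(dt$per_minute, names_from = "minute",
                           values_from = "mean_mm")
  expect_true(all(pm$`1` == 0) && all(pm$`2` == 5) && all(pm$`3` == 5))

  # pure rotation theta about z: distance = 2 r sin(theta/2) at the mean
  # in-plane radius (closed form vs the voxel-mapping implementation)
  theta <- 12
  Tr <- rigid_transform(rotation_deg = c(theta, 0, 0))
  dr <- hm_distance(list(rigid_transform(), Tr), seg, rs)
  ctrs <- voxel_centers(ph$labels)
  for (rg in c("frontal", "thalamus", "occipital")) {
    code <- match(rg, gm_region_names()) + 1L
    ix <- which(as.integer(ph$labels) == code)
    rbar <- mean(sqrt(ctrs[ix, 1]^2 + ctrs[ix, 2]^2))
    closed <- 2 * rbar * sin(theta / 2 * pi / 180)
    expect_equal(dr$by_region$max_mm[dr$by_region$region == rg], closed,
                 tolerance = 0.02)
  }
})

test_that("region reports survive a write/read round trip", {
  rs <- toy_roiset()
  set.seed(63)
  img <- image_volume(array(runif(13 * 4 * 2, 1, 2), c(13, 4, 2)), 3, role = "recon")
  ref <- roi_suv_mean(image_volume(array(1.5, c(13, 4, 2)), 3, role = "recon"), rs)
  test <- roi_suv_mean(img, rs)
  seg <- segment_mffs(60, 180)
  dist <- hm_distance(list(rigid_transform(),
                           rigid_transform(translation_mm = c(3, 4, 0))),
                      seg, roi_set(std_phantom()$labels))
  rep <- region_report(test, ref, dist)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_region_report(rep, path)
    back <- read_region_report(path)
    expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})
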