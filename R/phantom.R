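#' Names of the 11 composite gray-matter regions
#'
#' The evaluation layer summarises uptake over 11 composite gray-matter
#' regions (the standard composite regions used in brain FDG reporting).
#'
#' @return character vector of length 11.
#' @export
gm_region_names <- function() {
  c("amygdala", "caudate", "cerebellum", "frontal", "hippocampus",
    "insula", "occipital", "parietal", "putamen", "temporal", "thalamus")
}

# label codes: 0 background, 1 white matter, 2..12 GM regions in
# gm_region_names() order
phantom_label_table <- function() {
  tibble::tibble(
    label = 0:12,
    region = c("background", "white_matter", gm_region_names())
  )
}

# relative uptake per region for the "fdg" profile (white matter = 1);
# mimics the usual FDG contrast: cortex above cerebellum, mesial temporal
# structures lowest among GM, striatum highest. Mean GM uptake ~ 4x WM.
fdg_uptake_profile <- function() {
  c(amygdala = 3.8, caudate = 4.4, cerebellum = 3.6, frontal = 4.2,
    hippocampus = 3.9, insula = 4.2, occipital = 4.6, parietal = 4.2,
    putamen = 4.6, temporal = 4.0, thalamus = 4.2)
}

#' Generate a digital brain phantom
#'
#' Builds an ellipsoidal head phantom with a cortical gray-matter shell split
#' into lobes, subcortical gray-matter blobs, white matter, a uniform
#' soft-tissue attenuation map, and an integer label volume carrying the 11
#' composite gray-matter regions plus white matter and background.
#'
#' Two uptake profiles are available. `"fdg"` (the default study condition)
#' assigns each gray-matter region a realistic relative uptake
#' (cortex > cerebellum > mesial temporal, mean GM:WM about 4:1), which keeps
#' the cerebellum-referenced SUV-ratio gray-matter mask well defined.
#' `"uniform"` gives every gray-matter voxel exactly `gm_wm_ratio` times the
#' white-matter uptake.
#'
#' @param shape integer length-3 grid size, each >= 32.
#' @param voxel_size_mm voxel size in mm (scalar or length 3). Default 3 mm
#'   isotropic.
#' @param gm_wm_ratio target gray:white uptake ratio (default 4).
#' @param region_profile `"fdg"` or `"uniform"`.
#' @param mu_tissue_mm linear attenuation coefficient of soft tissue in 1/mm
#'   (default 0.0096, the 511 keV water value).
#' @return A list with elements `activity`, `mu_map`, `labels`
#'   (all [image_volume()]) and `regions` (label lookup tibble).
#' @export
make_phantom <- function(shape = c(64, 64, 32), voxel_size_mm = 3,
                         gm_wm_ratio = 4, region_profile = c("fdg", "uniform"),
                         mu_tissue_mm = 0.0096) {
  region_profile <- match.arg(region_profile)
  shape <- as.integer(shape)
  if (length(shape) != 3L) stop("`shape` must have 3 elements", call. = FALSE)
  for (ax in 1:3)
    if (is.na(shape[ax]) || shape[ax] < 32L)
      stop(sprintf("`shape` axis %d must be >= 32 (got %s)", ax, shape[ax]),
           call. = FALSE)
  if (gm_wm_ratio <= 0) stop("`gm_wm_ratio` must be positive", call. = FALSE)
  vs <- if (length(voxel_size_mm) == 1L) rep(voxel_size_mm, 3L) else voxel_size_mm

  # world grid centred at the origin
  xs <- (seq_len(shape[1]) - (shape[1] + 1) / 2) * vs[1]
  ys <- (seq_len(shape[2]) - (shape[2] + 1) / 2) * vs[2]
  zs <- (seq_len(shape[3]) - (shape[3] + 1) / 2) * vs[3]
  X <- array(rep(xs, times = shape[2] * shape[3]), dim = shape)
  Y <- array(rep(rep(ys, each = shape[1]), times = shape[3]), dim = shape)
  Z <- array(rep(zs, each = shape[1] * shape[2]), dim = shape)

  # head semi-axes scale with the grid extent, leaving margin for motion
  ext <- (shape - 1) * vs
  ax3 <- c(0.38, 0.46, 0.46) * ext        # x, y, z semi-axes in mm
  U <- X / ax3[1]; V <- Y / ax3[2]; W <- Z / ax3[3]
  rho <- sqrt(U^2 + V^2 + W^2)

  head <- rho <= 1
  brain <- rho <= 0.95
  shell <- brain & rho >= 0.78

  lab <- array(0L, dim = shape)
  lab[brain] <- 1L  # white matter default

  code <- function(region) match(region, gm_region_names()) + 1L

  # cortical shell partition (first match wins)
  assign_shell <- function(mask, region) {
    sel <- shell & mask & lab == 1L
    lab[sel] <<- code(region)
  }
  assign_shell(W < -0.45 & V < 0, "cerebellum")
  assign_shell(W < -0.05 & abs(U) > 0.30, "temporal")
  assign_shell(V > 0.30, "frontal")
  assign_shell(V < -0.30, "occipital")
  assign_shell(W > 0.40, "parietal")
  assign_shell(abs(U) > 0.45, "temporal")
  assign_shell(W > 0, "parietal")
  assign_shell(TRUE, "temporal")

  # subcortical blobs (normalised centre, normalised semi-axes), mirrored in x
  blob <- function(cu, cv, cw, su, sv, sw, region) {
    for (s in c(-1, 1)) {
      m <- ((U - s * cu) / su)^2 + ((V - cv) / sv)^2 + ((W - cw) / sw)^2 <= 1
      sel <- m & lab == 1L & rho < 0.78
      lab[sel] <<- code(region)
    }
  }
  blob(0.14, -0.08, 0.02, 0.14, 0.16, 0.20, "thalamus")
  blob(0.18, 0.20, 0.18, 0.10, 0.20, 0.18, "caudate")
  blob(0.36, 0.05, 0.00, 0.12, 0.18, 0.18, "putamen")
  blob(0.30, -0.28, -0.30, 0.12, 0.22, 0.15, "hippocampus")
  blob(0.28, 0.16, -0.36, 0.11, 0.13, 0.14, "amygdala")
  # insula: deep lateral cortical band
  for (s in c(-1, 1)) {
    m <- abs(U - s * 0.58) < 0.10 & abs(V) < 0.30 & abs(W) < 0.28
    sel <- m & lab == 1L & rho < 0.78
    lab[sel] <- code("insula")
  }

  uptake <- numeric(13)  # indexed by label + 1
  uptake[1] <- 0   # background
  uptake[2] <- 1   # white matter
  if (region_profile == "uniform") {
    uptake[3:13] <- gm_wm_ratio
  } else {
    prof <- fdg_uptake_profile()
    uptake[3:13] <- prof[gm_region_names()] * gm_wm_ratio / 4
  }
  act <- array(uptake[lab + 1L], dim = shape)

  mu <- array(0, dim = shape)
  mu[head] <- mu_tissue_mm

  list(activity = image_volume(act, vs, role = "activity"),
       mu_map = image_volume(mu, vs, role = "mu_map"),
       labels = image_volume(lab, vs, role = "labels"),
       regions = phantom_label_table())
}
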