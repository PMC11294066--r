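#' Registration configuration
#'
#' Controls the two-level coarse-to-fine mutual-information search:
#' an exhaustive coarse grid over translations (and axial rotations) at a
#' downsampled pyramid level, followed by derivative-free (Nelder-Mead)
#' refinement over all 6 rigid parameters, finishing at full resolution.
#' Fully deterministic: fixed start, fixed grid ordering, no restarts.
#'
#' @param n_histogram_bins joint-histogram bins per axis (>= 8, default 32).
#' @param pyramid_levels pyramid depth (>= 1, default 2): level k is
#'   downsampled by `2^(k-1)`.
#' @param translation_bound_mm coarse-search half-range for translations.
#' @param coarse_step_mm coarse translation grid step.
#' @param rotation_bound_deg coarse-search half-range for the axial (z)
#'   rotation.
#' @param coarse_step_deg coarse rotation grid step.
#' @param smoothing_sigma_mm Gaussian pre-smoothing SD applied to both
#'   images before the metric is evaluated (regularises the MI surface of
#'   noisy frame reconstructions; 0 disables).
#' @param maxit Nelder-Mead iteration cap per level.
#' @param mask_quantile moving/fixed voxels below this intensity quantile of
#'   the fixed image are excluded from the metric (head-support mask).
#' @param max_metric_points cap on the number of voxels entering the metric;
#'   above it a deterministic regular stride subset is used.
#' @return A `registration_config`.
#' @export
registration_config <- function(n_histogram_bins = 32L, pyramid_levels = 2L,
                                translation_bound_mm = 20,
                                coarse_step_mm = 6,
                                rotation_bound_deg = 15,
                                coarse_step_deg = 5,
                                smoothing_sigma_mm = 5,
                                maxit = 150L,
                                mask_quantile = 0.5,
                                max_metric_points = 20000L) {
  if (n_histogram_bins < 8L) stop("`n_histogram_bins` must be >= 8", call. = FALSE)
  if (pyramid_levels < 1L) stop("`pyramid_levels` must be >= 1", call. = FALSE)
  structure(list(n_histogram_bins = as.integer(n_histogram_bins),
                 pyramid_levels = as.integer(pyramid_levels),
                 translation_bound_mm = translation_bound_mm,
                 coarse_step_mm = coarse_step_mm,
                 rotation_bound_deg = rotation_bound_deg,
                 coarse_step_deg = coarse_step_deg,
                 smoothing_sigma_mm = smoothing_sigma_mm,
                 maxit = as.integer(maxit),
                 mask_quantile = mask_quantile,
                 max_metric_points = as.integer(max_metric_points)),
            class = "registration_config")
}

#' Mutual information between two intensity samples
#'
#' Joint-histogram mutual information (nats) over paired samples, with
#' equal-width bins spanning each sample's range.
#'
#' @param a,b numeric vectors of equal length.
#' @param n_bins histogram bins per axis.
#' @return scalar MI in nats.
#' @export
mutual_information <- function(a, b, n_bins = 32L) {
  n <- length(a)
  if (n == 0L) return(0)
  ra <- range(a); rb <- range(b)
  if (ra[1] == ra[2] || rb[1] == rb[2])
    stop("degenerate intensity distribution", call. = FALSE)
  ia <- pmin(n_bins, 1L + floor((a - ra[1]) / (ra[2] - ra[1]) * n_bins))
  ib <- pmin(n_bins, 1L + floor((b - rb[1]) / (rb[2] - rb[1]) * n_bins))
  joint <- tabulate(ia + (ib - 1L) * n_bins, nbins = n_bins * n_bins) / n
  pa <- tabulate(ia, nbins = n_bins) / n
  pb <- tabulate(ib, nbins = n_bins) / n
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  h(pa) + h(pb) - h(joint)
}

# negative MI of fixed vs moving resampled through T(params)
# params = (tx, ty, tz, rz, ry, rx); center fixed at the volume centre
mi_objective <- function(fixed, moving, config) {
  pts <- voxel_centers(fixed)
  fvals <- as.numeric(fixed)
  thr <- stats::quantile(fvals, config$mask_quantile)
  mask <- fvals > thr
  pts <- pts[mask, , drop = FALSE]
  fvals <- fvals[mask]
  if (nrow(pts) > config$max_metric_points) {
    stride <- ceiling(nrow(pts) / config$max_metric_points)
    keep <- seq(1L, nrow(pts), by = stride)
    pts <- pts[keep, , drop = FALSE]
    fvals <- fvals[keep]
  }
  if (length(unique(fvals)) < 2L)
    stop("degenerate intensity distribution", call. = FALSE)
  force(moving)
  function(par) {
    T <- rigid_transform(rotation_deg = par[4:6], translation_mm = par[1:3])
    q <- map_points(T, pts)
    mvals <- sample_volume(moving, world_to_voxel(moving, q), "linear")
    if (length(unique(mvals)) < 2L) return(0)
    -mutual_information(fvals, mvals, config$n_histogram_bins)
  }
}

#' Mutual-information rigid registration
#'
#' Estimates the rigid transform `T` mapping reference-space (fixed-image)
#' points into the moving frame's space, by maximising the joint-histogram
#' mutual information between the fixed image and the `T`-resampled moving
#' image. Search: exhaustive coarse grid over 3D translations crossed with
#' axial rotations at the coarsest pyramid level, then Nelder-Mead over all
#' 6 parameters at each level up to full resolution. Deterministic given the
#' configuration.
#'
#' @param moving the frame image to align ([image_volume()]).
#' @param fixed the reference frame image on the same grid.
#' @param config a [registration_config()].
#' @return A [rigid_transform()] (convention: reference to frame; resample
#'   the moving frame onto the reference grid with it directly).
#' @export
mi_rigid_register <- function(moving, fixed, config = registration_config()) {
  if (!isTRUE(all.equal(dim(moving), dim(fixed))))
    stop("`moving` and `fixed` must share a grid", call. = FALSE)
  if (max(fixed) == min(fixed) || max(moving) == min(moving))
    stop("degenerate intensity distribution", call. = FALSE)

  fixed_s <- gaussian_smooth(fixed, config$smoothing_sigma_mm)
  moving_s <- gaussian_smooth(moving, config$smoothing_sigma_mm)
  levels <- rev(seq_len(config$pyramid_levels))  # coarsest first
  par <- c(0, 0, 0, 0, 0, 0)

  # exhaustive grid one level coarser than the refinement pyramid
  f0 <- 2L^config$pyramid_levels
  cf <- tryCatch(downsample_volume(fixed_s, f0), error = function(e) NULL)
  cm <- tryCatch(downsample_volume(moving_s, f0), error = function(e) NULL)
  if (!is.null(cf) && !is.null(cm)) {
    obj0 <- mi_objective(cf, cm, config)
    tr <- seq(-config$translation_bound_mm, config$translation_bound_mm,
              by = config$coarse_step_mm)
    rz <- seq(-config$rotation_bound_deg, config$rotation_bound_deg,
              by = config$coarse_step_deg)
    best <- obj0(par)
    for (a in rz) for (x in tr) for (y in tr) for (z in tr) {
      v <- obj0(c(x, y, z, a, 0, 0))
      if (v < best) { best <- v; par <- c(x, y, z, a, 0, 0) }
    }
  }

  for (li in seq_along(levels)) {
    f <- 2L^(levels[li] - 1L)
    fx <- if (f > 1L) downsample_volume(fixed_s, f) else fixed_s
    mv <- if (f > 1L) downsample_volume(moving_s, f) else moving_s
    obj <- mi_objective(fx, mv, config)
    scale_deg <- 2 / max(attr(fx, "voxel_size_mm"))  # ~deg per mm step
    res <- stats::optim(par, obj, method = "Nelder-Mead",
                        control = list(maxit = config$maxit, reltol = 1e-8,
                                       parscale = c(1, 1, 1, rep(1 / scale_deg, 3))))
    par <- res$par
  }
  rigid_transform(rotation_deg = par[4:6], translation_mm = par[1:3])
}
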