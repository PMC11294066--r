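#' Reconstruction configuration
#'
#' @param n_iterations outer iterations (default 3, the clinical schedule).
#' @param n_subsets ordered subsets per iteration (default 10); must divide
#'   the geometry's angle count.
#' @param use_attenuation include attenuation factors in the system model.
#' @param postfilter_fwhm_mm full width at half maximum of the Gaussian
#'   post-reconstruction filter applied to the final image (default 6 mm,
#'   the usual clinical practice; 0 disables). Applied identically to every
#'   reconstruction, it sets a common nominal resolution so that downstream
#'   comparisons between resampled and unresampled images are not dominated
#'   by sub-voxel interpolation blur.
#' @return A `recon_config`.
#' @export
recon_config <- function(n_iterations = 3L, n_subsets = 10L,
                         use_attenuation = TRUE, postfilter_fwhm_mm = 6) {
  if (n_iterations < 1L || n_subsets < 1L)
    stop("`n_iterations` and `n_subsets` must be >= 1", call. = FALSE)
  if (postfilter_fwhm_mm < 0)
    stop("`postfilter_fwhm_mm` must be >= 0", call. = FALSE)
  structure(list(n_iterations = as.integer(n_iterations),
                 n_subsets = as.integer(n_subsets),
                 use_attenuation = isTRUE(use_attenuation),
                 postfilter_fwhm_mm = postfilter_fwhm_mm),
            class = "recon_config")
}

# interleaved balanced subsets: angle a -> subset (a - 1) mod n_subsets + 1
subset_rows <- function(geometry, n_subsets) {
  nr <- geometry$n_radial_bins
  lapply(seq_len(n_subsets), function(s) {
    angs <- seq(s, geometry$n_angles, by = n_subsets)
    as.vector(outer(seq_len(nr), (angs - 1L) * nr, `+`))
  })
}

# uniform initial image inside the field-of-view cylinder
osem_initial <- function(template, geometry) {
  d <- dim(template)
  vs <- attr(template, "voxel_size_mm")
  or <- attr(template, "origin_mm")
  xs <- or[1] + (seq_len(d[1]) - 1) * vs[1]
  ys <- or[2] + (seq_len(d[2]) - 1) * vs[2]
  rad <- geometry$n_radial_bins / 2 * geometry$radial_spacing_mm
  fov <- outer(xs^2, ys^2, `+`) <= rad^2
  x0 <- array(0, dim = d)
  x0[rep(fov, d[3])] <- 1
  x0
}

#' OSEM / MLEM reconstruction
#'
#' Ordered-subset expectation maximization for Poisson sinogram data under
#' the per-slice parallel-beam model, with optional attenuation factors in
#' the forward model. With `n_subsets = 1` this is plain MLEM, whose Poisson
#' log-likelihood is nondecreasing at every iteration. The update per subset
#' `s` is the standard multiplicative step
#' `x <- x * [P_s' (a_s y_s / (a_s P_s x))] / [P_s' a_s]`,
#' with `a = 1` when no attenuation map is given. Voxels with zero
#' sensitivity are forced to 0 and 0/0 ratios are treated as 0.
#'
#' @param sinogram a [sinogram_set()] of counts.
#' @param config a [recon_config()].
#' @param mu_map attenuation map ([image_volume()], 1/mm) aligned to this
#'   frame, or `NULL` for no attenuation correction.
#' @param image_template an [image_volume()] defining the output grid;
#'   defaults to a centred grid of `n_radial x n_radial x n_slices` voxels at
#'   the geometry's spacings (or the `mu_map` grid when given).
#' @return An [image_volume()] (role `"recon"`) in count scale, carrying the
#'   time-window duration as attribute `duration_s`.
#' @export
osem <- function(sinogram, config = recon_config(), mu_map = NULL,
                 image_template = NULL) {
  geometry <- attr(sinogram, "geometry")
  if (geometry$n_angles %% config$n_subsets != 0L)
    stop("`n_subsets` must divide the geometry's angle count", call. = FALSE)
  if (is.null(image_template)) {
    image_template <- mu_map %||% image_volume(
      array(0, dim = c(geometry$n_radial_bins, geometry$n_radial_bins,
                       geometry$n_slices)),
      c(geometry$radial_spacing_mm, geometry$radial_spacing_mm,
        geometry$slice_spacing_mm))
  }
  use_mu <- config$use_attenuation && !is.null(mu_map)
  y <- sino_matrix(sinogram, geometry)
  w <- attr(sinogram, "t_window_s")
  duration <- if (!is.null(w)) diff(w) else NA_real_

  if (sum(y) == 0) {
    warning("all-zero sinogram: returning zero image")
    out <- vol_like(array(0, dim = dim(image_template)), image_template,
                    role = "recon")
    attr(out, "duration_s") <- duration
    return(out)
  }

  P <- projector_matrix(geometry, image_template)
  att <- if (use_mu) attenuation_factors(mu_map, geometry) else
    matrix(1, nrow(y), ncol(y))
  rows <- subset_rows(geometry, config$n_subsets)

  X <- matrix(as.numeric(osem_initial(image_template, geometry)),
              nrow = dim(image_template)[1] * dim(image_template)[2])
  for (it in seq_len(config$n_iterations)) {
    for (s in seq_len(config$n_subsets)) {
      r <- rows[[s]]
      Ps <- P[r, , drop = FALSE]
      as_ <- att[r, , drop = FALSE]
      ybar <- as_ * as.matrix(Ps %*% X)
      ratio <- y[r, , drop = FALSE] / ybar
      ratio[!is.finite(ratio)] <- 0
      num <- as.matrix(Matrix::crossprod(Ps, as_ * ratio))
      sens <- as.matrix(Matrix::crossprod(Ps, as_))
      upd <- num / sens
      upd[sens == 0] <- 0
      X <- X * upd
    }
  }
  out <- vol_like(array(X, dim = dim(image_template)), image_template,
                  role = "recon")
  if (config$postfilter_fwhm_mm > 0)
    out <- gaussian_smooth(out, config$postfilter_fwhm_mm / 2.3548)
  attr(out, "duration_s") <- duration
  out
}

#' Poisson log-likelihood of a reconstruction
#'
#' `sum(y log(ybar) - ybar)` over sinogram bins with positive expected
#' counts (bins with `ybar = 0` and `y > 0` contribute `-Inf`). Used to
#' monitor EM monotonicity.
#'
#' @param sinogram a [sinogram_set()] of counts.
#' @param image the reconstructed [image_volume()].
#' @param mu_map optional attenuation map entering the forward model.
#' @return scalar log-likelihood (additive constants dropped).
#' @export
poisson_loglik <- function(sinogram, image, mu_map = NULL) {
  geometry <- attr(sinogram, "geometry")
  y <- sino_matrix(sinogram, geometry)
  ybar <- unclass(forward_project(image, geometry))
  if (!is.null(mu_map)) ybar <- ybar * attenuation_factors(mu_map, geometry)
  pos <- ybar > 0
  if (any(y[!pos] > 0)) return(-Inf)
  sum(y[pos] * log(ybar[pos])) - sum(ybar)
}
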