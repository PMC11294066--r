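#' Per-slice parallel-beam projector
#'
#' The system model is a stack of independent 2D parallel-beam sinograms:
#' each in-plane pixel deposits its value into the radial bin its centre
#' projects to at every view angle, split linearly between the two nearest
#' bins and weighted by the in-plane voxel size so that forward projection of
#' an attenuation map in 1/mm yields dimensionless line integrals. The
#' adjoint (back projection) is the exact matrix transpose, which keeps the
#' EM update self-consistent.
#'
#' The sparse system matrix depends only on the geometry and the in-plane
#' grid, so it is cached per (geometry, grid) pair within a session.
#'
#' @param geometry a [scanner_geometry()].
#' @param image an [image_volume()] whose grid the projector should match.
#' @return A `dgCMatrix` of size `(n_angles * n_radial_bins) x n_pixels`
#'   (rows ordered radial-fastest within angle).
#' @keywords internal
projector_matrix <- function(geometry, image) {
  d <- dim(image)
  vs <- attr(image, "voxel_size_mm")
  or <- attr(image, "origin_mm")
  if (abs(vs[1] - vs[2]) > 1e-9)
    stop("projector requires square in-plane voxels", call. = FALSE)
  key <- paste(geometry$n_angles, geometry$n_radial_bins,
               geometry$radial_spacing_mm, d[1], d[2], vs[1], or[1], or[2],
               sep = "|")
  cached <- projector_cache[[key]]
  if (!is.null(cached)) return(cached)

  xs <- or[1] + (seq_len(d[1]) - 1) * vs[1]
  ys <- or[2] + (seq_len(d[2]) - 1) * vs[2]
  px <- rep(xs, times = d[2])
  py <- rep(ys, each = d[1])
  npix <- d[1] * d[2]
  nr <- geometry$n_radial_bins
  angs <- geometry_angles(geometry)

  ii <- vector("list", geometry$n_angles)
  jj <- vector("list", geometry$n_angles)
  xx <- vector("list", geometry$n_angles)
  for (a in seq_len(geometry$n_angles)) {
    u <- radial_coordinate(geometry, px * cos(angs[a]) + py * sin(angs[a]))
    i0 <- floor(u)
    w1 <- 1 - (u - i0)
    row0 <- (a - 1L) * nr
    ok0 <- i0 >= 1 & i0 <= nr
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= nr
    ii[[a]] <- c(row0 + i0[ok0], row0 + i0[ok1] + 1)
    jj[[a]] <- c(which(ok0), which(ok1))
    xx[[a]] <- c(w1[ok0], (1 - w1)[ok1]) * vs[1]
  }
  P <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(geometry$n_angles * nr, npix))
  projector_cache[[key]] <- P
  P
}

projector_cache <- new.env(parent = emptyenv())

# reshape a volume matching the geometry into an (npix x n_slices) matrix
vol_to_slab <- function(image, geometry) {
  d <- dim(image)
  if (d[3] != geometry$n_slices)
    stop("image axial dimension does not match geometry slices", call. = FALSE)
  matrix(as.numeric(image), d[1] * d[2], d[3])
}

#' Forward and back projection
#'
#' `forward_project()` computes per-slice parallel-beam line integrals of a
#' volume; `back_project()` applies the exact adjoint to a sinogram-shaped
#' array.
#'
#' @param image an [image_volume()] on the reconstruction grid.
#' @param geometry a [scanner_geometry()].
#' @return `forward_project()` returns a `sinogram_set` with real-valued
#'   data; `back_project()` returns an [image_volume()].
#' @export
forward_project <- function(image, geometry) {
  P <- projector_matrix(geometry, image)
  proj <- as.matrix(P %*% vol_to_slab(image, geometry))
  sinogram_set(proj, geometry, t_window_s = attr(image, "t_window_s") %||% c(0, 0),
               check_counts = FALSE)
}

#' @param sinogram a `sinogram_set` (or its data) to back-project.
#' @param image_template an [image_volume()] defining the output grid.
#' @rdname forward_project
#' @export
back_project <- function(sinogram, image_template, geometry = attr(sinogram, "geometry")) {
  P <- projector_matrix(geometry, image_template)
  sl <- sino_matrix(sinogram, geometry)
  img <- as.matrix(Matrix::crossprod(P, sl))
  vol_like(array(img, dim = dim(image_template)), image_template, role = "recon")
}

#' Sinogram container
#'
#' Holds per-slice sinogram data as an `(n_angles * n_radial) x n_slices`
#' matrix (radial index fastest), with its geometry and time window.
#'
#' @param data matrix `(n_angles * n_radial) x n_slices`, or 3D array
#'   `(slice x angle x radial)`.
#' @param geometry a [scanner_geometry()].
#' @param t_window_s length-2 start/end seconds.
#' @param check_counts require nonnegative data.
#' @return A `sinogram_set`.
#' @export
sinogram_set <- function(data, geometry, t_window_s = c(0, 0),
                         check_counts = TRUE) {
  if (is.array(data) && length(dim(data)) == 3L) {
    # (slice x angle x radial) -> matrix
    data <- aperm(data, c(3, 2, 1))
    dim(data) <- c(geometry$n_radial_bins * geometry$n_angles, geometry$n_slices)
  }
  if (!is.matrix(data) ||
      nrow(data) != geometry$n_angles * geometry$n_radial_bins ||
      ncol(data) != geometry$n_slices)
    stop("sinogram shape does not match geometry", call. = FALSE)
  if (check_counts && any(data < 0))
    stop("sinogram counts must be nonnegative", call. = FALSE)
  structure(data, geometry = geometry, t_window_s = as.numeric(t_window_s),
            class = c("sinogram_set", "matrix"))
}

sino_matrix <- function(sinogram, geometry) {
  if (inherits(sinogram, "sinogram_set")) return(unclass(sinogram))
  if (is.matrix(sinogram)) return(sinogram)
  m <- aperm(sinogram, c(3, 2, 1))
  dim(m) <- c(geometry$n_radial_bins * geometry$n_angles, geometry$n_slices)
  m
}

#' @export
print.sinogram_set <- function(x, ...) {
  g <- attr(x, "geometry")
  w <- attr(x, "t_window_s")
  cat(sprintf("<sinogram_set> %d angles x %d radial x %d slices, window [%g, %g) s, total %g\n",
              g$n_angles, g$n_radial_bins, g$n_slices, w[1], w[2], sum(x)))
  invisible(x)
}

#' Convert a sinogram to a (slice x angle x radial) array
#'
#' @param x a `sinogram_set`.
#' @param ... unused.
#' @return 3D array `(slice, angle, radial)`.
#' @export
as.array.sinogram_set <- function(x, ...) {
  g <- attr(x, "geometry")
  a <- unclass(x)
  dim(a) <- c(g$n_radial_bins, g$n_angles, g$n_slices)
  aperm(a, c(3, 2, 1))
}

#' Histogram events into a sinogram
#'
#' Bins events with `t_s` in `[window_s[1], window_s[2])` by their stored
#' `(slice, angle, radial)` projection coordinates. The total count equals
#' the number of events in the window.
#'
#' @param events event tibble (see [simulate_events()]).
#' @param window_s length-2 start/end seconds.
#' @param geometry a [scanner_geometry()].
#' @return A `sinogram_set` of integer counts.
#' @export
bin_events <- function(events, window_s, geometry) {
  sel <- events$t_s >= window_s[1] & events$t_s < window_s[2]
  ev <- events[sel, ]
  nr <- geometry$n_radial_bins
  nrow_s <- nr * geometry$n_angles
  lin <- (ev$slice_idx - 1L) * nrow_s + (ev$angle_idx - 1L) * nr + ev$r_idx
  cnt <- tabulate(lin, nbins = nrow_s * geometry$n_slices)
  sinogram_set(matrix(cnt, nrow_s, geometry$n_slices), geometry,
               t_window_s = window_s)
}

#' Attenuation survival factors
#'
#' Per-LOR survival probabilities `exp(-integral of mu dl)`, computed by
#' forward-projecting the attenuation map.
#'
#' @param mu_map an [image_volume()] in 1/mm, nonnegative.
#' @param geometry a [scanner_geometry()].
#' @return Matrix `(n_angles * n_radial) x n_slices` of factors in `(0, 1]`.
#' @export
attenuation_factors <- function(mu_map, geometry) {
  if (any(mu_map < 0)) stop("`mu_map` must be nonnegative", call. = FALSE)
  exp(-unclass(forward_project(mu_map, geometry)))
}
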