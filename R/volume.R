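#' 3D image volume
#'
#' A minimal container for a 3D scalar grid with physical voxel size and
#' origin. World coordinates are in mm; by default the origin is placed so
#' that the world origin sits at the volume centre (voxel `(i,j,k)` (0-based)
#' has its centre at `origin_mm + c(i,j,k) * voxel_size_mm`).
#'
#' @param data numeric 3D array (all dimensions >= 1).
#' @param voxel_size_mm length-3 positive numeric, voxel edge lengths in mm.
#' @param origin_mm length-3 numeric, world coordinate of the centre of voxel
#'   `(0,0,0)`. Default centres the volume on the world origin.
#' @param role one of `"activity"`, `"mu_map"`, `"labels"`, `"recon"`,
#'   `"mask"`.
#' @return An `image_volume` object (a 3D array with attributes).
#' @export
image_volume <- function(data, voxel_size_mm, origin_mm = NULL,
                         role = c("activity", "mu_map", "labels", "recon", "mask")) {
  role <- match.arg(role)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(voxel_size_mm) == 1L) voxel_size_mm <- rep(voxel_size_mm, 3L)
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("`voxel_size_mm` must be 3 strictly positive values", call. = FALSE)
  d <- dim(data)
  if (is.null(origin_mm)) origin_mm <- -(d - 1) / 2 * voxel_size_mm
  origin_mm <- as.numeric(origin_mm)
  if (length(origin_mm) != 3L || any(!is.finite(origin_mm)))
    stop("`origin_mm` must be 3 finite values", call. = FALSE)
  if (role %in% c("activity", "mu_map") && any(data < 0, na.rm = TRUE))
    stop(sprintf("%s values must be nonnegative", role), call. = FALSE)
  if (role == "labels" && any(data != round(data), na.rm = TRUE))
    stop("label volumes must be integer-valued", call. = FALSE)
  structure(data,
            voxel_size_mm = voxel_size_mm,
            origin_mm = origin_mm,
            role = role,
            class = c("image_volume", "array"))
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<image_volume [%s]> role: %s\n", paste(d, collapse = " x "),
              attr(x, "role")))
  cat(sprintf("  voxel size (mm): %s\n",
              paste(signif(attr(x, "voxel_size_mm"), 4), collapse = " x ")))
  cat(sprintf("  origin (mm): %s\n",
              paste(signif(attr(x, "origin_mm"), 4), collapse = ", ")))
  cat(sprintf("  range: [%g, %g]\n", min(x), max(x)))
  invisible(x)
}

is_image_volume <- function(x) inherits(x, "image_volume")

vol_like <- function(data, template, role = attr(template, "role")) {
  image_volume(data, attr(template, "voxel_size_mm"),
               attr(template, "origin_mm"), role = role)
}

#' World coordinates of every voxel centre
#'
#' @param vol an [image_volume()].
#' @return An `n_voxel x 3` matrix of world mm coordinates, in array
#'   (column-major) order.
#' @export
voxel_centers <- function(vol) {
  d <- dim(vol)
  vs <- attr(vol, "voxel_size_mm")
  or <- attr(vol, "origin_mm")
  xs <- or[1] + (seq_len(d[1]) - 1) * vs[1]
  ys <- or[2] + (seq_len(d[2]) - 1) * vs[2]
  zs <- or[3] + (seq_len(d[3]) - 1) * vs[3]
  cbind(rep(xs, times = d[2] * d[3]),
        rep(rep(ys, each = d[1]), times = d[3]),
        rep(zs, each = d[1] * d[2]))
}

# world mm -> continuous 0-based voxel index
world_to_voxel <- function(vol, pts) {
  vs <- attr(vol, "voxel_size_mm")
  or <- attr(vol, "origin_mm")
  cbind((pts[, 1] - or[1]) / vs[1],
        (pts[, 2] - or[2]) / vs[2],
        (pts[, 3] - or[3]) / vs[3])
}

#' Sample a volume at continuous voxel coordinates
#'
#' Pull values from a volume at arbitrary (0-based, continuous) voxel
#' coordinates, with trilinear or nearest-neighbour interpolation. Samples
#' falling outside the grid return 0.
#'
#' @param vol an [image_volume()] or 3D array.
#' @param idx `n x 3` matrix of continuous 0-based voxel coordinates.
#' @param interpolation `"linear"` or `"nearest"`.
#' @return numeric vector of length `n`.
#' @export
sample_volume <- function(vol, idx, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  d <- dim(vol)
  a <- as.numeric(vol)
  ix <- idx[, 1]; iy <- idx[, 2]; iz <- idx[, 3]
  if (interpolation == "nearest") {
    i <- round(ix); j <- round(iy); k <- round(iz)
    ok <- i >= 0 & i <= d[1] - 1 & j >= 0 & j <= d[2] - 1 & k >= 0 & k <= d[3] - 1
    out <- numeric(length(ix))
    lin <- (i[ok] + 1) + j[ok] * d[1] + k[ok] * d[1] * d[2]
    out[ok] <- a[lin]
    return(out)
  }
  i0 <- floor(ix); j0 <- floor(iy); k0 <- floor(iz)
  fx <- ix - i0; fy <- iy - j0; fz <- iz - k0
  out <- numeric(length(ix))
  # accumulate the 8 corners, skipping out-of-grid corners (implicit zeros)
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di == 0) 1 - fx else fx) *
         (if (dj == 0) 1 - fy else fy) *
         (if (dk == 0) 1 - fz else fz)
    ci <- i0 + di; cj <- j0 + dj; ck <- k0 + dk
    ok <- w > 0 & ci >= 0 & ci <= d[1] - 1 & cj >= 0 & cj <= d[2] - 1 &
      ck >= 0 & ck <= d[3] - 1
    if (any(ok)) {
      lin <- (ci[ok] + 1) + cj[ok] * d[1] + ck[ok] * d[1] * d[2]
      out[ok] <- out[ok] + w[ok] * a[lin]
    }
  }
  out
}

#' Downsample a volume by integer block averaging
#'
#' Used to build coarse registration pyramid levels. Trailing rows that do
#' not fill a block are dropped.
#'
#' @param vol an [image_volume()].
#' @param factor integer >= 1 block edge.
#' @return An [image_volume()] with `factor`-times larger voxels.
#' @export
downsample_volume <- function(vol, factor = 2L) {
  factor <- as.integer(factor)
  if (factor < 1L) stop("`factor` must be >= 1", call. = FALSE)
  if (factor == 1L) return(vol)
  d <- dim(vol)
  nd <- d %/% factor
  if (any(nd < 1L)) stop("volume too small to downsample", call. = FALSE)
  a <- unclass(vol)[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                    seq_len(nd[3] * factor), drop = FALSE]
  dim(a) <- c(factor, nd[1], factor, nd[2], factor, nd[3])
  m <- apply(a, c(2, 4, 6), mean)
  vs <- attr(vol, "voxel_size_mm") * factor
  # new voxel (0,0,0) centre = mean of the first block's centres
  or <- attr(vol, "origin_mm") + (factor - 1) / 2 * attr(vol, "voxel_size_mm")
  image_volume(m, vs, or, role = attr(vol, "role"))
}

#' Read / write NIfTI-1 volumes
#'
#' Volumes are stored as NIfTI-1 with the voxel size carried in `pixdim` and
#' the origin in the affine. Reading recovers data, voxel size and origin.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param vol an [image_volume()].
#' @param role role to assign to the loaded volume.
#' @return `read_volume()` returns an [image_volume()]; `write_volume()`
#'   returns `path` invisibly.
#' @export
read_volume <- function(path, role = "recon") {
  if (!file.exists(path)) stop(sprintf("no such volume file: %s", path), call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- array(as.numeric(img), dim = dim(img))
  vs <- RNifti::pixdim(img)[1:3]
  aff <- RNifti::xform(img)
  # write_volume() stores an axis-aligned LPS-flipped affine; undo the flip
  or <- c(-aff[1, 4], -aff[2, 4], aff[3, 4])
  if (any(!is.finite(or))) or <- NULL
  image_volume(a, vs, origin_mm = or, role = role)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(unclass(vol))
  RNifti::pixdim(img) <- attr(vol, "voxel_size_mm")
  or <- attr(vol, "origin_mm")
  aff <- diag(4)
  aff[1, 1] <- -attr(vol, "voxel_size_mm")[1]
  aff[2, 2] <- -attr(vol, "voxel_size_mm")[2]
  aff[3, 3] <- attr(vol, "voxel_size_mm")[3]
  aff[1:3, 4] <- c(-or[1], -or[2], or[3])
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Separable Gaussian smoothing
#'
#' Smooths a volume with an axis-separable Gaussian kernel of the given SD
#' in mm (truncated at 3 SD, renormalised at the edges). Used to regularise
#' images before mutual-information registration.
#'
#' @param vol an [image_volume()].
#' @param sigma_mm Gaussian SD in mm (scalar; 0 returns the input).
#' @return An [image_volume()] on the same grid.
#' @export
gaussian_smooth <- function(vol, sigma_mm) {
  if (sigma_mm <= 0) return(vol)
  a <- unclass(vol)
  d <- dim(a)
  vs <- attr(vol, "voxel_size_mm")
  for (ax in 1:3) {
    sig <- sigma_mm / vs[ax]
    r <- max(1L, ceiling(3 * sig))
    k <- stats::dnorm(seq(-r, r), sd = sig)
    n <- d[ax]
    K <- matrix(0, n, n)
    for (i in seq_len(n)) {
      j <- i + seq(-r, r)
      ok <- j >= 1 & j <= n
      K[i, j[ok]] <- k[ok] / sum(k[ok])
    }
    m <- switch(ax,
                matrix(a, d[1]),
                matrix(aperm(a, c(2, 1, 3)), d[2]),
                matrix(aperm(a, c(3, 1, 2)), d[3]))
    m <- K %*% m
    a <- switch(ax,
                array(m, d),
                aperm(array(m, d[c(2, 1, 3)]), c(2, 1, 3)),
                aperm(array(m, d[c(3, 1, 2)]), c(2, 3, 1)))
  }
  vol_like(a, vol)
}
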