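#' 6-DOF rigid transform
#'
#' A rigid map of world points, `p -> R (p - center) + center + translation`,
#' with `R` built from intrinsic Z-Y-X Euler angles in degrees. The pipeline
#' convention is that the transform estimated for motion-free frame `i`
#' (`T(i)`) maps reference-space points into frame-`i` space; pull-back
#' resampling of frame `i` onto the reference grid therefore uses `T(i)`
#' directly, while the attenuation map is carried into frame `i` with
#' `T(i)^-1`.
#'
#' @param rotation_deg length-3 numeric, intrinsic Z-Y-X Euler angles (deg).
#' @param translation_mm length-3 numeric (mm).
#' @param center_mm length-3 rotation centre in world mm (default origin).
#' @return A `rigid_transform` object.
#' @export
rigid_transform <- function(rotation_deg = c(0, 0, 0),
                            translation_mm = c(0, 0, 0),
                            center_mm = c(0, 0, 0)) {
  rotation_deg <- as.numeric(rotation_deg)
  translation_mm <- as.numeric(translation_mm)
  center_mm <- as.numeric(center_mm)
  stopifnot(length(rotation_deg) == 3L, length(translation_mm) == 3L,
            length(center_mm) == 3L,
            all(is.finite(c(rotation_deg, translation_mm, center_mm))))
  structure(list(rotation_deg = rotation_deg,
                 translation_mm = translation_mm,
                 center_mm = center_mm),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot (deg): %s | trans (mm): %s | center (mm): %s\n",
              paste(signif(x$rotation_deg, 4), collapse = ", "),
              paste(signif(x$translation_mm, 4), collapse = ", "),
              paste(signif(x$center_mm, 4), collapse = ", ")))
  invisible(x)
}

is_identity_transform <- function(T, tol = 0) {
  all(abs(T$rotation_deg) <= tol) && all(abs(T$translation_mm) <= tol)
}

rotation_matrix <- function(rotation_deg) {
  r <- rotation_deg * pi / 180
  cz <- cos(r[1]); sz <- sin(r[1])
  cy <- cos(r[2]); sy <- sin(r[2])
  cx <- cos(r[3]); sx <- sin(r[3])
  Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
  Ry <- matrix(c(cy, 0, -sy, 0, 1, 0, sy, 0, cy), 3, 3)
  Rx <- matrix(c(1, 0, 0, 0, cx, sx, 0, -sx, cx), 3, 3)
  Rz %*% Ry %*% Rx
}

#' Map points through a rigid transform
#'
#' @param T a [rigid_transform()].
#' @param p a length-3 vector (`map_point`) or an `n x 3` matrix
#'   (`map_points`) of world mm coordinates.
#' @return The mapped point(s), same shape as the input.
#' @export
map_points <- function(T, p) {
  p <- matrix(as.numeric(p), ncol = 3L)
  R <- rotation_matrix(T$rotation_deg)
  ctr <- matrix(T$center_mm, nrow(p), 3, byrow = TRUE)
  p0 <- p - ctr
  p0 %*% t(R) + ctr + matrix(T$translation_mm, nrow(p), 3, byrow = TRUE)
}

#' @rdname map_points
#' @export
map_point <- function(T, p) as.numeric(map_points(T, matrix(p, 1L)))

#' Invert a rigid transform
#'
#' Returns the transform `S` with `S(T(p)) = p` for all points, in the same
#' Euler parameterisation and about the same centre.
#'
#' @param T a [rigid_transform()].
#' @return A [rigid_transform()].
#' @export
invert_transform <- function(T) {
  R <- rotation_matrix(T$rotation_deg)
  Rinv <- t(R)
  # inverse: p -> Rinv (p - center - translation) + center
  #        = Rinv (p - center) + center + [Rinv(-translation) + (Rinv - I)... ]
  # express as rotation about the same centre with translation t':
  # S(p) = Rinv (p - c) + c + t' with t' = Rinv (c + t ... ) solve directly:
  # need S(T(p)) = p; T(p) = R(p - c) + c + t
  # S(q) = Rinv (q - c) + c + t'  =>  S(T(p)) = Rinv(R(p - c) + t) + c + t'
  #       = (p - c) + Rinv t + c + t'  => t' = -Rinv t
  tr <- -as.numeric(Rinv %*% T$translation_mm)
  rigid_transform(euler_from_matrix(Rinv), tr, T$center_mm)
}

#' Compose rigid transforms
#'
#' `compose_transform(A, B)` returns the transform mapping `p` to `A(B(p))`,
#' expressed about `A`'s centre.
#'
#' @param A,B [rigid_transform()] objects.
#' @return A [rigid_transform()].
#' @export
compose_transform <- function(A, B) {
  Ra <- rotation_matrix(A$rotation_deg)
  Rb <- rotation_matrix(B$rotation_deg)
  R <- Ra %*% Rb
  c0 <- A$center_mm
  # A(B(p)) = Ra(Rb(p - cb) + cb + tb - ca) + ca + ta
  # want R (p - c0) + c0 + t
  p0 <- c(0, 0, 0)
  img <- map_point(A, map_point(B, p0))
  tr <- img - as.numeric(R %*% (p0 - c0)) - c0
  rigid_transform(euler_from_matrix(R), tr, c0)
}

# recover intrinsic Z-Y-X Euler angles (deg) from a rotation matrix
euler_from_matrix <- function(R) {
  sy <- -R[3, 1]
  sy <- max(-1, min(1, sy))
  y <- asin(sy)
  if (abs(cos(y)) > 1e-10) {
    z <- atan2(R[2, 1], R[1, 1])
    x <- atan2(R[3, 2], R[3, 3])
  } else {
    # gimbal lock: fold everything into z
    z <- atan2(-R[1, 2], R[2, 2])
    x <- 0
  }
  c(z, y, x) * 180 / pi
}

#' Resample a volume through a rigid transform
#'
#' Pull-back resampling: every output voxel centre `c` receives the input
#' value at `T(c)`; the output grid equals the input grid and samples falling
#' outside the grid are set to 0.
#'
#' @param image an [image_volume()].
#' @param T a [rigid_transform()].
#' @param interpolation `"linear"` or `"nearest"`.
#' @return An [image_volume()] on the same grid.
#' @export
apply_transform <- function(image, T, interpolation = c("linear", "nearest")) {
  interpolation <- match.arg(interpolation)
  if (is_identity_transform(T)) return(image)
  pts <- voxel_centers(image)
  q <- map_points(T, pts)
  idx <- world_to_voxel(image, q)
  vals <- sample_volume(image, idx, interpolation)
  out <- array(vals, dim = dim(image))
  vol_like(out, image)
}

#' Read / write rigid transforms as JSON
#'
#' Transforms are serialised as a list of objects with `rotation_deg`,
#' `translation_mm`, `center_mm` and the point-mapping convention tag
#' `"ref_to_frame"`.
#'
#' @param transforms a [rigid_transform()] or list of them.
#' @param path file path.
#' @return `read_transforms()` returns a list of [rigid_transform()].
#' @export
write_transforms <- function(transforms, path) {
  if (inherits(transforms, "rigid_transform")) transforms <- list(transforms)
  recs <- lapply(transforms, function(T)
    list(rotation_deg = T$rotation_deg, translation_mm = T$translation_mm,
         center_mm = T$center_mm, convention = "ref_to_frame"))
  jsonlite::write_json(recs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transforms
#' @export
read_transforms <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such transform file: %s", path), call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(recs, function(r)
    rigid_transform(r$rotation_deg, r$translation_mm, r$center_mm))
}

#' Tidy a list of per-frame rigid transforms
#'
#' @param x list of [rigid_transform()].
#' @return A tibble with one row per transform.
#' @export
tidy_transforms <- function(x) {
  tibble::tibble(
    frame = seq_along(x),
    rot_z_deg = vapply(x, function(T) T$rotation_deg[1], 0),
    rot_y_deg = vapply(x, function(T) T$rotation_deg[2], 0),
    rot_x_deg = vapply(x, function(T) T$rotation_deg[3], 0),
    trans_x_mm = vapply(x, function(T) T$translation_mm[1], 0),
    trans_y_mm = vapply(x, function(T) T$translation_mm[2], 0),
    trans_z_mm = vapply(x, function(T) T$translation_mm[3], 0)
  )
}
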