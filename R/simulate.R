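#' Simulate a list-mode coincidence event stream
#'
#' Emulates a short single-bed-position brain scan. Per 1 s interval the
#' event count is Poisson with mean `rate_cps`; each event's true
#' annihilation point is drawn proportionally to the activity image moved by
#' the trajectory transform active at that time (uniform jitter within the
#' voxel, uniform time within the second). Events are thinned by the
#' attenuation survival probability `exp(-integral of mu along the LOR)` of
#' a view angle drawn uniformly over the geometry's angles, then assigned the
#' nearest angle/radial/slice projection bins; events falling outside the
#' radial or axial field of view are discarded. The recorded `pos_*_mm` is
#' the true point plus isotropic Gaussian TOF blur.
#'
#' @param activity an [image_volume()] (role `"activity"`).
#' @param mu_map an [image_volume()] in 1/mm on the same grid, or `NULL` to
#'   disable attenuation thinning.
#' @param trajectory a [make_trajectory()] object; its duration sets the scan
#'   length.
#' @param geometry a [scanner_geometry()].
#' @param rate_cps expected true coincidence rate (counts/s), > 0.
#' @param seed integer RNG seed; the same seed reproduces the stream exactly.
#' @return A tibble with columns `t_s`, `angle_idx`, `r_idx`, `slice_idx`
#'   (1-based bins), `pos_x_mm`, `pos_y_mm`, `pos_z_mm`, sorted by `t_s`.
#' @export
simulate_events <- function(activity, mu_map, trajectory, geometry,
                            rate_cps = 5000, seed = 1L) {
  stopifnot(is_image_volume(activity))
  if (rate_cps <= 0) stop("`rate_cps` must be positive", call. = FALSE)
  if (!is.null(mu_map) && any(mu_map < 0))
    stop("`mu_map` must be nonnegative", call. = FALSE)
  duration <- trajectory$duration_s
  n_sec <- as.integer(ceiling(duration))

  p <- as.numeric(activity)
  total <- sum(p)
  empty <- event_tibble(0)
  if (total == 0) return(empty)

  set.seed(as.integer(seed))
  counts <- stats::rpois(n_sec, rate_cps * pmin(1, duration - (seq_len(n_sec) - 1)))
  n <- sum(counts)
  if (n == 0) return(empty)

  # event times: uniform within each second
  sec <- rep(seq_len(n_sec) - 1L, counts)
  t_s <- sec + stats::runif(n)

  # sample reference-space annihilation points from the activity image
  cdf <- cumsum(p) / total
  vox <- findInterval(stats::runif(n), cdf) + 1L
  d <- dim(activity)
  vs <- attr(activity, "voxel_size_mm")
  or <- attr(activity, "origin_mm")
  i <- (vox - 1L) %% d[1]
  j <- ((vox - 1L) %/% d[1]) %% d[2]
  k <- (vox - 1L) %/% (d[1] * d[2])
  pts <- cbind(or[1] + (i + stats::runif(n) - 0.5) * vs[1],
               or[2] + (j + stats::runif(n) - 0.5) * vs[2],
               or[3] + (k + stats::runif(n) - 0.5) * vs[3])

  # move points by the trajectory segment active at each event time
  seg <- segment_at(trajectory, pmin(t_s, duration - 1e-9))
  for (s in unique(seg)) {
    T <- trajectory$transforms[[s]]
    if (!is_identity_transform(T)) {
      sel <- seg == s
      pts[sel, ] <- map_points(T, pts[sel, , drop = FALSE])
    }
  }

  # projection coordinates from the true (moved) point
  ang_idx <- sample.int(geometry$n_angles, n, replace = TRUE)
  th <- geometry_angles(geometry)[ang_idx]
  u <- radial_coordinate(geometry, pts[, 1] * cos(th) + pts[, 2] * sin(th))
  r_idx <- as.integer(round(u))
  s_idx <- as.integer(round(pts[, 3] / geometry$slice_spacing_mm +
                              (geometry$n_slices + 1) / 2))
  keep <- r_idx >= 1L & r_idx <= geometry$n_radial_bins &
    s_idx >= 1L & s_idx <= geometry$n_slices

  # attenuation thinning via the survival factors of the moved mu-map
  if (!is.null(mu_map)) {
    accept <- stats::runif(n)
    for (s in unique(seg)) {
      T <- trajectory$transforms[[s]]
      mu_s <- if (is_identity_transform(T)) mu_map else
        apply_transform(mu_map, invert_transform(T))
      fac <- attenuation_factors(mu_s, geometry)  # (n_angles*n_radial) x n_slices
      sel <- which(seg == s & keep)
      lin <- (ang_idx[sel] - 1L) * geometry$n_radial_bins + r_idx[sel]
      keep[sel] <- accept[sel] < fac[cbind(lin, s_idx[sel])]
    }
  }

  # TOF-estimated positions
  if (geometry$tof_sigma_mm > 0)
    pts <- pts + matrix(stats::rnorm(3 * n, sd = geometry$tof_sigma_mm), n, 3)

  out <- tibble::tibble(
    t_s = t_s[keep], angle_idx = ang_idx[keep], r_idx = r_idx[keep],
    slice_idx = s_idx[keep],
    pos_x_mm = pts[keep, 1], pos_y_mm = pts[keep, 2], pos_z_mm = pts[keep, 3])
  dplyr::arrange(out, .data$t_s)
}

event_tibble <- function(n) {
  tibble::tibble(t_s = numeric(n), angle_idx = integer(n), r_idx = integer(n),
                 slice_idx = integer(n), pos_x_mm = numeric(n),
                 pos_y_mm = numeric(n), pos_z_mm = numeric(n))
}

event_pos_matrix <- function(events) {
  cbind(events$pos_x_mm, events$pos_y_mm, events$pos_z_mm)
}

#' Read / write event streams as CSV
#'
#' Comma-separated with a header row; columns as in [simulate_events()].
#'
#' @param events event tibble.
#' @param path file path.
#' @return `read_events()` returns the event tibble.
#' @export
write_events <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such event file: %s", path), call. = FALSE)
  df <- utils::read.csv(path)
  need <- names(event_tibble(0))
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop(sprintf("event file %s lacks column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  out <- tibble::as_tibble(df[need])
  out$angle_idx <- as.integer(out$angle_idx)
  out$r_idx <- as.integer(out$r_idx)
  out$slice_idx <- as.integer(out$slice_idx)
  out
}
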