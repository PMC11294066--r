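#' Piecewise-constant rigid motion trajectory
#'
#' Builds a step-motion trajectory from a list of discrete repositioning
#' events. The head is assumed aligned with the CT at scan start, so the
#' first segment is always the identity; at each event time the head jumps to
#' the given pose and holds it until the next event.
#'
#' @param spec a list of events, each a list/vector with elements `time_s`,
#'   `translation_mm` (length 3) and `rotation_deg` (length 3, intrinsic
#'   Z-Y-X). Times must be strictly increasing and inside `(0, duration_s)`.
#' @param duration_s scan duration in seconds.
#' @param center_mm rotation centre for all segments (default world origin,
#'   the volume centre).
#' @return A `motion_trajectory` object: tibble-backed list of segments
#'   tiling `[0, duration_s)`.
#' @export
make_trajectory <- function(spec = list(), duration_s, center_mm = c(0, 0, 0)) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  times <- vapply(spec, function(e) as.numeric(e$time_s %||% e[[1]]), 0)
  if (length(times)) {
    if (any(diff(times) <= 0)) stop("event times must be strictly increasing", call. = FALSE)
    if (any(times <= 0 | times >= duration_s))
      stop("event times must lie strictly inside (0, duration_s)", call. = FALSE)
  }
  transforms <- c(list(rigid_transform(center_mm = center_mm)),
                  lapply(spec, function(e) {
                    tr <- e$translation_mm %||% e[[2]]
                    ro <- e$rotation_deg %||% e[[3]]
                    rigid_transform(ro, tr, center_mm)
                  }))
  starts <- c(0, times)
  ends <- c(times, duration_s)
  structure(list(t_start_s = starts, t_end_s = ends, transforms = transforms,
                 duration_s = duration_s),
            class = "motion_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.motion_trajectory <- function(x, ...) {
  cat(sprintf("<motion_trajectory> %d segment(s) over [0, %g) s\n",
              length(x$transforms), x$duration_s))
  print(tidy(x))
  invisible(x)
}

#' Transform active at a given time
#'
#' @param trajectory a [make_trajectory()] object.
#' @param t_s time in seconds (vectorised).
#' @return For scalar `t_s` a [rigid_transform()]; otherwise an integer
#'   vector of segment indices via `segment_at()`.
#' @export
transform_at <- function(trajectory, t_s) {
  i <- segment_at(trajectory, t_s)
  if (length(t_s) == 1L) trajectory$transforms[[i]] else trajectory$transforms[i]
}

#' @rdname transform_at
#' @export
segment_at <- function(trajectory, t_s) {
  i <- findInterval(t_s, trajectory$t_start_s, rightmost.closed = FALSE)
  i[t_s < 0 | t_s >= trajectory$duration_s] <- NA_integer_
  i
}

#' @method tidy motion_trajectory
#' @export
tidy.motion_trajectory <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(segment = seq_along(x$transforms),
                   t_start_s = x$t_start_s, t_end_s = x$t_end_s),
    tidy_transforms(x$transforms)[, -1]
  )
}

#' Read / write motion trajectories as JSON
#'
#' @param trajectory a [make_trajectory()] object.
#' @param path file path.
#' @return `read_trajectory()` returns a `motion_trajectory`.
#' @export
write_trajectory <- function(trajectory, path) {
  recs <- lapply(seq_along(trajectory$transforms), function(i) {
    T <- trajectory$transforms[[i]]
    list(t_start_s = trajectory$t_start_s[i], t_end_s = trajectory$t_end_s[i],
         translation_mm = T$translation_mm, rotation_deg = T$rotation_deg,
         center_mm = T$center_mm)
  })
  jsonlite::write_json(recs, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such trajectory file: %s", path), call. = FALSE)
  recs <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  duration <- recs[[length(recs)]]$t_end_s
  center <- as.numeric(recs[[1]]$center_mm)
  spec <- lapply(recs[-1], function(r)
    list(time_s = r$t_start_s, translation_mm = as.numeric(r$translation_mm),
         rotation_deg = as.numeric(r$rotation_deg)))
  make_trajectory(spec, duration, center)
}
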