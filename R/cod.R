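#' Centroid-of-distribution (COD) trace at 1 Hz
#'
#' The COD is the mean TOF-estimated event position over each 1 s bin; its
#' jumps indicate head motion while its bin-to-bin jitter reflects counting
#' statistics. Empty bins are flagged (`NA` coordinates).
#'
#' @param events event tibble (see [simulate_events()]).
#' @param duration_s scan duration; bins cover `[0, duration_s)`.
#' @return A `cod_trace` tibble: `bin_start_s`, `n_events`, `cod_x_mm`,
#'   `cod_y_mm`, `cod_z_mm`, `sigma_x_mm`, `sigma_y_mm`, `sigma_z_mm` (the
#'   sigma columns are `NA` until [estimate_stat_noise()] fills them).
#' @export
compute_cod_trace <- function(events, duration_s) {
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  n_bins <- as.integer(ceiling(duration_s))
  bin <- findInterval(events$t_s, seq_len(n_bins) - 1L)
  ok <- bin >= 1L & bin <= n_bins
  bin <- bin[ok]
  n <- tabulate(bin, nbins = n_bins)
  sums <- function(v) {
    s <- numeric(n_bins)
    t <- tapply(v[ok], bin, sum)
    s[as.integer(names(t))] <- t
    s
  }
  out <- tibble::tibble(
    bin_start_s = as.numeric(seq_len(n_bins) - 1L),
    n_events = n,
    cod_x_mm = ifelse(n > 0, sums(events$pos_x_mm) / n, NA_real_),
    cod_y_mm = ifelse(n > 0, sums(events$pos_y_mm) / n, NA_real_),
    cod_z_mm = ifelse(n > 0, sums(events$pos_z_mm) / n, NA_real_),
    sigma_x_mm = NA_real_, sigma_y_mm = NA_real_, sigma_z_mm = NA_real_)
  class(out) <- c("cod_trace", class(out))
  out
}

#' Estimate the count-statistics noise of a COD trace
#'
#' The COD of a bin with `n` events is a sample mean, so its statistical SD
#' along each axis is `s / sqrt(n)` where `s` is the per-event positional SD.
#' `s` is estimated globally and robustly from all event coordinates (median
#' absolute deviation scaled to SD), so that head motion — which shifts the
#' whole distribution but barely changes its spread — does not inflate it.
#'
#' @param trace a `cod_trace` from [compute_cod_trace()].
#' @param events the event tibble the trace was computed from.
#' @return The trace with `sigma_*_mm` filled (`NA` for empty bins).
#' @export
estimate_stat_noise <- function(trace, events) {
  s <- c(stats::mad(events$pos_x_mm), stats::mad(events$pos_y_mm),
         stats::mad(events$pos_z_mm))
  n <- trace$n_events
  trace$sigma_x_mm <- ifelse(n > 0, s[1] / sqrt(n), NA_real_)
  trace$sigma_y_mm <- ifelse(n > 0, s[2] / sqrt(n), NA_real_)
  trace$sigma_z_mm <- ifelse(n > 0, s[3] / sqrt(n), NA_real_)
  attr(trace, "per_event_sd_mm") <- s
  trace
}

#' Simulate a stationary (null) COD trace
#'
#' Draws per-bin COD values directly at the trace level: Gaussian around a
#' fixed centroid with the exact root-n statistical SD, with `sigma_*_mm`
#' filled in. Used to calibrate and power-test the detector without the cost
#' of event-level simulation; optional step displacements inject motion.
#'
#' @param n_bins number of 1 s bins.
#' @param events_per_bin events per bin (constant).
#' @param per_event_sd_mm length-3 per-event positional SD (mm).
#' @param steps optional tibble/data.frame with columns `bin` (1-based bin at
#'   which the step takes effect) and `dx`, `dy`, `dz` (mm, cumulative shift
#'   applied from that bin on).
#' @param seed RNG seed.
#' @return A `cod_trace` tibble with sigma columns filled.
#' @export
simulate_cod_trace <- function(n_bins, events_per_bin = 2000,
                               per_event_sd_mm = c(40, 40, 40),
                               steps = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  sd_bin <- per_event_sd_mm / sqrt(events_per_bin)
  mu <- matrix(0, n_bins, 3)
  if (!is.null(steps)) {
    for (r in seq_len(nrow(steps))) {
      b <- steps$bin[r]
      mu[b:n_bins, ] <- mu[b:n_bins, , drop = FALSE] +
        matrix(c(steps$dx[r], steps$dy[r], steps$dz[r]), n_bins - b + 1, 3,
               byrow = TRUE)
    }
  }
  cod <- mu + cbind(stats::rnorm(n_bins, sd = sd_bin[1]),
                    stats::rnorm(n_bins, sd = sd_bin[2]),
                    stats::rnorm(n_bins, sd = sd_bin[3]))
  out <- tibble::tibble(
    bin_start_s = as.numeric(seq_len(n_bins) - 1L),
    n_events = rep(as.integer(events_per_bin), n_bins),
    cod_x_mm = cod[, 1], cod_y_mm = cod[, 2], cod_z_mm = cod[, 3],
    sigma_x_mm = sd_bin[1], sigma_y_mm = sd_bin[2], sigma_z_mm = sd_bin[3])
  class(out) <- c("cod_trace", class(out))
  attr(out, "per_event_sd_mm") <- per_event_sd_mm
  out
}

#' Detect head-motion time points on a COD trace
#'
#' A running-mean z-test: within the current motion-free stretch the
#' count-weighted mean COD is tracked per axis, and each new bin's COD is
#' compared against it using the combined statistical SD
#' `sqrt(s^2/n_bin + s^2/N_accumulated)`. A bin is *flagged* when any axis
#' exceeds the two-sided normal quantile at a Sidak-shared level
#' `1 - (1 - alpha)^(1/3)`, so the per-bin any-axis false-alarm rate is
#' `alpha` under the null. Motion is *declared* when two consecutive bins
#' are flagged (suppressing single-bin count flukes); the motion time is the
#' first flagged bin's start and the running mean restarts there. Flagged
#' bins awaiting confirmation are withheld from the running mean and folded
#' back in if not confirmed. Empty bins are bridged with a warning.
#'
#' @param trace a `cod_trace` with `sigma_*_mm` filled.
#' @param alpha per-bin false-alarm level in `(0, 1)` (default 0.01; the
#'   detector's only knob).
#' @return Numeric vector of motion times (s), with a `diagnostics`
#'   attribute: tibble of `bin_start_s`, `z_max`, `flagged`, `tested`.
#' @export
detect_motion <- function(trace, alpha = 0.01) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  n_bins <- nrow(trace)
  diag_tbl <- tibble::tibble(bin_start_s = trace$bin_start_s,
                             z_max = NA_real_, flagged = FALSE, tested = FALSE)
  if (n_bins < 3L) {
    warning("trace shorter than 3 bins: no motion detection attempted")
    return(structure(numeric(0), diagnostics = diag_tbl))
  }
  if (any(is.na(trace$sigma_x_mm) & trace$n_events > 0))
    stop("sigma_stat not filled: run estimate_stat_noise() first", call. = FALSE)
  if (any(trace$n_events == 0))
    warning("empty 1 s bin(s) bridged during motion detection")

  cod <- cbind(trace$cod_x_mm, trace$cod_y_mm, trace$cod_z_mm)
  nev <- trace$n_events
  # per-event SD recovered from any populated bin: sigma * sqrt(n)
  s <- attr(trace, "per_event_sd_mm")
  if (is.null(s)) {
    b0 <- which(nev > 0)[1]
    s <- c(trace$sigma_x_mm[b0], trace$sigma_y_mm[b0], trace$sigma_z_mm[b0]) *
      sqrt(nev[b0])
  }
  alpha_axis <- 1 - (1 - alpha)^(1 / 3)
  zcrit <- stats::qnorm(1 - alpha_axis / 2)

  motion <- numeric(0)
  sum_w <- c(0, 0, 0); n_cum <- 0          # running weighted sums
  pending <- NA_integer_
  z_max <- rep(NA_real_, n_bins)
  flagged <- logical(n_bins)
  tested <- logical(n_bins)

  for (b in seq_len(n_bins)) {
    nb <- nev[b]
    if (nb == 0) next
    if (n_cum == 0) {
      sum_w <- cod[b, ] * nb; n_cum <- nb
      next
    }
    m <- sum_w / n_cum
    se <- s * sqrt(1 / nb + 1 / n_cum)
    z <- abs(cod[b, ] - m) / se
    z_max[b] <- max(z)
    tested[b] <- TRUE
    if (z_max[b] > zcrit) {
      flagged[b] <- TRUE
      if (!is.na(pending)) {
        # confirmed: motion at the first flagged bin; restart there
        motion <- c(motion, trace$bin_start_s[pending])
        sum_w <- cod[pending, ] * nev[pending] + cod[b, ] * nb
        n_cum <- nev[pending] + nb
        pending <- NA_integer_
      } else {
        pending <- b
      }
    } else {
      if (!is.na(pending)) {
        sum_w <- sum_w + cod[pending, ] * nev[pending]
        n_cum <- n_cum + nev[pending]
        pending <- NA_integer_
      }
      sum_w <- sum_w + cod[b, ] * nb
      n_cum <- n_cum + nb
    }
  }
  diag_tbl$z_max <- z_max
  diag_tbl$flagged <- flagged
  diag_tbl$tested <- tested
  structure(motion, diagnostics = diag_tbl)
}

#' Segment a scan into motion-free frames (MFFs)
#'
#' Intervals between consecutive motion times (and the scan ends) become
#' MFFs; intervals shorter than `min_mff_s` are discarded and their duration
#' accumulated as rejected data.
#'
#' @param motion_times_s sorted motion times strictly inside
#'   `(0, duration_s)`.
#' @param duration_s scan duration (s).
#' @param min_mff_s minimum retained frame length (default 5 s).
#' @return A `motion_segmentation`: list with `motion_times_s`, `mffs`
#'   (tibble `t_start_s`, `t_end_s`), `rejected_s`, `duration_s`.
#' @export
segment_mffs <- function(motion_times_s, duration_s, min_mff_s = 5) {
  motion_times_s <- as.numeric(motion_times_s)
  if (is.unsorted(motion_times_s, strictly = TRUE) && length(motion_times_s) > 1)
    stop("`motion_times_s` must be strictly increasing", call. = FALSE)
  if (any(motion_times_s <= 0 | motion_times_s >= duration_s))
    stop("`motion_times_s` must lie strictly inside (0, duration_s)", call. = FALSE)
  starts <- c(0, motion_times_s)
  ends <- c(motion_times_s, duration_s)
  keep <- (ends - starts) >= min_mff_s
  if (!any(keep)) stop("no usable MFF: all segments shorter than min_mff_s", call. = FALSE)
  mffs <- tibble::tibble(t_start_s = starts[keep], t_end_s = ends[keep])
  structure(list(motion_times_s = motion_times_s, mffs = mffs,
                 rejected_s = duration_s - sum(mffs$t_end_s - mffs$t_start_s),
                 duration_s = duration_s),
            class = "motion_segmentation")
}

#' @export
print.motion_segmentation <- function(x, ...) {
  cat(sprintf("<motion_segmentation> %d MFF(s), %d motion time(s), %.3g s rejected of %g s\n",
              nrow(x$mffs), length(x$motion_times_s), x$rejected_s, x$duration_s))
  print(x$mffs)
  invisible(x)
}

#' @method tidy motion_segmentation
#' @export
tidy.motion_segmentation <- function(x, ...) {
  dplyr::mutate(x$mffs, mff = dplyr::row_number(),
                duration_s = .data$t_end_s - .data$t_start_s,
                .before = 1)
}

#' @method glance motion_segmentation
#' @export
glance.motion_segmentation <- function(x, ...) {
  tibble::tibble(n_mffs = nrow(x$mffs),
                 n_motion_times = length(x$motion_times_s),
                 rejected_s = x$rejected_s,
                 duration_s = x$duration_s)
}

#' Read / write COD traces and segmentations
#'
#' Traces go to CSV (one row per 1 s bin); segmentations to JSON.
#'
#' @param trace a `cod_trace`.
#' @param segmentation a `motion_segmentation`.
#' @param path file path.
#' @return Readers return the reconstructed object.
#' @export
write_cod_trace <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cod_trace
#' @export
read_cod_trace <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such trace file: %s", path), call. = FALSE)
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("cod_trace", class(out))
  out
}

#' @rdname write_cod_trace
#' @export
write_segmentation <- function(segmentation, path) {
  jsonlite::write_json(
    list(motion_times_s = segmentation$motion_times_s,
         mffs = segmentation$mffs,
         rejected_s = segmentation$rejected_s,
         duration_s = segmentation$duration_s),
    path, auto_unbox = FALSE, digits = NA, dataframe = "columns")
  invisible(path)
}

#' @rdname write_cod_trace
#' @export
read_segmentation <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such segmentation file: %s", path), call. = FALSE)
  r <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(motion_times_s = as.numeric(r$motion_times_s),
                 mffs = tibble::as_tibble(r$mffs),
                 rejected_s = as.numeric(r$rejected_s),
                 duration_s = as.numeric(r$duration_s)),
            class = "motion_segmentation")
}
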