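#' Head-motion correction run configuration
#'
#' Bundles the per-stage settings of [run_hmc()] / [run_nmc()].
#'
#' @param duration_s scan duration (s).
#' @param alpha per-bin false-alarm level of the motion detector.
#' @param min_mff_s minimum retained motion-free-frame length (s).
#' @param recon a [recon_config()] for the attenuation-corrected
#'   reconstructions (the no-AC frame reconstructions use the same
#'   iteration schedule with attenuation disabled).
#' @param registration a [registration_config()].
#' @param ct_misalignment optional [rigid_transform()] deliberately applied
#'   to the attenuation map before use, to demonstrate the PET-CT mismatch
#'   artifact; no correction for it is attempted.
#' @return An `hmc_config`.
#' @export
hmc_config <- function(duration_s = 180, alpha = 0.01, min_mff_s = 5,
                       recon = recon_config(),
                       registration = registration_config(),
                       ct_misalignment = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (min_mff_s <= 0) stop("`min_mff_s` must be positive", call. = FALSE)
  structure(list(duration_s = duration_s, alpha = alpha, min_mff_s = min_mff_s,
                 recon = recon, registration = registration,
                 ct_misalignment = ct_misalignment),
            class = "hmc_config")
}

#' Run the full head-motion correction pipeline
#'
#' Three stages, mirroring detection, estimation and correction:
#' \enumerate{
#'   \item COD trace at 1 Hz, statistical-noise estimate, running-mean
#'     z-test motion detection, segmentation into motion-free frames (MFFs)
#'     with frames shorter than `min_mff_s` discarded;
#'   \item per-MFF OSEM reconstruction without attenuation correction, then
#'     mutual-information rigid registration of every frame to the first MFF
#'     (the reference, assumed aligned with the CT so its transform is the
#'     identity), giving `T(i)`;
#'   \item per-MFF attenuation map aligned with `T(i)^-1`, OSEM with
#'     attenuation correction, pull-back of each frame image to reference
#'     space with `T(i)`, voxelwise summation of the count-scale images and
#'     division by the total retained duration.
#' }
#'
#' @param events event tibble spanning the configured duration.
#' @param mu_map attenuation map ([image_volume()], 1/mm) on the
#'   reconstruction grid, aligned with the head at scan start.
#' @param geometry a [scanner_geometry()].
#' @param config an [hmc_config()].
#' @return An `hmc_result`: list with `hmc_image`, `nmc_image` (rate-scale
#'   [image_volume()]s), `transforms` (per-MFF [rigid_transform()]s),
#'   `segmentation`, `trace`, and a per-stage `log` tibble.
#' @export
run_hmc <- function(events, mu_map, geometry, config = hmc_config()) {
  t0 <- Sys.time()
  log <- list()
  note <- function(stage, detail) {
    log[[length(log) + 1L]] <<- tibble::tibble(
      stage = stage, detail = detail,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  }
  mu_used <- if (!is.null(config$ct_misalignment))
    apply_transform(mu_map, config$ct_misalignment) else mu_map

  trace <- compute_cod_trace(events, config$duration_s)
  trace <- estimate_stat_noise(trace, events)
  note("cod", sprintf("%d events in %d bins", nrow(events), nrow(trace)))
  motion <- detect_motion(trace, config$alpha)
  note("detect", sprintf("%d motion time(s): %s", length(motion),
                         paste(motion, collapse = ", ")))
  seg <- segment_mffs(motion, config$duration_s, config$min_mff_s)
  note("segment", sprintf("%d MFF(s), %.3g s rejected", nrow(seg$mffs),
                          seg$rejected_s))

  n_mff <- nrow(seg$mffs)
  noac_cfg <- recon_config(config$recon$n_iterations, config$recon$n_subsets,
                           use_attenuation = FALSE)
  frames <- vector("list", n_mff)
  transforms <- vector("list", n_mff)
  if (n_mff == 1L) note("register", "single usable MFF: plain AC reconstruction")

  noac_ref <- NULL
  for (i in seq_len(n_mff)) {
    win <- c(seg$mffs$t_start_s[i], seg$mffs$t_end_s[i])
    sino <- bin_events(events, win, geometry)
    if (i == 1L) {
      transforms[[1]] <- rigid_transform()
      if (n_mff > 1L) noac_ref <- osem(sino, noac_cfg, image_template = mu_used)
      mu_i <- mu_used
    } else {
      noac_i <- osem(sino, noac_cfg, image_template = mu_used)
      transforms[[i]] <- mi_rigid_register(noac_i, noac_ref, config$registration)
      note("register", sprintf(
        "MFF %d: trans (%s) mm, rot (%s) deg", i,
        paste(signif(transforms[[i]]$translation_mm, 4), collapse = ", "),
        paste(signif(transforms[[i]]$rotation_deg, 4), collapse = ", ")))
      mu_i <- apply_transform(mu_used, invert_transform(transforms[[i]]))
    }
    ac_i <- osem(sino, config$recon, mu_map = mu_i)
    frames[[i]] <- if (i == 1L) ac_i else apply_transform(ac_i, transforms[[i]])
  }
  total_s <- sum(seg$mffs$t_end_s - seg$mffs$t_start_s)
  hmc_sum <- Reduce(`+`, lapply(frames, unclass))
  hmc_image <- vol_like(hmc_sum / total_s, mu_map, role = "recon")
  note("sum", sprintf("%d frame(s) over %.4g retained s", n_mff, total_s))

  nmc_image <- run_nmc(events, mu_used, geometry, config)
  note("nmc", "uncorrected full-duration reconstruction")

  structure(list(hmc_image = hmc_image, nmc_image = nmc_image,
                 transforms = transforms, segmentation = seg, trace = trace,
                 log = dplyr::bind_rows(log)),
            class = "hmc_result")
}

#' Uncorrected (NMC) reconstruction
#'
#' Single OSEM reconstruction with attenuation correction of all events over
#' the full scan, with the unmoved attenuation map, normalised to rate scale
#' by the scan duration.
#'
#' @inheritParams run_hmc
#' @return A rate-scale [image_volume()].
#' @export
run_nmc <- function(events, mu_map, geometry, config = hmc_config()) {
  sino <- bin_events(events, c(0, config$duration_s), geometry)
  img <- osem(sino, config$recon, mu_map = mu_map)
  vol_like(unclass(img) / config$duration_s, mu_map, role = "recon")
}

#' @export
print.hmc_result <- function(x, ...) {
  cat("<hmc_result>\n")
  print(x$segmentation)
  print(tidy_transforms(x$transforms))
  invisible(x)
}

#' @method tidy hmc_result
#' @export
tidy.hmc_result <- function(x, ...) {
  dplyr::bind_cols(tidy(x$segmentation),
                   tidy_transforms(x$transforms)[, -1])
}

#' @method glance hmc_result
#' @export
glance.hmc_result <- function(x, ...) {
  tr <- tidy_transforms(x$transforms)
  disp <- sqrt(tr$trans_x_mm^2 + tr$trans_y_mm^2 + tr$trans_z_mm^2)
  dplyr::bind_cols(glance(x$segmentation),
                   tibble::tibble(max_translation_mm = max(disp),
                                  max_rotation_deg = max(abs(
                                    c(tr$rot_x_deg, tr$rot_y_deg, tr$rot_z_deg)))))
}
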