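#' Load a run configuration from YAML
#'
#' Reads a structured configuration mirroring the per-stage settings
#' (simulation, detection, reconstruction, registration, evaluation) into an
#' [hmc_config()] plus simulation settings. Unknown keys and out-of-range
#' values are rejected with the offending key named.
#'
#' Recognised keys (all optional):
#' \preformatted{
#' seed: 1
#' simulation: {rate_cps, duration_s, phantom_shape, voxel_size_mm}
#' detection:  {alpha, min_mff_s}
#' recon:      {n_iterations, n_subsets}
#' registration: {n_histogram_bins, pyramid_levels, translation_bound_mm,
#'                coarse_step_mm, rotation_bound_deg, coarse_step_deg, maxit,
#'                mask_quantile}
#' evaluation: {suvr_threshold, classify_threshold_pct}
#' }
#'
#' @param path YAML file path.
#' @return A named list (`run_config`) with elements `seed`, `simulation`,
#'   `hmc` (an [hmc_config()]) and `evaluation`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such config file: %s", path), call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()

  allowed <- list(
    seed = NULL,
    simulation = c("rate_cps", "duration_s", "phantom_shape", "voxel_size_mm"),
    detection = c("alpha", "min_mff_s"),
    recon = c("n_iterations", "n_subsets"),
    registration = c("n_histogram_bins", "pyramid_levels",
                     "translation_bound_mm", "coarse_step_mm",
                     "rotation_bound_deg", "coarse_step_deg", "maxit",
                     "mask_quantile"),
    evaluation = c("suvr_threshold", "classify_threshold_pct"))
  bad <- setdiff(names(raw), names(allowed))
  if (length(bad))
    stop(sprintf("unknown config key: %s", bad[1]), call. = FALSE)
  for (sec in setdiff(names(raw), "seed")) {
    bad <- setdiff(names(raw[[sec]]), allowed[[sec]])
    if (length(bad))
      stop(sprintf("unknown config key: %s.%s", sec, bad[1]), call. = FALSE)
  }

  getd <- function(sec, key, default) raw[[sec]][[key]] %||% default
  check_range <- function(value, lo, hi, key, open = TRUE) {
    bad <- if (open) (value <= lo || value >= hi) else (value < lo || value > hi)
    if (bad) stop(sprintf("config value out of range: %s", key), call. = FALSE)
    value
  }
  alpha <- check_range(getd("detection", "alpha", 0.01), 0, 1, "detection.alpha")
  min_mff <- getd("detection", "min_mff_s", 5)
  if (min_mff <= 0) stop("config value out of range: detection.min_mff_s", call. = FALSE)
  rate <- getd("simulation", "rate_cps", 5000)
  if (rate <= 0) stop("config value out of range: simulation.rate_cps", call. = FALSE)
  dur <- getd("simulation", "duration_s", 180)
  if (dur <= 0) stop("config value out of range: simulation.duration_s", call. = FALSE)

  rc <- recon_config(getd("recon", "n_iterations", 3L),
                     getd("recon", "n_subsets", 10L))
  rg <- registration_config(
    n_histogram_bins = getd("registration", "n_histogram_bins", 32L),
    pyramid_levels = getd("registration", "pyramid_levels", 2L),
    translation_bound_mm = getd("registration", "translation_bound_mm", 20),
    coarse_step_mm = getd("registration", "coarse_step_mm", 6),
    rotation_bound_deg = getd("registration", "rotation_bound_deg", 15),
    coarse_step_deg = getd("registration", "coarse_step_deg", 5),
    maxit = getd("registration", "maxit", 200L),
    mask_quantile = check_range(getd("registration", "mask_quantile", 0.5),
                                0, 1, "registration.mask_quantile", open = FALSE))

  list(seed = as.integer(raw$seed %||% 1L),
       simulation = list(rate_cps = rate, duration_s = dur,
                         phantom_shape = as.integer(
                           getd("simulation", "phantom_shape", c(64L, 64L, 32L))),
                         voxel_size_mm = getd("simulation", "voxel_size_mm", 3)),
       hmc = hmc_config(duration_s = dur, alpha = alpha, min_mff_s = min_mff,
                        recon = rc, registration = rg),
       evaluation = list(
         suvr_threshold = getd("evaluation", "suvr_threshold", 1.0),
         classify_threshold_pct = getd("evaluation", "classify_threshold_pct", 5)))
}
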