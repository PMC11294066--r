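#' ROI set for regional quantification
#'
#' Couples an integer label volume with a label-to-region name map and a
#' merge map from (possibly many) sub-regions onto the 11 composite
#' gray-matter regions. With the shipped phantom the sub-regions already are
#' the 11 composite regions, but the merge map is configurable so atlas
#' label volumes with finer parcellations (e.g. the 116-region automated
#' anatomical labeling atlas) can be dropped in.
#'
#' @param labels integer [image_volume()] (role `"labels"`).
#' @param name_map named integer vector or tibble (`label`, `region`) giving
#'   the sub-region name per label code; defaults to the phantom's table.
#' @param merged_map named character vector mapping sub-region name to one of
#'   [gm_region_names()]; defaults to identity on names that already are
#'   composite regions.
#' @param gm_mask optional binary [image_volume()]; when present, refined
#'   ROIs are the intersection of each sub-region with the mask.
#' @return An `roi_set`.
#' @export
roi_set <- function(labels, name_map = NULL, merged_map = NULL, gm_mask = NULL) {
  stopifnot(is_image_volume(labels))
  if (is.null(name_map)) name_map <- phantom_label_table()
  if (is.data.frame(name_map)) {
    nm <- name_map$region
    names(nm) <- as.character(name_map$label)
  } else {
    nm <- name_map
  }
  regions <- gm_region_names()
  if (is.null(merged_map)) {
    merged_map <- stats::setNames(ifelse(nm %in% regions, nm, NA_character_), nm)
  }
  structure(list(labels = labels, name_map = nm, merged_map = merged_map,
                 gm_mask = gm_mask),
            class = "roi_set")
}

# logical index of voxels belonging to a composite region (refined by the
# GM mask when present)
region_voxels <- function(roiset, region, refined = TRUE) {
  subnames <- names(roiset$merged_map)[roiset$merged_map %in% region]
  codes <- as.integer(names(roiset$name_map)[roiset$name_map %in% subnames])
  sel <- array(as.integer(roiset$labels) %in% codes, dim = dim(roiset$labels))
  if (refined && !is.null(roiset$gm_mask)) sel <- sel & (unclass(roiset$gm_mask) > 0)
  sel
}

#' Gray-matter mask from the cerebellum-referenced SUV-ratio image
#'
#' Divides the image by its mean over the cerebellum ROI and thresholds the
#' ratio (strictly greater than `threshold`, default 1.0) into a binary
#' gray-matter mask. Attach the mask to an [roi_set()] to obtain refined
#' ROIs (intersections of the mask with each labeled region).
#'
#' @param image a reconstructed [image_volume()] (typically the reference
#'   frame).
#' @param roiset an [roi_set()] containing a cerebellum region.
#' @param threshold SUV-ratio threshold (default 1.0).
#' @return A binary [image_volume()] (role `"mask"`).
#' @export
gm_mask_from_suvr <- function(image, roiset, threshold = 1.0) {
  sel <- region_voxels(roiset, "cerebellum", refined = FALSE)
  if (!any(sel)) stop("cerebellum region absent from ROI set", call. = FALSE)
  ref <- mean(image[sel])
  if (!is.finite(ref) || ref <= 0)
    stop("cerebellum mean uptake must be positive", call. = FALSE)
  mask <- array(as.numeric(unclass(image) / ref > threshold), dim = dim(image))
  vol_like(mask, image, role = "mask")
}

#' Regional SUV means
#'
#' Mean image value over each composite region's (refined) voxels. When dose
#' and weight are given the values are scaled to standardized uptake values
#' (`concentration * weight_kg / dose_MBq`); percent changes are invariant
#' to this scaling, so it is optional.
#'
#' @param image an [image_volume()] on the label grid.
#' @param roiset an [roi_set()].
#' @param scaling optional list/vector with `dose_MBq` and `weight_kg`.
#' @return A tibble `region`, `suv_mean`, `n_voxels`; empty refined regions
#'   yield `NA` with a warning.
#' @export
roi_suv_mean <- function(image, roiset, scaling = NULL) {
  if (!isTRUE(all.equal(dim(image), dim(roiset$labels))))
    stop("image and label grids differ", call. = FALSE)
  sc <- 1
  if (!is.null(scaling)) {
    scaling <- as.list(scaling)
    sc <- scaling$weight_kg / scaling$dose_MBq
  }
  rows <- lapply(gm_region_names(), function(rg) {
    sel <- region_voxels(roiset, rg)
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("refined ROI '%s' is empty", rg))
      return(tibble::tibble(region = rg, suv_mean = NA_real_, n_voxels = 0L))
    }
    tibble::tibble(region = rg, suv_mean = mean(image[sel]) * sc, n_voxels = n)
  })
  dplyr::bind_rows(rows)
}

#' Regional percent change between two SUV reports
#'
#' `100 * (test - ref) / ref` per composite region, with the across-region
#' mean and SD attached (the summary rows of regional error tables).
#'
#' @param test_report,ref_report tibbles from [roi_suv_mean()] over the same
#'   region set.
#' @param suffixes column suffixes for the joined means.
#' @return A tibble `region`, `suv_mean_ref`, `suv_mean_test`,
#'   `percent_change`, with attributes `mean_pct` and `sd_pct`.
#' @export
percent_change <- function(test_report, ref_report, suffixes = c("_test", "_ref")) {
  stopifnot(setequal(test_report$region, ref_report$region))
  j <- dplyr::inner_join(
    dplyr::select(ref_report, "region", suv_mean_ref = "suv_mean"),
    dplyr::select(test_report, "region", suv_mean_test = "suv_mean"),
    by = "region")
  j <- dplyr::mutate(j, percent_change = ifelse(
    .data$suv_mean_ref > 0,
    100 * (.data$suv_mean_test - .data$suv_mean_ref) / .data$suv_mean_ref,
    NA_real_))
  structure(j,
            mean_pct = mean(j$percent_change, na.rm = TRUE),
            sd_pct = stats::sd(j$percent_change, na.rm = TRUE))
}

#' Classify a study's head motion as small or large
#'
#' Applies the frontal-lobe rule: the motion is *large* when the absolute
#' percent change of the frontal-lobe SUV mean between the corrected and
#' uncorrected images is at least `threshold_pct` (default 5; the boundary
#' counts as large).
#'
#' @param hmc_report,nmc_report tibbles from [roi_suv_mean()] on the
#'   corrected and uncorrected images.
#' @param threshold_pct classification threshold in percent.
#' @return `"small"` or `"large"`, with attribute `frontal_change_pct`.
#' @export
classify_motion <- function(hmc_report, nmc_report, threshold_pct = 5) {
  pc <- percent_change(hmc_report, nmc_report)
  fr <- pc$percent_change[pc$region == "frontal"]
  if (length(fr) != 1L || is.na(fr))
    stop("frontal region missing from report(s)", call. = FALSE)
  cls <- if (abs(fr) >= threshold_pct) "large" else "small"
  structure(cls, frontal_change_pct = fr)
}

#' Per-region head-motion distance summaries
#'
#' For each motion-free frame `i` and composite region, the motion distance
#' is the mean over the region's (refined) voxel centres `v` of
#' `|T(i)(v) - v|`. Summaries: the per-minute value is the duration-weighted
#' mean over the MFF portions inside each minute (frames are split at minute
#' boundaries), the region mean is the duration-weighted mean over the whole
#' scan, and the region max is the maximum over frames. Composite-region
#' values are the average over their constituent sub-regions.
#'
#' @param transforms list of per-MFF [rigid_transform()]s (first identity).
#' @param segmentation a [segment_mffs()] result with one MFF per transform.
#' @param roiset an [roi_set()].
#' @return A list of tibbles: `by_region` (`region`, `mean_mm`, `max_mm`) and
#'   `per_minute` (`region`, `minute`, `mean_mm`).
#' @export
hm_distance <- function(transforms, segmentation, roiset) {
  if (length(transforms) == 0L) stop("no transforms given", call. = FALSE)
  mffs <- segmentation$mffs
  if (nrow(mffs) != length(transforms))
    stop("number of transforms must match number of MFFs", call. = FALSE)
  regions <- gm_region_names()
  labels <- roiset$labels
  ctrs <- voxel_centers(labels)

  # sub-region -> composite map at voxel level
  sub_by_region <- lapply(regions, function(rg) {
    subnames <- names(roiset$merged_map)[roiset$merged_map %in% rg]
    lapply(subnames, function(sn) {
      codes <- as.integer(names(roiset$name_map)[roiset$name_map == sn])
      sel <- as.integer(labels) %in% codes
      if (!is.null(roiset$gm_mask)) sel <- sel & (as.numeric(roiset$gm_mask) > 0)
      which(sel)
    })
  })

  # d[frame, region]: composite = mean over sub-regions of mean voxel motion
  n_f <- length(transforms)
  d <- matrix(0, n_f, length(regions))
  for (i in seq_len(n_f)) {
    T <- transforms[[i]]
    if (is_identity_transform(T)) next
    for (r in seq_along(regions)) {
      subs <- sub_by_region[[r]]
      vals <- vapply(subs, function(ix) {
        if (!length(ix)) return(NA_real_)
        p <- ctrs[ix, , drop = FALSE]
        mean(sqrt(rowSums((map_points(T, p) - p)^2)))
      }, 0)
      d[i, r] <- mean(vals, na.rm = TRUE)
    }
  }

  dur <- mffs$t_end_s - mffs$t_start_s
  by_region <- tibble::tibble(
    region = regions,
    mean_mm = as.numeric(crossprod(d, dur) / sum(dur)),
    max_mm = apply(d, 2, max))

  minutes <- seq_len(ceiling(segmentation$duration_s / 60))
  per_minute <- dplyr::bind_rows(lapply(minutes, function(m) {
    lo <- (m - 1) * 60; hi <- m * 60
    wt <- pmax(0, pmin(mffs$t_end_s, hi) - pmax(mffs$t_start_s, lo))
    if (sum(wt) == 0)
      return(tibble::tibble(region = regions, minute = m, mean_mm = NA_real_))
    tibble::tibble(region = regions, minute = m,
                   mean_mm = as.numeric(crossprod(d, wt) / sum(wt)))
  }))
  list(by_region = by_region, per_minute = per_minute)
}

#' Build and write a regional evaluation report
#'
#' Joins reference/test SUV means, percent changes and motion-distance
#' summaries into one per-region table mirroring the structure of regional
#' SUV-error tables, and writes it as CSV and/or JSON.
#'
#' @param test_report,ref_report tibbles from [roi_suv_mean()].
#' @param distances optional result of [hm_distance()].
#' @return A `region_report` tibble.
#' @export
region_report <- function(test_report, ref_report, distances = NULL) {
  out <- percent_change(test_report, ref_report)
  if (!is.null(distances)) {
    out <- dplyr::left_join(out, dplyr::rename(distances$by_region,
                                               mean_hm_distance_mm = "mean_mm",
                                               max_hm_distance_mm = "max_mm"),
                            by = "region")
  }
  class(out) <- c("region_report", class(out))
  out
}

#' @rdname region_report
#' @param report a `region_report`.
#' @param path output file path (`.csv` or `.json` chosen by extension).
#' @export
write_region_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(as.data.frame(report), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname region_report
#' @export
read_region_report <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such report file: %s", path), call. = FALSE)
  df <- if (grepl("\\.json$", path))
    jsonlite::read_json(path, simplifyVector = TRUE) else utils::read.csv(path)
  out <- tibble::as_tibble(df)
  class(out) <- c("region_report", class(out))
  out
}

#' @method glance region_report
#' @export
glance.region_report <- function(x, ...) {
  tibble::tibble(mean_pct = mean(x$percent_change, na.rm = TRUE),
                 sd_pct = stats::sd(x$percent_change, na.rm = TRUE),
                 mean_abs_pct = mean(abs(x$percent_change), na.rm = TRUE))
}
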