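#' Classification parameters
#'
#' The classification rule needs a coverage threshold `T` shared by both
#' myosin channels and a minimum ROI area. Neither cut-off is a published
#' constant; both are mandatory configuration echoed into output
#' provenance. Defaults: T = 0.3, minimum area = area of a 15 um circle.
#'
#' @param coverage_threshold minimum channel coverage fraction to call a
#'   class.
#' @param min_area_um2 ROIs below this area are classified as noise.
#' @param slow_threshold,fast_threshold optional per-channel overrides of
#'   `coverage_threshold`.
#' @return list of parameters.
#' @export
classification_params <- function(coverage_threshold = 0.3,
                                  min_area_um2 = pi * (15 / 2)^2,
                                  slow_threshold = NULL,
                                  fast_threshold = NULL) {
  list(coverage_threshold = coverage_threshold,
       min_area_um2 = min_area_um2,
       slow_threshold = if (is.null(slow_threshold)) coverage_threshold else slow_threshold,
       fast_threshold = if (is.null(fast_threshold)) coverage_threshold else fast_threshold)
}

#' Coverage of an ROI in the binarised myosin channels
#'
#' @param roi an ROI from [labels_to_rois()].
#' @param slow_mask,fast_mask [binarise_channel()] masks sharing the
#'   ROI's image dimensions.
#' @return numeric vector `c(slow_coverage, fast_coverage)`, each the
#'   fraction of ROI pixels that are mask foreground.
#' @export
measure_coverage <- function(roi, slow_mask, fast_mask) {
  if (length(roi$pixels) == 0L) stop("empty ROI")
  sm <- if (inherits(slow_mask, "binary_mask")) slow_mask$mask else slow_mask
  fm <- if (inherits(fast_mask, "binary_mask")) fast_mask$mask else fast_mask
  if (!all(dim(sm) == roi$dim) || !all(dim(fm) == roi$dim)) {
    stop("mask dimensions must match the ROI's image dimensions")
  }
  c(slow_coverage = mean(sm[roi$pixels]),
    fast_coverage = mean(fm[roi$pixels]))
}

#' Classify one ROI as slow, fast, hybrid or noise
#'
#' The rule: ROIs below the minimum area are noise (other structures);
#' otherwise an ROI covered at or above threshold in both myosin channels
#' is a hybrid fibre, in exactly one channel that pure type, and in
#' neither an unstained object (noise).
#'
#' @param area_um2 ROI area in square micrometres.
#' @param slow_coverage,fast_coverage coverage fractions (0-1).
#' @param params a [classification_params()].
#' @return one of `"slow"`, `"fast"`, `"hybrid"`, `"noise"` (vectorised).
#' @export
classify_roi <- function(area_um2, slow_coverage, fast_coverage,
                         params = classification_params()) {
  s <- slow_coverage >= params$slow_threshold
  f <- fast_coverage >= params$fast_threshold
  out <- ifelse(s & f, "hybrid", ifelse(s, "slow", ifelse(f, "fast", "noise")))
  out[area_um2 < params$min_area_um2] <- "noise"
  out
}

#' Classify all interior ROIs of one image
#'
#' @param rois interior ROIs ([filter_border_rois()]).
#' @param slow_mask,fast_mask binarised myosin channels.
#' @param params a [classification_params()].
#' @param compute_mfd also fill each record's minimum Feret diameter.
#' @return list with `records` (data frame: roi_id, area_um2, slow_cov,
#'   fast_cov, class, mfd_um) and `counts` (named vector n_slow, n_fast,
#'   n_hybrid, n_noise).
#' @export
classify_image <- function(rois, slow_mask, fast_mask,
                           params = classification_params(),
                           compute_mfd = TRUE) {
  if (length(rois) == 0L) {
    records <- data.frame(roi_id = integer(0), area_um2 = numeric(0),
                          slow_cov = numeric(0), fast_cov = numeric(0),
                          class = character(0), mfd_um = numeric(0))
    return(list(records = records,
                counts = c(n_slow = 0L, n_fast = 0L, n_hybrid = 0L, n_noise = 0L)))
  }
  cov <- t(vapply(rois, measure_coverage, numeric(2),
                  slow_mask = slow_mask, fast_mask = fast_mask))
  records <- data.frame(
    roi_id = vapply(rois, `[[`, integer(1), "id"),
    area_um2 = vapply(rois, `[[`, numeric(1), "area_um2"),
    slow_cov = cov[, 1], fast_cov = cov[, 2]
  )
  records$class <- classify_roi(records$area_um2, records$slow_cov,
                                records$fast_cov, params)
  records$mfd_um <- if (compute_mfd) {
    vapply(rois, function(r) min_feret_diameter(r), numeric(1))
  } else {
    NA_real_
  }
  counts <- c(n_slow = sum(records$class == "slow"),
              n_fast = sum(records$class == "fast"),
              n_hybrid = sum(records$class == "hybrid"),
              n_noise = sum(records$class == "noise"))
  list(records = records, counts = counts)
}

#' Compare automated classes with manual annotation
#'
#' @param auto data frame of automated records with `roi_id` and `class`
#'   (optionally `image_id` for multi-image summaries).
#' @param manual data frame with `roi_id` and `class` (and matching
#'   `image_id` when present in `auto`).
#' @return list with `per_image` (image_id, n_shared, pct_correct) and
#'   the cross-image `mean`, `median` and `iqr` of the per-image percent
#'   correct. Images with zero shared ids get `NA` and a warning.
#' @export
compare_to_annotation <- function(auto, manual) {
  has_img <- "image_id" %in% names(auto) && "image_id" %in% names(manual)
  if (!has_img) {
    auto$image_id <- "image"
    manual$image_id <- "image"
  }
  per_image <- lapply(split(auto, auto$image_id), function(a) {
    m <- manual[manual$image_id == a$image_id[1], ]
    shared <- intersect(a$roi_id, m$roi_id)
    if (length(shared) == 0L) {
      warning(sprintf("no shared roi_ids for image '%s'", a$image_id[1]))
      return(data.frame(image_id = a$image_id[1], n_shared = 0L,
                        pct_correct = NA_real_))
    }
    ac <- a$class[match(shared, a$roi_id)]
    mc <- m$class[match(shared, m$roi_id)]
    data.frame(image_id = a$image_id[1], n_shared = length(shared),
               pct_correct = 100 * mean(ac == mc))
  })
  per_image <- do.call(rbind, per_image)
  pc <- per_image$pct_correct
  list(per_image = per_image,
       mean = mean(pc, na.rm = TRUE),
       median = median(pc, na.rm = TRUE),
       iqr = unname(diff(quantile(pc, c(0.25, 0.75), na.rm = TRUE))))
}
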