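#' Minimum Feret diameter
#'
#' Smallest caliper width of a shape over all directions: the minimum
#' over all orientations of the width of the convex hull (Feret widths of
#' a point set equal those of its hull). Computed by rotating calipers
#' over hull edges -- the minimum width is attained with one caliper jaw
#' flush against a hull edge, so it suffices to take, for each hull edge,
#' the largest vertex distance to the edge's supporting line, and then the
#' minimum over edges.
#'
#' @param x an ROI from [labels_to_rois()] (the hull is taken over the
#'   pixel corner points, so a single pixel has MFD = one pixel size), or
#'   a 2-column coordinate matrix.
#' @param pixel_size micrometres per pixel; taken from the ROI when
#'   omitted. Coordinate matrices are assumed already in physical units
#'   (`pixel_size` then defaults to 1).
#' @return MFD in micrometres. Degenerate (collinear) shapes return 0
#'   with a warning.
#' @export
min_feret_diameter <- function(x, pixel_size = NULL) {
  pts <- feret_points(x)
  scale <- feret_scale(x, pixel_size)
  min_width_hull(pts) * scale
}

#' Maximum Feret diameter
#'
#' Largest caliper width: the maximum pairwise distance between convex
#' hull points.
#'
#' @inheritParams min_feret_diameter
#' @return maximum Feret diameter in micrometres.
#' @export
max_feret_diameter <- function(x, pixel_size = NULL) {
  pts <- feret_points(x)
  scale <- feret_scale(x, pixel_size)
  h <- pts[chull(pts), , drop = FALSE]
  max(stats::dist(h)) * scale
}

feret_points <- function(x) {
  if (is.list(x) && !is.null(x$pixels)) {
    rows <- (x$pixels - 1L) %% x$dim[1] + 1L
    cols <- (x$pixels - 1L) %/% x$dim[1] + 1L
    # the four corners of every pixel, in pixel units
    cbind(c(cols - 1, cols, cols - 1, cols),
          c(rows - 1, rows - 1, rows, rows))
  } else {
    as.matrix(x)
  }
}

feret_scale <- function(x, pixel_size) {
  if (!is.null(pixel_size)) return(pixel_size)
  if (is.list(x) && !is.null(x$pixel_size)) x$pixel_size else 1
}

# Minimum directional width of the convex hull of a point set (unitless).
min_width_hull <- function(pts) {
  if (nrow(pts) < 3) {
    warning("degenerate ROI; width 0")
    return(0)
  }
  h <- pts[chull(pts), , drop = FALSE]
  n <- nrow(h)
  if (n < 3) {
    warning("degenerate (collinear) ROI; width 0")
    return(0)
  }
  widths <- vapply(seq_len(n), function(i) {
    a <- h[i, ]
    b <- h[if (i == n) 1L else i + 1L, ]
    e <- b - a
    len <- sqrt(sum(e^2))
    if (len == 0) return(Inf)
    # distance of every hull vertex to the line through edge (a, b)
    max(abs((h[, 1] - a[1]) * e[2] - (h[, 2] - a[2]) * e[1]) / len)
  }, numeric(1))
  min(widths)
}

#' Fibre type ratio
#'
#' Number of slow fibres divided by the number of fast fibres. When no
#' fast fibre is present the ratio is undefined and `NA` is returned
#' (undefined is a value, not an error).
#'
#' @param n_slow,n_fast non-negative counts.
#' @return the ratio, or `NA` when `n_fast` is 0.
#' @export
fibre_type_ratio <- function(n_slow, n_fast) {
  if (n_slow < 0 || n_fast < 0) stop("counts must be >= 0")
  if (n_fast == 0) return(NA_real_)
  n_slow / n_fast
}

#' Collagen area fraction
#'
#' Percentage of analysed pixels that are collagen foreground, a measure
#' of the intramuscular collagen amount.
#'
#' @param collagen_mask a [binarise_channel()] mask or logical matrix.
#' @param analysis_region optional logical matrix restricting the
#'   analysed pixels (whole image when omitted).
#' @return percentage in \[0, 100\]; `NA` with a warning for an empty
#'   analysis region.
#' @export
collagen_area_fraction <- function(collagen_mask, analysis_region = NULL) {
  m <- if (inherits(collagen_mask, "binary_mask")) collagen_mask$mask else collagen_mask
  if (is.null(analysis_region)) {
    return(100 * mean(m))
  }
  if (!all(dim(analysis_region) == dim(m))) stop("mask dimensions must match")
  n <- sum(analysis_region)
  if (n == 0) {
    warning("empty analysis region; collagen fraction undefined")
    return(NA_real_)
  }
  100 * sum(m & analysis_region) / n
}

#' Nerve morphometrics from inner and outer boundaries
#'
#' Axon diameter (AD) and overall diameter (OD) are reported as
#' equivalent-circle diameters of the inner (axoplasm) and outer (filled
#' fibre) regions; myelin thickness is MT = (OD - AD) / 2.
#'
#' @param inner,outer logical pixel masks; `inner` must be contained in
#'   `outer`.
#' @param pixel_size micrometres per pixel.
#' @return list with `ad_um`, `mt_um`, `od_um`.
#' @export
nerve_metrics <- function(inner, outer, pixel_size) {
  if (!all(dim(inner) == dim(outer))) stop("mask dimensions must match")
  if (!all(outer[inner])) stop("inner boundary not contained in outer boundary")
  ad <- 2 * sqrt(sum(inner) / pi) * pixel_size
  od <- 2 * sqrt(sum(outer) / pi) * pixel_size
  list(ad_um = ad, mt_um = (od - ad) / 2, od_um = od)
}

#' Per-image summary metrics
#'
#' Aggregates one image's classified fibre records into the quantities
#' the statistical layer consumes: fibre type ratio (slow / fast, pure
#' classes only -- hybrids are excluded from both counts), hybrid
#' percentage among fibres, collagen area percentage, class counts, and
#' minimum-Feret-diameter distributions by class.
#'
#' @param records fibre record data frame from [classify_image()].
#' @param collagen_mask binarised collagen channel (or logical matrix);
#'   `NULL` leaves `collagen_pct` as `NA`.
#' @return object of class `image_metrics`: list with `ftr`,
#'   `ftr_undefined`, `hybrid_pct`, `collagen_pct`, counts and
#'   `mfd_by_class`.
#' @export
image_metrics <- function(records, collagen_mask = NULL) {
  n_slow <- sum(records$class == "slow")
  n_fast <- sum(records$class == "fast")
  n_hybrid <- sum(records$class == "hybrid")
  n_noise <- sum(records$class == "noise")
  n_fibre <- n_slow + n_fast + n_hybrid
  structure(list(
    ftr = fibre_type_ratio(n_slow, n_fast),
    ftr_undefined = n_fast == 0,
    hybrid_pct = if (n_fibre > 0) 100 * n_hybrid / n_fibre else NA_real_,
    collagen_pct = if (is.null(collagen_mask)) NA_real_ else
      collagen_area_fraction(collagen_mask),
    n_slow = n_slow, n_fast = n_fast, n_hybrid = n_hybrid, n_noise = n_noise,
    mfd_by_class = split(records$mfd_um, records$class)
  ), class = "image_metrics")
}

#' @export
print.image_metrics <- function(x, ...) {
  cat(sprintf(
    "<image_metrics> FTR = %s, hybrid = %s%%, collagen = %s%% (slow %d / fast %d / hybrid %d / noise %d)\n",
    format(x$ftr, digits = 3), format(x$hybrid_pct, digits = 3),
    format(x$collagen_pct, digits = 3),
    x$n_slow, x$n_fast, x$n_hybrid, x$n_noise))
  invisible(x)
}

#' @export
as.data.frame.image_metrics <- function(x, ...) {
  data.frame(ftr = x$ftr, ftr_undefined = x$ftr_undefined,
             hybrid_pct = x$hybrid_pct, collagen_pct = x$collagen_pct,
             n_slow = x$n_slow, n_fast = x$n_fast,
             n_hybrid = x$n_hybrid, n_noise = x$n_noise)
}
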