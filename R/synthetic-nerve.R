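#' Specification of a toy nerve cross-section
#'
#' A set of myelinated axons, each an inner disc (axon) surrounded by a
#' darker annulus (myelin). Per axon the ground truth stores the axon
#' diameter (AD), myelin thickness (MT) and overall diameter
#' OD = AD + 2 MT. Axons must not overlap.
#'
#' @param centres n x 2 matrix of axon centres in micrometres.
#' @param ad axon diameters in micrometres (> 0).
#' @param mt myelin thicknesses in micrometres (>= 0).
#' @return object of class `nerve_spec` with an `axons` data frame
#'   (cx_um, cy_um, ad_um, mt_um, od_um).
#' @export
nerve_spec <- function(centres, ad, mt) {
  centres <- matrix(centres, ncol = 2)
  if (any(ad <= 0)) stop("axon diameters must be > 0")
  if (any(mt < 0)) stop("myelin thickness must be >= 0")
  od <- ad + 2 * mt
  n <- nrow(centres)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        gap <- sqrt(sum((centres[i, ] - centres[j, ])^2)) - (od[i] + od[j]) / 2
        if (gap < 0) stop("axons overlap; rejected at construction")
      }
    }
  }
  structure(
    list(axons = data.frame(cx_um = centres[, 1], cy_um = centres[, 2],
                            ad_um = ad, mt_um = mt, od_um = od)),
    class = "nerve_spec"
  )
}

#' Draw a random non-overlapping nerve specification
#'
#' Axon diameters and myelin thicknesses are drawn uniformly from
#' physiologically plausible ranges for a large-mammal peripheral nerve
#' and placed by dart throwing so no two fibres overlap.
#'
#' @param n_axons number of axons.
#' @param width_um,height_um field size in micrometres.
#' @param ad_range,mt_range uniform sampling ranges (micrometres).
#' @param seed integer seed.
#' @return a [nerve_spec()].
#' @export
random_nerve_spec <- function(n_axons = 50, width_um = 200, height_um = 200,
                              ad_range = c(4, 10), mt_range = c(1, 2.5),
                              seed = 1L) {
  with_seed(seed, {
    ad <- runif(n_axons, ad_range[1], ad_range[2])
    mt <- runif(n_axons, mt_range[1], mt_range[2])
    od <- ad + 2 * mt
    centres <- matrix(NA_real_, 0, 2)
    placed_od <- numeric(0)
    tries <- 0L
    while (nrow(centres) < n_axons && tries < 20000L) {
      tries <- tries + 1L
      k <- nrow(centres) + 1L
      margin <- od[k] / 2 + 1
      cand <- c(runif(1, margin, width_um - margin),
                runif(1, margin, height_um - margin))
      ok <- nrow(centres) == 0 ||
        all(sqrt((centres[, 1] - cand[1])^2 + (centres[, 2] - cand[2])^2) >=
              (placed_od + od[k]) / 2 + 0.5)
      if (ok) {
        centres <- rbind(centres, cand)
        placed_od <- c(placed_od, od[k])
      }
    }
    n_ok <- nrow(centres)
    nerve_spec(centres, ad[seq_len(n_ok)], mt[seq_len(n_ok)])
  })
}

#' Render a toy nerve cross-section image
#'
#' Emulates a toluidine-blue-stained semithin section: light background,
#' dark myelin annuli, intermediate axoplasm discs. Mild blur and noise
#' are applied.
#'
#' @param spec a [nerve_spec()].
#' @param pixel_size micrometres per pixel.
#' @param width_um,height_um rendered field in micrometres (default from
#'   axon extent + margin).
#' @param background,myelin,axoplasm grey levels (0-255).
#' @param blur_sigma blur in pixels; `noise_sd` Gaussian noise sd.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed integer seed for the noise.
#' @return list with `image` (numeric matrix, 0-255) and `truth` (the
#'   per-axon AD/MT/OD table).
#' @export
generate_nerve_image <- function(spec, pixel_size = 0.1,
                                 width_um = NULL, height_um = NULL,
                                 background = 200, myelin = 40,
                                 axoplasm = 140, blur_sigma = 0.5,
                                 noise_sd = 4, seed = 1L) {
  stopifnot(inherits(spec, "nerve_spec"))
  ax <- spec$axons
  if (is.null(width_um)) width_um <- max(ax$cx_um + ax$od_um / 2) + 5
  if (is.null(height_um)) height_um <- max(ax$cy_um + ax$od_um / 2) + 5
  nx <- ceiling(width_um / pixel_size)
  ny <- ceiling(height_um / pixel_size)
  img <- matrix(background, ny, nx)
  px <- (seq_len(nx) - 0.5) * pixel_size
  py <- (seq_len(ny) - 0.5) * pixel_size
  for (i in seq_len(nrow(ax))) {
    # restrict the distance evaluation to the axon's bounding box
    rad <- ax$od_um[i] / 2
    cs <- which(px >= ax$cx_um[i] - rad - pixel_size &
                  px <= ax$cx_um[i] + rad + pixel_size)
    rs <- which(py >= ax$cy_um[i] - rad - pixel_size &
                  py <= ax$cy_um[i] + rad + pixel_size)
    r <- sqrt(outer((py[rs] - ax$cy_um[i])^2, (px[cs] - ax$cx_um[i])^2, "+"))
    patch <- img[rs, cs]
    patch[r <= rad] <- myelin
    patch[r <= ax$ad_um[i] / 2] <- axoplasm
    img[rs, cs] <- patch
  }
  if (blur_sigma > 0) img <- from_ebimage(EBImage::gblur(as_ebimage(img), blur_sigma))
  if (noise_sd > 0) img <- img + with_seed(seed, rnorm(length(img), 0, noise_sd))
  img <- matrix(round(pmin(pmax(img, 0), 255)), ny, nx)
  list(image = img, truth = ax, pixel_size = pixel_size)
}

#' Measure AD, MT and OD from a nerve image
#'
#' Segments the dark myelin annuli (pixels below `myelin_threshold`),
#' fills each annulus to recover the whole fibre disc, and reports
#' equivalent-circle diameters: AD from the inner (axoplasm) region, OD
#' from the filled disc, MT = (OD - AD) / 2. Annuli touching the image
#' border are discarded.
#'
#' @param img numeric matrix (0-255) from [generate_nerve_image()] or a
#'   comparable acquisition.
#' @param pixel_size micrometres per pixel.
#' @param myelin_threshold grey level separating myelin from axoplasm and
#'   background; default 90 matches the default rendering contrast.
#' @param min_area_um2 discard specks below this area.
#' @return data frame with ad_um, mt_um, od_um per detected fibre.
#' @export
measure_nerve_image <- function(img, pixel_size, myelin_threshold = 90,
                                min_area_um2 = 2) {
  ring <- img < myelin_threshold
  lab <- EBImage::bwlabel(EBImage::Image(t(ring)))
  n <- max(lab)
  out <- list()
  labm <- t(EBImage::imageData(lab))
  for (k in seq_len(n)) {
    ringk <- labm == k
    if (sum(ringk) * pixel_size^2 < min_area_um2) next
    idx <- which(ringk, arr.ind = TRUE)
    if (any(idx[, 1] %in% c(1, nrow(img))) || any(idx[, 2] %in% c(1, ncol(img)))) next
    filled <- t(EBImage::imageData(EBImage::fillHull(EBImage::Image(t(ringk)))) > 0)
    inner <- filled & !ringk
    od <- 2 * sqrt(sum(filled) / pi) * pixel_size
    ad <- 2 * sqrt(sum(inner) / pi) * pixel_size
    fidx <- which(filled, arr.ind = TRUE)
    out[[length(out) + 1]] <- data.frame(
      cx_um = mean(fidx[, 2] - 0.5) * pixel_size,
      cy_um = mean(fidx[, 1] - 0.5) * pixel_size,
      ad_um = ad, mt_um = (od - ad) / 2, od_um = od)
  }
  if (length(out) == 0) {
    return(data.frame(cx_um = numeric(0), cy_um = numeric(0),
                      ad_um = numeric(0), mt_um = numeric(0),
                      od_um = numeric(0)))
  }
  do.call(rbind, out)
}
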