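#' Generate a tessellated fibre geometry
#'
#' Builds a synthetic muscle cross-section geometry: Poisson-disc seed
#' points tessellate the image into convex, fibre-like cells (2 Lloyd
#' relaxation iterations for isotropy), and every cell is shrunk inward by
#' half the collagen band so an interstitial lattice of prescribed width
#' remains between neighbouring fibres.
#'
#' @param width_px,height_px image size in pixels (>= 64).
#' @param mean_fibre_diameter target mean fibre diameter in micrometres
#'   (>= 4 pixel sizes).
#' @param pixel_size micrometres per pixel.
#' @param collagen_band physical width of the interstitial collagen
#'   lattice in micrometres (< `mean_fibre_diameter / 2`).
#' @param seed integer RNG seed; the geometry is a pure function of its
#'   arguments.
#' @return A `fibre_map`: list with the integer `labels` matrix (0 =
#'   interstitial lattice, k >= 1 = fibre id), a `fibres` data frame
#'   (id, centroid, area in um^2, `true_class` to be filled by
#'   [assign_fibre_types()]), and the generation parameters.
#' @export
generate_fibre_geometry <- function(width_px, height_px, mean_fibre_diameter,
                                    pixel_size = 0.5, collagen_band = 4,
                                    seed = 1L) {
  if (width_px < 64 || height_px < 64) stop("image must be at least 64 x 64 px")
  if (mean_fibre_diameter < 4 * pixel_size) {
    stop("mean_fibre_diameter must be at least 4 pixel sizes")
  }
  if (collagen_band >= mean_fibre_diameter / 2) {
    stop("collagen_band must be below mean_fibre_diameter / 2")
  }
  d_px <- mean_fibre_diameter / pixel_size
  n_target <- max(4L, round(width_px * height_px / (pi / 4 * d_px^2)))
  seeds <- with_seed(seed, poisson_disc(width_px, height_px,
                                        r_min = 0.65 * d_px, n = n_target))

  # Lloyd relaxation: move each seed to the centroid of its Voronoi cell.
  px_x <- rep(seq_len(width_px) - 0.5, each = height_px)
  px_y <- rep(seq_len(height_px) - 0.5, times = width_px)
  for (i in 1:2) {
    v <- voronoi_assign(height_px, width_px, seeds[, 1], seeds[, 2])
    lab <- as.vector(v$label)
    cx <- rowsum(px_x, lab) / tabulate(lab, nrow(seeds))
    cy <- rowsum(px_y, lab) / tabulate(lab, nrow(seeds))
    keep <- is.finite(cx) & is.finite(cy)
    seeds <- cbind(cx[keep], cy[keep])
  }

  v <- voronoi_assign(height_px, width_px, seeds[, 1], seeds[, 2])
  labels <- v$label
  band_px <- collagen_band / pixel_size
  # d2 - d1 is twice the distance to the Voronoi boundary: thresholding it
  # carves a lattice of total width `collagen_band` between cells.
  labels[v$d2 - v$d1 < band_px] <- 0L

  counts <- tabulate(labels[labels > 0], nbins = nrow(seeds))
  if (any(counts == 0)) {
    warning(sprintf("%d fibre(s) degenerate after collagen shrink; dropped",
                    sum(counts == 0)))
  }
  ids <- which(counts > 0)
  lab_vec <- as.vector(labels)
  inside <- lab_vec > 0
  cx <- rowsum(px_x[inside], lab_vec[inside])[, 1] / counts[ids]
  cy <- rowsum(px_y[inside], lab_vec[inside])[, 1] / counts[ids]
  fibres <- data.frame(
    id = ids,
    cx_um = cx * pixel_size,
    cy_um = cy * pixel_size,
    area_um2 = counts[ids] * pixel_size^2,
    true_class = NA_character_
  )
  structure(
    list(labels = labels, fibres = fibres, pixel_size = pixel_size,
         collagen_band = collagen_band, width_px = width_px,
         height_px = height_px, seed = seed),
    class = "fibre_map"
  )
}

#' @export
print.fibre_map <- function(x, ...) {
  cat(sprintf("<fibre_map> %d x %d px, %d fibres, collagen lattice %.1f%% of area\n",
              x$width_px, x$height_px, nrow(x$fibres),
              100 * mean(x$labels == 0)))
  invisible(x)
}

# Dart-throwing Poisson-disc sampling: n points with pairwise distance
# >= r_min, uniform over the (w x h) pixel domain. Caller controls RNG.
poisson_disc <- function(w, h, r_min, n, max_attempts = 200L * n) {
  pts <- matrix(numeric(0), ncol = 2)
  attempts <- 0L
  r2 <- r_min^2
  while (nrow(pts) < n && attempts < max_attempts) {
    cand <- c(runif(1, 0, w), runif(1, 0, h))
    attempts <- attempts + 1L
    if (nrow(pts) == 0 ||
        min((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2) >= r2) {
      pts <- rbind(pts, cand)
    }
  }
  unname(pts)
}

#' Assign slow / fast / hybrid types to fibres
#'
#' Each fibre is independently labelled hybrid with probability
#' `hybrid_fraction`, otherwise slow with conditional probability
#' `slow_fraction / (1 - hybrid_fraction)`, so `slow_fraction` is the
#' marginal slow proportion. The realised fibre type ratio (FTR,
#' n_slow / n_fast over pure classes) is recorded as ground truth; it is
#' flagged undefined when no fast fibre was realised.
#'
#' @param map a `fibre_map` from [generate_fibre_geometry()].
#' @param slow_fraction,hybrid_fraction marginal class proportions,
#'   `slow_fraction + hybrid_fraction <= 1`.
#' @param seed integer RNG seed.
#' @return The `fibre_map` with `fibres$true_class` filled and attributes
#'   `true_ftr` (NA when undefined) and `true_hybrid_pct`.
#' @export
assign_fibre_types <- function(map, slow_fraction, hybrid_fraction = 0,
                               seed = 1L) {
  stopifnot(inherits(map, "fibre_map"))
  if (slow_fraction < 0 || hybrid_fraction < 0 ||
      slow_fraction + hybrid_fraction > 1) {
    stop("require slow_fraction, hybrid_fraction >= 0 and their sum <= 1")
  }
  n <- nrow(map$fibres)
  cls <- with_seed(seed, {
    u <- runif(n)
    hyb <- u < hybrid_fraction
    p_slow <- if (hybrid_fraction < 1) slow_fraction / (1 - hybrid_fraction) else 0
    slow <- !hyb & (runif(n) < p_slow)
    ifelse(hyb, "hybrid", ifelse(slow, "slow", "fast"))
  })
  map$fibres$true_class <- cls
  n_slow <- sum(cls == "slow")
  n_fast <- sum(cls == "fast")
  attr(map, "true_ftr") <- if (n_fast > 0) n_slow / n_fast else NA_real_
  attr(map, "ftr_undefined") <- n_fast == 0
  attr(map, "true_hybrid_pct") <- if (n > 0) 100 * sum(cls == "hybrid") / n else NA_real_
  map
}

#' Default intensity model for channel rendering
#'
#' Per-class channel means on the 8-bit scale, plus acquisition blur and
#' noise. Hybrid fibres express both myosin channels at
#' `hybrid_factor` of the pure-class mean.
#'
#' @param slow_mean,fast_mean,collagen_mean foreground class means (0-255).
#' @param hybrid_factor fraction of the pure-class mean expressed by
#'   hybrid fibres in each myosin channel.
#' @param background background mean (0-255).
#' @param noise_sd Gaussian noise standard deviation (8-bit units).
#' @param blur_sigma Gaussian blur sigma in pixels (0 = none).
#' @return list of intensity parameters.
#' @export
intensity_model <- function(slow_mean = 180, fast_mean = 180,
                            collagen_mean = 160, hybrid_factor = 0.6,
                            background = 10, noise_sd = 8, blur_sigma = 1) {
  list(slow_mean = slow_mean, fast_mean = fast_mean,
       collagen_mean = collagen_mean, hybrid_factor = hybrid_factor,
       background = background, noise_sd = noise_sd, blur_sigma = blur_sigma)
}

#' Render the three fluorescence channels of a typed fibre map
#'
#' The red (slow) channel is bright inside slow and hybrid fibres, the
#' green (fast) channel inside fast and hybrid fibres, and the orange
#' (collagen) channel on the interstitial lattice. Gaussian blur is
#' applied first, then Gaussian noise; values are clipped to \[0, 255\]
#' and rounded.
#'
#' @param map a typed `fibre_map` ([assign_fibre_types()]).
#' @param intensity an [intensity_model()].
#' @param seed integer RNG seed for the noise.
#' @return list with `image` (a [multichannel_image()]) and `truth`
#'   (labels matrix, logical collagen mask, fibre table with true classes,
#'   `true_ftr`, `true_hybrid_pct`, `true_collagen_pct`).
#' @export
render_channels <- function(map, intensity = intensity_model(), seed = 1L) {
  stopifnot(inherits(map, "fibre_map"))
  if (anyNA(map$fibres$true_class)) {
    stop("fibre types not assigned; call assign_fibre_types() first")
  }
  means <- c(intensity$slow_mean, intensity$fast_mean, intensity$collagen_mean,
             intensity$hybrid_factor * intensity$slow_mean,
             intensity$hybrid_factor * intensity$fast_mean)
  if (min(means) - intensity$background <= intensity$noise_sd) {
    stop("unresolvable contrast: class-vs-background contrast must exceed noise sd")
  }
  lab <- map$labels
  bg <- intensity$background
  cls_of <- rep(NA_character_, max(lab))
  cls_of[map$fibres$id] <- map$fibres$true_class

  slow_ch <- matrix(bg, nrow(lab), ncol(lab))
  fast_ch <- matrix(bg, nrow(lab), ncol(lab))
  col_ch <- matrix(bg, nrow(lab), ncol(lab))
  inside <- lab > 0
  pix_cls <- cls_of[lab[inside]]
  slow_ch[inside][pix_cls == "slow"] <- intensity$slow_mean
  slow_ch[inside][pix_cls == "hybrid"] <- intensity$hybrid_factor * intensity$slow_mean
  fast_ch[inside][pix_cls == "fast"] <- intensity$fast_mean
  fast_ch[inside][pix_cls == "hybrid"] <- intensity$hybrid_factor * intensity$fast_mean
  col_ch[!inside] <- intensity$collagen_mean

  degrade <- function(ch, sub_seed) {
    if (intensity$blur_sigma > 0) {
      ch <- from_ebimage(EBImage::gblur(as_ebimage(ch),
                                        sigma = intensity$blur_sigma))
    }
    if (intensity$noise_sd > 0) {
      ch <- ch + with_seed(sub_seed, rnorm(length(ch), 0, intensity$noise_sd))
    }
    matrix(round(pmin(pmax(ch, 0), 255)), nrow(ch), ncol(ch))
  }
  sub <- derive_seeds(seed, 3)
  img <- multichannel_image(
    degrade(slow_ch, sub[1]), degrade(fast_ch, sub[2]), degrade(col_ch, sub[3]),
    pixel_size = map$pixel_size, bit_depth = 8L,
    provenance = list(simulator_seed = seed)
  )
  truth <- list(
    labels = lab,
    collagen_mask = !inside,
    fibres = map$fibres,
    true_ftr = attr(map, "true_ftr"),
    ftr_undefined = isTRUE(attr(map, "ftr_undefined")),
    true_hybrid_pct = attr(map, "true_hybrid_pct"),
    true_collagen_pct = 100 * mean(!inside)
  )
  list(image = img, truth = truth)
}

#' Simulate one typed, rendered muscle cross-section
#'
#' Convenience wrapper chaining [generate_fibre_geometry()],
#' [assign_fibre_types()] and [render_channels()] under one seed.
#'
#' @inheritParams generate_fibre_geometry
#' @inheritParams assign_fibre_types
#' @param intensity an [intensity_model()].
#' @param seed integer seed controlling geometry, typing and noise.
#' @return As [render_channels()], with the typed `map` attached.
#' @export
simulate_muscle_image <- function(width_px = 512, height_px = 512,
                                  mean_fibre_diameter = 50, pixel_size = 0.5,
                                  collagen_band = 4, slow_fraction = 0.3,
                                  hybrid_fraction = 0.05,
                                  intensity = intensity_model(), seed = 1L) {
  sub <- derive_seeds(seed, 3)
  map <- generate_fibre_geometry(width_px, height_px, mean_fibre_diameter,
                                 pixel_size, collagen_band, seed = sub[1])
  map <- assign_fibre_types(map, slow_fraction, hybrid_fraction, seed = sub[2])
  out <- render_channels(map, intensity, seed = sub[3])
  out$map <- map
  out
}

#' Assign spatially zonated fibre types
#'
#' Variant of [assign_fibre_types()] with a left/right composition split:
#' fibres whose centroid lies in the left half of the section use
#' `slow_fraction_left`, the rest `slow_fraction_right`. Used to build
#' deliberately non-representative sections for field-of-view validation.
#'
#' @inheritParams assign_fibre_types
#' @param slow_fraction_left,slow_fraction_right marginal slow
#'   proportions in the two halves.
#' @return the typed `fibre_map`, as [assign_fibre_types()].
#' @export
assign_fibre_types_zonated <- function(map, slow_fraction_left,
                                       slow_fraction_right,
                                       hybrid_fraction = 0, seed = 1L) {
  stopifnot(inherits(map, "fibre_map"))
  half <- map$width_px * map$pixel_size / 2
  left <- map$fibres$cx_um < half
  sub <- derive_seeds(seed, 2)
  ml <- mr <- map
  ml$fibres <- map$fibres[left, , drop = FALSE]
  mr$fibres <- map$fibres[!left, , drop = FALSE]
  ml <- assign_fibre_types(ml, slow_fraction_left, hybrid_fraction, sub[1])
  mr <- assign_fibre_types(mr, slow_fraction_right, hybrid_fraction, sub[2])
  map$fibres$true_class[left] <- ml$fibres$true_class
  map$fibres$true_class[!left] <- mr$fibres$true_class
  cls <- map$fibres$true_class
  n_slow <- sum(cls == "slow")
  n_fast <- sum(cls == "fast")
  attr(map, "true_ftr") <- if (n_fast > 0) n_slow / n_fast else NA_real_
  attr(map, "ftr_undefined") <- n_fast == 0
  attr(map, "true_hybrid_pct") <- 100 * mean(cls == "hybrid")
  map
}

#' Calibrate the collagen band width for a target area fraction
#'
#' The interstitial lattice area grows monotonically with the band width;
#' this helper bisects the band so the rendered ground-truth collagen
#' fraction matches a designed percentage for the given geometry settings.
#'
#' @inheritParams generate_fibre_geometry
#' @param target_pct designed collagen area percentage (0-100).
#' @param tol_pct bisection tolerance in percentage points.
#' @return band width in micrometres.
#' @export
calibrate_collagen_band <- function(target_pct, width_px = 512, height_px = 512,
                                    mean_fibre_diameter = 50, pixel_size = 0.5,
                                    seed = 1L, tol_pct = 0.2) {
  frac_at <- function(band) {
    m <- generate_fibre_geometry(width_px, height_px, mean_fibre_diameter,
                                 pixel_size, band, seed = seed)
    100 * mean(m$labels == 0)
  }
  lo <- 0
  hi <- mean_fibre_diameter / 2 - pixel_size
  for (i in 1:25) {
    mid <- (lo + hi) / 2
    f <- frac_at(mid)
    if (abs(f - target_pct) < tol_pct) return(mid)
    if (f < target_pct) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
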