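# Shared fixtures and independent oracles for the test suite.

# Small rendered cross-section used by several tests. Memoised per
# argument combination so repeated calls inside one test run are free.
local({
  cache <- new.env(parent = emptyenv())
  sim_fixture <<- function(seed = 42, width = 256, height = 256,
                           diameter = 40, pixel_size = 1, band = 4,
                           slow_fraction = 0.3, hybrid_fraction = 0.05,
                           intensity = intensity_model()) {
    key <- paste(seed, width, height, diameter, pixel_size, band,
                 slow_fraction, hybrid_fraction,
                 paste(unlist(intensity), collapse = ","), sep = "|")
    if (is.null(cache[[key]])) {
      cache[[key]] <- simulate_muscle_image(
        width, height, diameter, pixel_size, band,
        slow_fraction, hybrid_fraction, intensity, seed = seed)
    }
    cache[[key]]
  }
})

noiseless_intensity <- function() intensity_model(noise_sd = 0, blur_sigma = 0)

# A fibre map stub with n untyped fibres; enough for assign_fibre_types().
fake_fibre_map <- function(n) {
  structure(list(fibres = data.frame(id = seq_len(n),
                                     true_class = NA_character_)),
            class = "fibre_map")
}

# An ROI built from explicit (row, col) pixel coordinates.
fake_roi <- function(rows, cols, dim, pixel_size = 1, id = 1L) {
  px <- (cols - 1L) * dim[1] + rows
  list(id = id, pixels = as.integer(px),
       area_um2 = length(px) * pixel_size^2,
       touches_border = any(rows == 1L | rows == dim[1] |
                              cols == 1L | cols == dim[2]),
       dim = dim, pixel_size = pixel_size)
}

# Independent brute-force Otsu: minimise the within-class variance over
# all 8-bit thresholds (foreground strictly above t).
brute_otsu_objective <- function(channel, t) {
  lo <- channel[channel <= t]
  hi <- channel[channel > t]
  w <- length(lo) / length(channel)
  v_lo <- if (length(lo) > 1) stats::var(lo) * (length(lo) - 1) / length(lo) else 0
  v_hi <- if (length(hi) > 1) stats::var(hi) * (length(hi) - 1) / length(hi) else 0
  w * v_lo + (1 - w) * v_hi
}

brute_otsu <- function(channel) {
  obj <- vapply(0:254, function(t) brute_otsu_objective(channel, t), numeric(1))
  (0:254)[which.min(obj)]
}

# Independent step-up FDR adjustment, written from the definition.
stepup_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  for (i in (m - 1):1) {
    if (m > 1) q_sorted[i] <- min(q_sorted[i], q_sorted[i + 1])
  }
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Independent MFD oracle: minimum directional width over a dense 0.1
# degree angle grid, then golden-section refinement of the best basin
# (the width profile is V-shaped at a minimum). Works only with the
# directional-width function itself, never with hull edges.
directional_width <- function(pts, a) {
  proj <- pts[, 1] * cos(a) + pts[, 2] * sin(a)
  max(proj) - min(proj)
}

grid_min_width <- function(pts, n_angles = 1800, refine = TRUE) {
  thetas <- seq(0, pi, length.out = n_angles + 1)[-(n_angles + 1)]
  widths <- vapply(thetas, directional_width, numeric(1), pts = pts)
  if (!refine) return(min(widths))
  step <- pi / n_angles
  lo <- thetas[which.min(widths)] - step
  hi <- thetas[which.min(widths)] + step
  phi <- (sqrt(5) - 1) / 2
  for (i in 1:80) {
    m1 <- hi - phi * (hi - lo)
    m2 <- lo + phi * (hi - lo)
    if (directional_width(pts, m1) < directional_width(pts, m2)) hi <- m2
    else lo <- m1
  }
  min(widths, directional_width(pts, (lo + hi) / 2))
}

# Random convex polygon: convex hull of random points.
random_convex_polygon <- function(n = 12, scale = 10) {
  pts <- matrix(runif(2 * n, 0, scale), ncol = 2)
  pts[chull(pts), , drop = FALSE]
}

# Ground-truth class counts restricted to fibres not touching the image
# border (the population the pipeline measures).
interior_truth_counts <- function(truth) {
  labels <- truth$labels
  d <- dim(labels)
  border <- unique(c(labels[1, ], labels[d[1], ], labels[, 1], labels[, d[2]]))
  ids <- setdiff(truth$fibres$id, border)
  cls <- truth$fibres$true_class[match(ids, truth$fibres$id)]
  c(n_slow = sum(cls == "slow"), n_fast = sum(cls == "fast"),
    n_hybrid = sum(cls == "hybrid"))
}
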