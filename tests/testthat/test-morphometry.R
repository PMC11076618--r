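test_that("minimum Feret diameter of simple shapes", {
  rect <- cbind(c(0, 7, 7, 0), c(0, 0, 3, 3))
  expect_equal(min_feret_diameter(rect), 3)
  expect_equal(max_feret_diameter(rect), sqrt(7^2 + 3^2))

  # digitised disc: MFD within 2 pixel sizes of the true diameter
  r <- 20
  d <- c(51L, 51L)
  idx <- which(matrix(TRUE, d[1], d[2]), arr.ind = TRUE)
  inside <- (idx[, 1] - 26)^2 + (idx[, 2] - 26)^2 <= r^2
  roi <- fake_roi(idx[inside, 1], idx[inside, 2], d, pixel_size = 1)
  expect_lt(abs(min_feret_diameter(roi) - 2 * r), 2)

  # degenerate: collinear points have zero width
  expect_warning(w <- min_feret_diameter(cbind(0:5, 0:5)), "degenerate")
  expect_equal(w, 0)
})

test_that("rotating calipers equals the dense angle-grid oracle", {
  set.seed(31)
  for (i in 1:100) {
    poly <- random_convex_polygon(n = sample(5:20, 1))
    mfd <- min_feret_diameter(poly)
    oracle <- grid_min_width(poly, n_angles = 3600)
    expect_lt(abs(mfd - oracle) / oracle, 1e-6)
    expect_lte(mfd, max_feret_diameter(poly) + 1e-12)
  }
})

test_that("MFD is rotation invariant", {
  set.seed(37)
  poly <- random_convex_polygon(10)
  base <- min_feret_diameter(poly)
  rot90 <- poly %*% matrix(c(0, -1, 1, 0), 2)
  expect_equal(min_feret_diameter(rot90), base)
  for (a in c(0.3, 1.1, 2.5)) {
    rot <- poly %*% matrix(c(cos(a), -sin(a), sin(a), cos(a)), 2)
    expect_equal(min_feret_diameter(rot), base, tolerance = 1e-9)
  }
})

test_that("fibre type ratio handles zero counts as undefined", {
  expect_equal(fibre_type_ratio(10, 10), 1)
  expect_equal(fibre_type_ratio(0, 25), 0)
  expect_true(is.na(fibre_type_ratio(5, 0)))
  expect_error(fibre_type_ratio(-1, 2), ">= 0")

  set.seed(41)
  for (i in 1:20) {
    a <- sample(1:50, 1)
    b <- sample(1:50, 1)
    expect_equal(fibre_type_ratio(a, b) * fibre_type_ratio(b, a), 1)
  }
})

test_that("collagen area fraction counts foreground percentage", {
  expect_equal(collagen_area_fraction(matrix(TRUE, 4, 4)), 100)
  expect_equal(collagen_area_fraction(matrix(FALSE, 4, 4)), 0)

  m <- matrix(FALSE, 4, 4)
  m[1:2, ] <- TRUE
  region <- matrix(FALSE, 4, 4)
  region[1, ] <- TRUE
  expect_equal(collagen_area_fraction(m, region), 100)
  expect_warning(out <- collagen_area_fraction(m, matrix(FALSE, 4, 4)),
                 "empty analysis region")
  expect_true(is.na(out))
})

test_that("nerve metrics follow MT = (OD - AD) / 2", {
  d <- c(120L, 120L)
  idx <- which(matrix(TRUE, d[1], d[2]), arr.ind = TRUE)
  r2 <- (idx[, 1] - 60)^2 + (idx[, 2] - 60)^2
  inner <- matrix(r2 <= 30^2, d[1], d[2])
  outer <- matrix(r2 <= 50^2, d[1], d[2])
  nm <- nerve_metrics(inner, outer, pixel_size = 0.1)
  expect_equal(nm$mt_um, (nm$od_um - nm$ad_um) / 2)
  expect_equal(nm$ad_um, 6, tolerance = 0.02)
  expect_equal(nm$od_um, 10, tolerance = 0.02)

  same <- nerve_metrics(inner, inner, pixel_size = 0.1)
  expect_equal(same$mt_um, 0)
  expect_error(nerve_metrics(outer, inner, 0.1), "not contained")
})

test_that("nerve image measurement recovers the ground truth", {
  spec <- random_nerve_spec(12, width_um = 100, height_um = 100, seed = 5)
  img <- generate_nerve_image(spec, pixel_size = 0.1, width_um = 100,
                              height_um = 100, seed = 5)
  m <- measure_nerve_image(img$image, 0.1)
  expect_equal(nrow(m), nrow(spec$axons))
  # match measured fibres to the specification by centroid
  match_id <- vapply(seq_len(nrow(m)), function(i) {
    which.min((spec$axons$cx_um - m$cx_um[i])^2 +
                (spec$axons$cy_um - m$cy_um[i])^2)
  }, integer(1))
  expect_lte(mean(abs(m$ad_um - spec$axons$ad_um[match_id])), 0.2)
  expect_lte(mean(abs(m$od_um - spec$axons$od_um[match_id])), 0.2)
  expect_equal(m$mt_um, (m$od_um - m$ad_um) / 2)
})

test_that("image metrics aggregate the fibre records", {
  rec <- data.frame(
    roi_id = 1:35, area_um2 = 500,
    slow_cov = 0, fast_cov = 0,
    class = c(rep("slow", 10), rep("fast", 25)),
    mfd_um = 20
  )
  m <- image_metrics(rec)
  expect_equal(m$ftr, 0.4)
  expect_equal(m$hybrid_pct, 0)
  expect_equal(m$n_noise, 0)

  empty <- image_metrics(rec[0, ])
  expect_true(is.na(empty$ftr))
  expect_true(empty$ftr_undefined)
  expect_true(is.na(empty$hybrid_pct))
})
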