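test_that("8-bit conversion rescales the nominal range, rounding half up", {
  m16 <- matrix(c(0, 65535, 32768, 100), 2)
  out <- to_grayscale8(m16, bit_depth = 16)
  expect_equal(out[1, 1], 0)
  expect_equal(out[2, 1], 255)
  expect_equal(out[1, 2], 128)  # 32768 * 255 / 65535 = 127.5 -> up

  m8 <- matrix(sample(0:255, 16), 4)
  expect_identical(to_grayscale8(m8), m8)
})

test_that("histogram stretching maps the percentile range onto [0, 255]", {
  full <- matrix(rep(0:255, 4), 32)
  expect_equal(enhance_collagen(full, 0, 100), full)

  const <- matrix(42, 8, 8)
  expect_warning(out <- enhance_collagen(const, 1, 99), "constant")
  expect_identical(out, const)

  two <- matrix(rep(c(10, 20), each = 128), 16)
  stretched <- enhance_collagen(two, 1, 99)
  expect_setequal(unique(as.vector(stretched)), c(0, 255))
  expect_true(all(stretched[two == 10] == 0))
  expect_true(all(stretched[two == 20] == 255))

  expect_error(enhance_collagen(two, 99, 1), "low < high")
})

test_that("segmentation input is the clipped channel sum minus collagen", {
  expect_equal(compose_segmentation_input(matrix(100), matrix(100), matrix(0)),
               matrix(200))
  expect_equal(compose_segmentation_input(matrix(0), matrix(0), matrix(255)),
               matrix(0))
  expect_equal(compose_segmentation_input(matrix(200), matrix(200), matrix(0)),
               matrix(255))

  set.seed(1)
  vals <- c(0, 1, 127, 128, 254, 255, sample(0:255, 10))
  grid <- expand.grid(r = vals, g = vals, c = vals)
  got <- compose_segmentation_input(matrix(grid$r), matrix(grid$g),
                                    matrix(grid$c))
  expect_equal(as.vector(got), pmax(0, pmin(255, grid$r + grid$g - grid$c)))

  expect_error(compose_segmentation_input(matrix(0, 2, 2), matrix(0, 2, 3),
                                          matrix(0, 2, 2)), "dimension")
})

test_that("Otsu binarisation matches the brute-force variance minimiser", {
  set.seed(7)
  for (i in 1:5) {
    ch <- matrix(round(c(rnorm(600, 50, 12), rnorm(400, 190, 20))), 40)
    ch <- pmin(pmax(ch, 0), 255)
    bm <- binarise_channel(ch, "otsu")
    t_star <- brute_otsu(ch)
    # the chosen threshold must achieve the optimal within-class variance
    expect_lt(abs(brute_otsu_objective(ch, floor(bm$threshold)) -
                    brute_otsu_objective(ch, t_star)),
              1e-6 * (1 + brute_otsu_objective(ch, t_star)))
  }

  bimodal <- matrix(rep(c(30, 220), each = 128), 16)
  thr <- binarise_channel(bimodal, "otsu")$threshold
  expect_gt(thr, 30)
  expect_lt(thr, 220)
})

test_that("fixed thresholds behave monotonically", {
  const <- matrix(200, 8, 8)
  expect_true(all(binarise_channel(const, "fixed:128")$mask))
  expect_warning(bm <- binarise_channel(const, "otsu"), "constant")
  expect_false(any(bm$mask))

  set.seed(3)
  ch <- matrix(sample(0:255, 1024, replace = TRUE), 32)
  areas <- vapply(c(20, 60, 128, 200, 250), function(t) {
    sum(binarise_channel(ch, t)$mask)
  }, numeric(1))
  expect_true(all(diff(areas) <= 0))
})

test_that("TIFF round-trips preserve pixels across both dialects", {
  sim <- sim_fixture(width = 128, height = 128, diameter = 30)
  dir <- withr::local_tempdir()

  p_multi <- file.path(dir, "multi.tif")
  p_rgb <- file.path(dir, "rgb.tif")
  write_image(sim$image, p_multi, layout = "multipage")
  write_image(sim$image, p_rgb, layout = "rgb")

  back_multi <- load_image(p_multi)
  back_rgb <- load_image(p_rgb)
  expect_equal(back_multi$channels, sim$image$channels)
  expect_equal(back_rgb$channels, back_multi$channels)
  expect_equal(back_multi$pixel_size, sim$image$pixel_size)

  # a 2-channel file cannot satisfy the channel contract
  p2 <- file.path(dir, "two.tif")
  tiff::writeTIFF(list(matrix(0.5, 8, 8), matrix(0.2, 8, 8)), p2)
  expect_error(load_image(p2, pixel_size = 1), "missing channel: collagen")
  expect_error(load_image(file.path(dir, "nope.tif")), "cannot read")
})

test_that("label images round-trip through 16-bit TIFF", {
  sim <- sim_fixture(width = 128, height = 128, diameter = 30)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "labels.tif")
  write_labels(sim$truth$labels, p)
  expect_identical(read_labels(p), sim$truth$labels)
})
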