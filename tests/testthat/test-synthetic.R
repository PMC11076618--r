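test_that("fibre geometry is deterministic under a fixed seed", {
  g1 <- generate_fibre_geometry(128, 128, 30, 1, 3, seed = 7)
  g2 <- generate_fibre_geometry(128, 128, 30, 1, 3, seed = 7)
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$fibres, g2$fibres)

  s1 <- simulate_muscle_image(128, 128, 30, 1, 3, seed = 9)
  s2 <- simulate_muscle_image(128, 128, 30, 1, 3, seed = 9)
  expect_identical(s1$image$channels, s2$image$channels)
  expect_identical(s1$truth$fibres, s2$truth$fibres)
})

test_that("collagen band controls the interstitial lattice", {
  g0 <- generate_fibre_geometry(128, 128, 30, 1, 0, seed = 3)
  expect_gte(mean(g0$labels > 0), 0.99)

  fracs <- vapply(c(2, 4, 8), function(b) {
    mean(generate_fibre_geometry(128, 128, 30, 1, b, seed = 3)$labels == 0)
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("fibre interiors and collagen lattice partition every pixel", {
  sim <- sim_fixture()
  fibre_mask <- sim$truth$labels > 0
  expect_true(all(xor(fibre_mask, sim$truth$collagen_mask)))
  expect_equal(sum(sim$truth$collagen_mask),
               sum(sim$truth$labels == 0))
})

test_that("type assignment realises the requested composition", {
  map <- fake_fibre_map(10000)

  all_fast <- assign_fibre_types(map, 0, 0, seed = 1)
  expect_true(all(all_fast$fibres$true_class == "fast"))
  expect_equal(attr(all_fast, "true_ftr"), 0)

  half <- assign_fibre_types(map, 0.5, 0, seed = 2)
  expect_lt(abs(mean(half$fibres$true_class == "slow") - 0.5), 0.015)

  all_hyb <- assign_fibre_types(map, 0, 1, seed = 3)
  expect_true(is.na(attr(all_hyb, "true_ftr")))
  expect_true(attr(all_hyb, "ftr_undefined"))
  expect_equal(attr(all_hyb, "true_hybrid_pct"), 100)

  # recorded FTR agrees exactly with counting the labels
  typed <- assign_fibre_types(map, 0.4, 0.1, seed = 4)
  cls <- typed$fibres$true_class
  expect_identical(attr(typed, "true_ftr"),
                   sum(cls == "slow") / sum(cls == "fast"))

  expect_error(assign_fibre_types(map, 0.8, 0.5), "sum")
})

test_that("noise-free rendering reproduces class means exactly", {
  sim <- sim_fixture(seed = 5, intensity = noiseless_intensity())
  slow_ids <- sim$map$fibres$id[sim$map$fibres$true_class == "slow"]
  expect_gt(length(slow_ids), 0)
  inside <- sim$truth$labels == slow_ids[1]
  expect_true(all(sim$image$channels$slow[inside] ==
                    intensity_model()$slow_mean))
  expect_true(all(sim$image$channels$fast[inside] ==
                    intensity_model()$background))
  # conservation: rendered lattice equals the ground-truth collagen mask
  expect_equal(sum(sim$image$channels$collagen ==
                     intensity_model()$collagen_mean &
                     sim$truth$collagen_mask),
               sum(sim$truth$collagen_mask))
})

test_that("per-fibre red intensity separates slow from fast at default contrast", {
  sim <- sim_fixture(seed = 6, slow_fraction = 0.5, hybrid_fraction = 0)
  f <- sim$map$fibres
  mean_red <- vapply(f$id, function(id) {
    mean(sim$image$channels$slow[sim$truth$labels == id])
  }, numeric(1))
  slow_red <- mean_red[f$true_class == "slow"]
  fast_red <- mean_red[f$true_class == "fast"]
  expect_gt(length(slow_red), 0)
  expect_gt(length(fast_red), 0)
  expect_gt(min(slow_red), max(fast_red))
})

test_that("rendering refuses unresolvable contrast", {
  sim_map <- sim_fixture()$map
  expect_error(
    render_channels(sim_map, intensity_model(slow_mean = 20, fast_mean = 20,
                                             collagen_mean = 20,
                                             background = 10, noise_sd = 15)),
    "unresolvable contrast")
})

test_that("nerve specifications enforce the AD/MT/OD relationship", {
  sp <- nerve_spec(matrix(c(20, 20), 1), ad = 6, mt = 2)
  expect_equal(sp$axons$od_um, 10)
  sp0 <- nerve_spec(matrix(c(20, 20), 1), ad = 6, mt = 0)
  expect_equal(sp0$axons$od_um, 6)
  expect_error(nerve_spec(matrix(c(10, 10, 12, 10), 2, byrow = TRUE),
                          ad = c(6, 6), mt = c(2, 2)), "overlap")
})

test_that("rendered annulus area matches the closed form", {
  sp <- nerve_spec(matrix(c(15, 15), 1), ad = 6, mt = 2)
  img <- generate_nerve_image(sp, pixel_size = 0.1, width_um = 30,
                              height_um = 30, blur_sigma = 0, noise_sd = 0,
                              seed = 1)
  annulus_px <- sum(img$image == 40)
  expected <- pi * ((10 / 2)^2 - (6 / 2)^2) / 0.1^2
  expect_lt(abs(annulus_px - expected) / expected, 0.05)
  # MT = 0 leaves no annulus
  img0 <- generate_nerve_image(nerve_spec(matrix(c(15, 15), 1), 6, 0),
                               pixel_size = 0.1, width_um = 30, height_um = 30,
                               blur_sigma = 0, noise_sd = 0, seed = 1)
  expect_equal(sum(img0$image == 40), 0)
})

test_that("cohort generation respects the design layout", {
  d <- cohort_design(groups = c(A = 2L, B = 2L), sides = "nPCA",
                     regions = "PCA+", images_per_condition = 2L,
                     base_ftr = c(A = 0.5, B = 1), animal_sd = 0,
                     width_px = 128, height_px = 128,
                     mean_fibre_diameter = 30, pixel_size = 1, seed = 11)
  co <- generate_cohort(d)
  expect_equal(nrow(co$metadata), 8L)
  expect_equal(length(co$images), 8L)
  # animal_sd = 0: all animals of a condition share the expected FTR
  n_distinct <- tapply(co$metadata$expected_ftr, co$metadata$group,
                       function(x) length(unique(x)))
  expect_true(all(n_distinct == 1))
  expect_equal(unique(co$metadata$expected_ftr[co$metadata$group == "A"]), 0.5)
})

test_that("per-animal log-FTR spread matches the designed random effect", {
  d <- cohort_design(groups = c(G = 20L), sides = "nPCA", regions = "PCA+",
                     images_per_condition = 2L, base_ftr = c(G = 1),
                     animal_sd = 0.3, width_px = 256, height_px = 256,
                     mean_fibre_diameter = 30, pixel_size = 1, seed = 21)
  co <- generate_cohort(d)
  per_animal <- tapply(log(co$metadata$true_ftr), co$metadata$animal_id, mean)
  expect_gt(sd(per_animal), 0.18)
  expect_lt(sd(per_animal), 0.45)
})

test_that("cohort generation is reproducible and writes the file contract", {
  d <- cohort_design(groups = c(A = 2L), sides = "nPCA", regions = "PCA+",
                     images_per_condition = 1L, base_ftr = c(A = 1),
                     width_px = 128, height_px = 128,
                     mean_fibre_diameter = 30, pixel_size = 1, seed = 31)
  co1 <- generate_cohort(d)
  co2 <- generate_cohort(d)
  expect_identical(co1$metadata, co2$metadata)
  expect_identical(co1$images[[1]]$image$channels,
                   co2$images[[1]]$image$channels)

  out <- withr::local_tempdir()
  co3 <- generate_cohort(d, out_dir = out)
  expect_true(file.exists(file.path(out, "metadata.csv")))
  id <- co3$metadata$image_id[1]
  expect_true(file.exists(file.path(out, paste0(id, ".tif"))))
  expect_true(file.exists(file.path(out, paste0(id, "_labels.tif"))))
  reread <- load_image(file.path(out, paste0(id, ".tif")))
  expect_equal(reread$channels$slow, co1$images[[id]]$image$channels$slow)
})
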