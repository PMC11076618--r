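#' Cohort design for the synthetic study
#'
#' Describes a synthetic cohort structured like the animal study the
#' pipeline targets: experimental groups with per-group animal counts
#' (default CT = 4, SHAM = 8, DC04 = 4, DC07 = 6), two muscle sides
#' (`nPCA` = naturally innervated, `cdPCA` = cryo-damaged nerve side) and
#' two regions relative to the stimulation electrode (`PCA+` far,
#' `PCA++` close; the unimplanted CT group carries the single region
#' `PCA-`), with several images per condition. Each animal receives a
#' random intercept on log-FTR with standard deviation `animal_sd`, which
#' keeps the fibre type ratio positive and is what the mixed-model layer
#' is expected to recover.
#'
#' @param groups named integer vector of animals per group.
#' @param sides side labels.
#' @param regions region labels for implanted groups.
#' @param images_per_condition images per animal x side x region.
#' @param base_ftr named numeric vector: expected FTR per group (before
#'   side/region modifiers and animal effects).
#' @param cd_side_factor multiplicative FTR shift on the cryo-damaged
#'   side.
#' @param region_factor multiplicative FTR shift in the electrode-near
#'   `PCA++` region.
#' @param animal_sd standard deviation of the per-animal random intercept
#'   on log-FTR.
#' @param hybrid_fraction marginal hybrid-fibre proportion.
#' @param collagen_fraction designed interstitial collagen area fraction
#'   (0-1).
#' @param width_px,height_px,mean_fibre_diameter,pixel_size image
#'   geometry settings, see [generate_fibre_geometry()].
#' @param intensity an [intensity_model()].
#' @param seed master seed for the whole cohort.
#' @return object of class `cohort_design`.
#' @export
cohort_design <- function(groups = c(CT = 4L, SHAM = 8L, DC04 = 4L, DC07 = 6L),
                          sides = c("nPCA", "cdPCA"),
                          regions = c("PCA+", "PCA++"),
                          images_per_condition = 4L,
                          base_ftr = c(CT = 0.45, SHAM = 0.6,
                                       DC04 = 4.0, DC07 = 3.8),
                          cd_side_factor = 1.3,
                          region_factor = 1.2,
                          animal_sd = 0.3,
                          hybrid_fraction = 0.05,
                          collagen_fraction = 0.12,
                          width_px = 512L, height_px = 512L,
                          mean_fibre_diameter = 50, pixel_size = 0.5,
                          intensity = intensity_model(), seed = 1L) {
  if (any(groups < 1) || images_per_condition < 1) stop("all counts must be >= 1")
  if (hybrid_fraction < 0 || hybrid_fraction > 1 ||
      collagen_fraction < 0 || collagen_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (any(base_ftr <= 0)) stop("base_ftr must be > 0")
  if (!all(names(groups) %in% names(base_ftr))) {
    stop("base_ftr must name every group")
  }
  structure(
    list(groups = groups, sides = sides, regions = regions,
         images_per_condition = as.integer(images_per_condition),
         base_ftr = base_ftr, cd_side_factor = cd_side_factor,
         region_factor = region_factor, animal_sd = animal_sd,
         hybrid_fraction = hybrid_fraction,
         collagen_fraction = collagen_fraction,
         width_px = width_px, height_px = height_px,
         mean_fibre_diameter = mean_fibre_diameter, pixel_size = pixel_size,
         intensity = intensity, seed = seed),
    class = "cohort_design"
  )
}

#' Generate a synthetic cohort of muscle images with ground truth
#'
#' Draws a per-animal random intercept on log-FTR (sd = `animal_sd`),
#' derives each image's slow fraction from the animal's expected FTR and
#' the design's hybrid fraction, and renders `images_per_condition`
#' cross-sections per animal x side x region. Everything is reproducible
#' from the design seed.
#'
#' @param design a [cohort_design()].
#' @param out_dir optional directory; when given, each image is written as
#'   multi-page TIFF with a ground-truth label TIFF, collagen-mask TIFF
#'   and a `metadata.csv`, and the returned bundle carries file paths
#'   instead of in-memory images.
#' @return list with `design`, `metadata` (one row per image: image_id,
#'   animal_id, group, side, region, true_ftr, true_hybrid_pct,
#'   true_collagen_pct, seed, plus the animal's expected FTR), and
#'   `images` (named list of [render_channels()] bundles, or paths).
#' @export
generate_cohort <- function(design, out_dir = NULL) {
  stopifnot(inherits(design, "cohort_design"))
  band <- calibrate_collagen_band(
    100 * design$collagen_fraction, design$width_px, design$height_px,
    design$mean_fibre_diameter, design$pixel_size, seed = design$seed
  )
  animals <- data.frame(
    animal_id = unlist(lapply(names(design$groups), function(g) {
      sprintf("%s_a%02d", g, seq_len(design$groups[[g]]))
    })),
    group = rep(names(design$groups), design$groups)
  )
  master <- derive_seeds(design$seed, 2)
  animals$intercept <- with_seed(master[1],
                                 rnorm(nrow(animals), 0, design$animal_sd))

  rows <- list()
  images <- list()
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counter <- 0L
  for (a in seq_len(nrow(animals))) {
    grp <- animals$group[a]
    regions <- if (grp == "CT") "PCA-" else design$regions
    for (side in design$sides) {
      for (region in regions) {
        mu_ftr <- design$base_ftr[[grp]] *
          (if (side == "cdPCA") design$cd_side_factor else 1) *
          (if (region == "PCA++") design$region_factor else 1)
        ftr_a <- mu_ftr * exp(animals$intercept[a])
        slow_frac <- (1 - design$hybrid_fraction) * ftr_a / (1 + ftr_a)
        for (k in seq_len(design$images_per_condition)) {
          counter <- counter + 1L
          img_seed <- derive_seeds(master[2] %% 1e9 + counter, 1)
          image_id <- sprintf("%s_%s_%s_im%02d", animals$animal_id[a],
                              side, gsub("[+]", "p", region), k)
          sub <- derive_seeds(img_seed, 3)
          map <- generate_fibre_geometry(design$width_px, design$height_px,
                                         design$mean_fibre_diameter,
                                         design$pixel_size, band,
                                         seed = sub[1])
          map <- assign_fibre_types(map, slow_frac, design$hybrid_fraction,
                                    seed = sub[2])
          bundle <- render_channels(map, design$intensity, seed = sub[3])
          rows[[counter]] <- data.frame(
            image_id = image_id, animal_id = animals$animal_id[a],
            group = grp, side = side, region = region,
            true_ftr = bundle$truth$true_ftr,
            true_hybrid_pct = bundle$truth$true_hybrid_pct,
            true_collagen_pct = bundle$truth$true_collagen_pct,
            expected_ftr = ftr_a, seed = img_seed
          )
          if (is.null(out_dir)) {
            images[[image_id]] <- bundle
          } else {
            img_path <- file.path(out_dir, paste0(image_id, ".tif"))
            write_image(bundle$image, img_path)
            write_labels(bundle$truth$labels,
                         file.path(out_dir, paste0(image_id, "_labels.tif")))
            tiff::writeTIFF(bundle$truth$collagen_mask * 1,
                            file.path(out_dir, paste0(image_id, "_collagen.tif")),
                            bits.per.sample = 8)
            images[[image_id]] <- img_path
          }
        }
      }
    }
  }
  metadata <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    write.csv(metadata, file.path(out_dir, "metadata.csv"), row.names = FALSE)
  }
  list(design = design, metadata = metadata, images = images,
       collagen_band = band, animals = animals)
}
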