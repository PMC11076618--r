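#' Pipeline run configuration
#'
#' Collects every tunable parameter of the workflow; the full
#' configuration is echoed verbatim into the run manifest so no run can
#' silently use a default.
#'
#' @param stretch_low,stretch_high histogram-stretch percentiles for the
#'   collagen channel.
#' @param backend segmentation backend, see [segment_fibres()].
#' @param min_fibre_diameter watershed merge scale in micrometres.
#' @param seg_threshold binarisation method for the segmentation input.
#' @param mask_threshold binarisation method for the myosin channels used
#'   in classification.
#' @param collagen_threshold binarisation method for the enhanced collagen
#'   channel. The stretch maps the collagen structures onto the top of the
#'   8-bit range, so the mid-range cut 128 is the natural area-preserving
#'   threshold; Otsu is unreliable here because the collagen foreground is
#'   a small minority of the pixels.
#' @param classification a [classification_params()].
#' @param alpha significance level on q-values for the statistics stage.
#' @param stat_metrics metric columns passed to [fit_metric_lmm()].
#' @param condition_cols columns defining the experimental condition.
#' @param seed integer seed (reserved for stages with randomness).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(stretch_low = 1, stretch_high = 99,
                            backend = "watershed", min_fibre_diameter = 15,
                            seg_threshold = "otsu", mask_threshold = "otsu",
                            collagen_threshold = "fixed:128",
                            classification = classification_params(),
                            alpha = 0.1,
                            stat_metrics = c("ftr", "hybrid_pct", "collagen_pct"),
                            condition_cols = c("group", "side", "region"),
                            seed = 1L) {
  structure(list(stretch_low = stretch_low, stretch_high = stretch_high,
                 backend = backend, min_fibre_diameter = min_fibre_diameter,
                 seg_threshold = seg_threshold, mask_threshold = mask_threshold,
                 collagen_threshold = collagen_threshold,
                 classification = classification, alpha = alpha,
                 stat_metrics = stat_metrics, condition_cols = condition_cols,
                 seed = seed),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Reads a flat YAML mapping of [pipeline_config()] arguments (nested
#' `classification:` entries become [classification_params()]).
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
pipeline_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$classification)) {
    vals$classification <- do.call(classification_params, vals$classification)
  }
  unknown <- setdiff(names(vals), names(formals(pipeline_config)))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  }
  do.call(pipeline_config, vals)
}

#' Analyse one multi-channel muscle image
#'
#' Runs the three-step workflow on a single image: pre-processing (8-bit
#' conversion, collagen enhancement, channel composition), fibre
#' segmentation, border filtering, classification against the binarised
#' myosin channels, and morphometry (per-fibre MFD, per-image FTR, hybrid
#' percentage, collagen area fraction).
#'
#' @param image a [multichannel_image()].
#' @param config a [pipeline_config()].
#' @param external_labels optional instance label matrix for the external
#'   segmentation backend.
#' @return list with `records` (fibre table), `metrics`
#'   ([image_metrics()]), `label_map` and a `provenance` list of the
#'   thresholds actually applied.
#' @export
analyse_image <- function(image, config = pipeline_config(),
                          external_labels = NULL) {
  stopifnot(inherits(image, "multichannel_image"))
  chans <- lapply(image$channels, to_grayscale8, bit_depth = image$bit_depth)
  enhanced <- enhance_collagen(chans$collagen, config$stretch_low,
                               config$stretch_high)
  seg_input <- compose_segmentation_input(chans$slow, chans$fast, enhanced)
  lm <- segment_fibres(seg_input, image$pixel_size, backend = config$backend,
                       min_fibre_diameter = config$min_fibre_diameter,
                       threshold = config$seg_threshold,
                       external_labels = external_labels)
  rois <- filter_border_rois(labels_to_rois(lm, image$pixel_size))
  slow_mask <- binarise_channel(chans$slow, config$mask_threshold)
  fast_mask <- binarise_channel(chans$fast, config$mask_threshold)
  collagen_mask <- binarise_channel(enhanced, config$collagen_threshold)
  cls <- classify_image(rois, slow_mask, fast_mask, config$classification)
  metrics <- image_metrics(cls$records, collagen_mask)
  list(records = cls$records, metrics = metrics, label_map = lm,
       provenance = list(
         slow_threshold = slow_mask$threshold,
         fast_threshold = fast_mask$threshold,
         collagen_threshold = collagen_mask$threshold,
         segmentation = lm$params, backend = lm$backend,
         classification = config$classification
       ))
}

#' Run the full pipeline over a cohort
#'
#' Orchestrates simulate/load -> pre-process -> segment -> classify ->
#' measure -> test. Per-image failures are isolated and reported; the run
#' errors only if every image fails. When `out_dir` is given, the
#' per-fibre table, per-image metrics, per-metric statistics and a JSON
#' manifest (full configuration echo + package version) are written as
#' CSV/JSON, deterministically for a fixed cohort and configuration.
#'
#' @param cohort a [generate_cohort()] bundle, or a list with `metadata`
#'   (data frame including `image_id`, `animal_id` and condition columns)
#'   and `images` (named list of [multichannel_image()] objects, of
#'   [render_channels()] bundles, or of TIFF paths).
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory.
#' @return list with `fibre_table`, `image_metrics` (metadata joined with
#'   measured metrics), `stats` (named list of [fit_metric_lmm()] fits or
#'   `NULL` when a metric could not be modelled), `errors` (per-image
#'   error messages) and `manifest`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config(), out_dir = NULL) {
  meta <- cohort$metadata
  stopifnot(is.data.frame(meta), "image_id" %in% names(meta))
  fibre_rows <- list()
  metric_rows <- list()
  errors <- list()
  for (i in seq_len(nrow(meta))) {
    id <- meta$image_id[i]
    res <- tryCatch({
      obj <- cohort$images[[id]]
      img <- if (inherits(obj, "multichannel_image")) obj
             else if (is.list(obj) && !is.null(obj$image)) obj$image
             else load_image(obj)
      analyse_image(img, config)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[id]] <- conditionMessage(res)
      next
    }
    rec <- res$records
    if (nrow(rec) > 0) rec <- cbind(image_id = id, rec)
    fibre_rows[[id]] <- rec
    metric_rows[[id]] <- cbind(meta[i, , drop = FALSE],
                               as.data.frame(res$metrics))
  }
  if (length(metric_rows) == 0) {
    stop("all images failed: ", paste(unlist(errors), collapse = "; "))
  }
  fibre_table <- do.call(rbind, fibre_rows[!vapply(fibre_rows, is.null, TRUE)])
  image_metrics_tab <- do.call(rbind, metric_rows)
  rownames(image_metrics_tab) <- NULL

  stats <- list()
  for (m in config$stat_metrics) {
    stats[[m]] <- tryCatch(
      fit_metric_lmm(image_metrics_tab, m,
                     condition_cols = config$condition_cols,
                     alpha = config$alpha),
      error = function(e) {
        message(sprintf("statistics for '%s' skipped: %s", m,
                        conditionMessage(e)))
        NULL
      })
  }

  manifest <- list(
    package = "fibremorph",
    version = as.character(utils::packageVersion("fibremorph")),
    config = unclass(config),
    n_images = nrow(meta), n_failed = length(errors),
    image_ids = meta$image_id
  )
  out <- list(fibre_table = fibre_table, image_metrics = image_metrics_tab,
              stats = stats, errors = errors, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(fibre_table, file.path(out_dir, "fibre_table.csv"),
              row.names = FALSE)
    write.csv(image_metrics_tab, file.path(out_dir, "image_metrics.csv"),
              row.names = FALSE)
    for (m in names(stats)) {
      if (!is.null(stats[[m]])) {
        write.csv(stats[[m]]$results,
                  file.path(out_dir, sprintf("stats_%s.csv", m)),
                  row.names = FALSE)
      }
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Check that a small field of view is representative of a section
#'
#' Samples `n_fovs` disjoint fields of view at random positions of a
#' synthetic full section, computes the ground-truth FTR inside each FOV
#' (fibres touching the FOV border excluded, as in the image pipeline),
#' and compares the FOV FTRs against the full-section FTR with a
#' one-sample t-test. Disjointness keeps the FOV values independent; the
#' section must be able to host `n_fovs` non-overlapping FOVs. A
#' homogeneous section should show no difference; a spatially zonated one
#' should be detected.
#'
#' @param scene a [simulate_muscle_image()] bundle (or any list with
#'   `truth$labels` and `truth$fibres` incl. `true_class`).
#' @param fov_px FOV side length in pixels; must not exceed the section.
#' @param n_fovs number of disjoint FOVs to sample.
#' @param seed integer seed for FOV placement.
#' @return list with `table` (per-FOV origin, counts and FTR),
#'   `section_ftr`, the mean FOV FTR and the t-test `p` (1 when every FOV
#'   reproduces the section FTR exactly).
#' @export
validate_fov_representativeness <- function(scene, fov_px, n_fovs = 8,
                                            seed = 1L) {
  labels <- scene$truth$labels
  fibres <- scene$truth$fibres
  d <- dim(labels)
  if (fov_px > min(d)) stop("FOV larger than the section")
  cls_of <- setNames(fibres$true_class, fibres$id)
  # the section FTR uses the same border-exclusion rule as any FOV
  sec_border <- unique(c(labels[1, ], labels[d[1], ],
                         labels[, 1], labels[, d[2]]))
  sec_ids <- setdiff(fibres$id, sec_border)
  sec_cls <- cls_of[as.character(sec_ids)]
  section_ftr <- fibre_type_ratio(sum(sec_cls == "slow"),
                                  sum(sec_cls == "fast"))
  tiles <- expand.grid(
    row = seq(1L, d[1] - fov_px + 1L, by = fov_px),
    col = seq(1L, d[2] - fov_px + 1L, by = fov_px)
  )
  if (nrow(tiles) < n_fovs) {
    stop("section too small to host n_fovs disjoint FOVs")
  }
  origins <- with_seed(seed, tiles[sample.int(nrow(tiles), n_fovs), , drop = FALSE])
  rows <- lapply(seq_len(n_fovs), function(k) {
    r0 <- origins[k, "row"]; c0 <- origins[k, "col"]
    crop <- labels[r0:(r0 + fov_px - 1L), c0:(c0 + fov_px - 1L)]
    ids <- setdiff(unique(as.vector(crop)), 0L)
    border <- unique(c(crop[1, ], crop[fov_px, ], crop[, 1], crop[, fov_px]))
    ids <- setdiff(ids, border)
    cls <- cls_of[as.character(ids)]
    n_slow <- sum(cls == "slow", na.rm = TRUE)
    n_fast <- sum(cls == "fast", na.rm = TRUE)
    data.frame(fov = k, row = r0, col = c0, n_slow = n_slow, n_fast = n_fast,
               ftr = fibre_type_ratio(n_slow, n_fast))
  })
  tab <- do.call(rbind, rows)
  ftrs <- tab$ftr[is.finite(tab$ftr)]
  p <- if (length(ftrs) >= 2 && stats::sd(ftrs) > 0) {
    t.test(ftrs, mu = section_ftr)$p.value
  } else if (all(ftrs == section_ftr)) {
    1
  } else {
    NA_real_
  }
  list(table = tab, section_ftr = section_ftr,
       mean_fov_ftr = mean(ftrs), p = p)
}

#' Score pipeline classifications against simulator ground truth
#'
#' Pairs every classified ROI with the ground-truth fibre it overlaps
#' most, and reports the percentage of ROIs whose assigned class equals
#' the true class. ROIs that overlap no ground-truth fibre count as
#' errors.
#'
#' @param pred_labels label matrix of the segmentation
#'   (`label_map$labels`).
#' @param records classified fibre records ([classify_image()]).
#' @param truth simulator ground truth (with `labels` and `fibres`).
#' @return list with `accuracy_pct` and `n` (ROIs scored).
#' @export
classification_accuracy <- function(pred_labels, records, truth) {
  if (nrow(records) == 0) return(list(accuracy_pct = NA_real_, n = 0L))
  pv <- as.vector(pred_labels)
  tv <- as.vector(truth$labels)
  cls_of <- setNames(truth$fibres$true_class, truth$fibres$id)
  correct <- vapply(seq_len(nrow(records)), function(i) {
    sel <- pv == records$roi_id[i]
    overlap <- table(tv[sel])
    overlap <- overlap[names(overlap) != "0"]
    if (length(overlap) == 0) return(FALSE)
    true_cls <- cls_of[names(overlap)[which.max(overlap)]]
    identical(unname(true_cls), records$class[i])
  }, logical(1))
  list(accuracy_pct = 100 * mean(correct), n = nrow(records))
}

#' Validate pipeline classes against expert annotation
#'
#' @param run a [run_pipeline()] result (uses its `fibre_table`).
#' @param annotation data frame with `image_id`, `roi_id`, `class` from
#'   manual annotation; unmatched ids are reported, not fatal.
#' @return list with the per-image accuracy report of
#'   [compare_to_annotation()] plus a class confusion matrix
#'   (rows = automated, columns = manual).
#' @export
validate_against_annotation <- function(run, annotation) {
  auto <- run$fibre_table[, c("image_id", "roi_id", "class")]
  acc <- compare_to_annotation(auto, annotation)
  key_a <- paste(auto$image_id, auto$roi_id)
  key_m <- paste(annotation$image_id, annotation$roi_id)
  shared <- intersect(key_a, key_m)
  unmatched <- setdiff(key_m, key_a)
  if (length(unmatched)) {
    message(sprintf("%d annotated ROI(s) not found in run output",
                    length(unmatched)))
  }
  lv <- c("slow", "fast", "hybrid", "noise")
  confusion <- table(
    automated = factor(auto$class[match(shared, key_a)], levels = lv),
    manual = factor(annotation$class[match(shared, key_m)], levels = lv)
  )
  c(acc, list(confusion = confusion, unmatched_ids = unmatched))
}
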