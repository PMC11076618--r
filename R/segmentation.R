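#' Segment muscle fibres into an instance label map
#'
#' Default backend is a classical distance-transform watershed: the
#' composed segmentation input (bright fibre interiors, dark interstitial
#' lattice) is thresholded, the distance transform of the foreground is
#' flooded from its regional maxima, and each catchment basin becomes one
#' fibre label. The `external` backend ingests a label image produced by
#' any instance-segmentation tool (e.g. a learned model), so downstream
#' results are a pure function of the label map, never of the backend.
#'
#' @param seg_input 8-bit numeric matrix from
#'   [compose_segmentation_input()] (ignored by the external backend
#'   except for dimension checking).
#' @param pixel_size micrometres per pixel.
#' @param backend `"watershed"` or `"external"`.
#' @param min_fibre_diameter minimum expected fibre diameter in
#'   micrometres; sets the watershed merge tolerance. Default 15 um, a
#'   physiological lower bound for adult large-mammal fibres.
#' @param threshold binarisation method for the watershed backend, see
#'   [binarise_channel()].
#' @param external_labels integer matrix of instance labels for the
#'   external backend.
#' @return A `label_map`: list with integer `labels` matrix (0 =
#'   background), `backend` tag and `params`.
#' @export
segment_fibres <- function(seg_input, pixel_size,
                           backend = c("watershed", "external"),
                           min_fibre_diameter = 15, threshold = "otsu",
                           external_labels = NULL) {
  backend <- match.arg(backend)
  if (backend == "external") {
    if (is.null(external_labels)) stop("external backend requires 'external_labels'")
    if (!is.null(seg_input) && !all(dim(external_labels) == dim(seg_input))) {
      stop("external label dimensions do not match the input image")
    }
    return(new_label_map(external_labels, "external",
                         list(min_fibre_diameter = min_fibre_diameter)))
  }
  bm <- binarise_channel(seg_input, threshold)
  if (!any(bm$mask)) {
    warning("empty foreground; returning empty label map")
    return(new_label_map(matrix(0L, nrow(seg_input), ncol(seg_input)),
                         "watershed",
                         list(threshold = bm$threshold,
                              min_fibre_diameter = min_fibre_diameter)))
  }
  maskE <- EBImage::Image(t(bm$mask))
  dm <- EBImage::distmap(maskE)
  tol <- max(1, (min_fibre_diameter / pixel_size) / 4)
  ws <- EBImage::watershed(dm, tolerance = tol, ext = 1)
  labels <- t(EBImage::imageData(ws))
  storage.mode(labels) <- "integer"
  new_label_map(labels, "watershed",
                list(threshold = bm$threshold, threshold_method = bm$method,
                     min_fibre_diameter = min_fibre_diameter, tolerance = tol))
}

new_label_map <- function(labels, backend, params) {
  structure(list(labels = labels, backend = backend, params = params),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  cat(sprintf("<label_map> %d x %d px, %d labels, backend = %s\n",
              ncol(x$labels), nrow(x$labels),
              length(setdiff(unique(as.vector(x$labels)), 0L)), x$backend))
  invisible(x)
}

#' Convert an instance label map to ROIs
#'
#' One ROI per label id. Area is the pixel count times the squared pixel
#' size; `touches_border` is set iff any ROI pixel lies on the outermost
#' row or column.
#'
#' @param label_map a `label_map` from [segment_fibres()], or a plain
#'   integer matrix.
#' @param pixel_size micrometres per pixel.
#' @return list of ROIs, each a list with `id`, `pixels` (linear indices
#'   into the image matrix), `area_um2`, `touches_border` and the image
#'   `dim`.
#' @export
labels_to_rois <- function(label_map, pixel_size) {
  labels <- if (inherits(label_map, "label_map")) label_map$labels else label_map
  d <- dim(labels)
  vec <- as.vector(labels)
  inside <- which(vec > 0L)
  if (length(inside) == 0L) return(list())
  groups <- split(inside, vec[inside])
  lapply(names(groups), function(id) {
    px <- groups[[id]]
    rows <- (px - 1L) %% d[1] + 1L
    cols <- (px - 1L) %/% d[1] + 1L
    list(id = as.integer(id), pixels = px,
         area_um2 = length(px) * pixel_size^2,
         touches_border = any(rows == 1L | rows == d[1] |
                                cols == 1L | cols == d[2]),
         dim = d, pixel_size = pixel_size)
  })
}

#' Exclude ROIs touching the image border
#'
#' Fibres cut by the field of view would bias size and coverage measures;
#' only interior ROIs are kept. The number of removed ROIs is reported
#' via `message()`.
#'
#' @param rois list of ROIs from [labels_to_rois()].
#' @return the interior ROIs.
#' @export
filter_border_rois <- function(rois) {
  keep <- !vapply(rois, `[[`, logical(1), "touches_border")
  if (any(!keep)) {
    message(sprintf("removed %d border-touching ROI(s)", sum(!keep)))
  }
  rois[keep]
}

#' Match predicted instances to ground-truth instances
#'
#' Greedy best-overlap matching: each ground-truth instance is paired
#' with the predicted label covering most of its pixels, and the
#' intersection-over-union of the pair is reported. Used to score a
#' segmentation backend against simulator ground truth.
#'
#' @param pred,truth integer label matrices of identical dimensions.
#' @return data frame with `true_id`, `pred_id` (0 when unmatched) and
#'   `iou`.
#' @export
match_instances <- function(pred, truth) {
  stopifnot(all(dim(pred) == dim(truth)))
  tv <- as.vector(truth)
  pv <- as.vector(pred)
  ids <- setdiff(sort(unique(tv)), 0L)
  pred_sizes <- table(pv[pv > 0])
  out <- lapply(ids, function(id) {
    sel <- tv == id
    overlap <- table(pv[sel])
    overlap <- overlap[names(overlap) != "0"]
    if (length(overlap) == 0) {
      return(data.frame(true_id = id, pred_id = 0L, iou = 0))
    }
    best <- names(overlap)[which.max(overlap)]
    inter <- overlap[[best]]
    union <- sum(sel) + pred_sizes[[best]] - inter
    data.frame(true_id = id, pred_id = as.integer(best), iou = inter / union)
  })
  do.call(rbind, out)
}

#' Export ROIs as run-length-encoded JSON
#'
#' @param rois list of ROIs from [labels_to_rois()].
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
export_rois_json <- function(rois, path) {
  enc <- lapply(rois, function(r) {
    px <- sort(r$pixels)
    breaks <- which(diff(px) != 1L)
    starts <- px[c(1L, breaks + 1L)]
    lengths <- diff(c(0L, breaks, length(px)))
    list(id = r$id, dim = r$dim, area_um2 = r$area_um2,
         touches_border = r$touches_border, pixel_size = r$pixel_size,
         rle = list(starts = starts, lengths = lengths))
  })
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import ROIs from run-length-encoded JSON
#'
#' @param path JSON written by [export_rois_json()].
#' @return list of ROIs.
#' @export
import_rois_json <- function(path) {
  enc <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(nrow(enc)), function(i) {
    starts <- enc$rle$starts[[i]]
    lengths <- enc$rle$lengths[[i]]
    px <- unlist(mapply(function(s, l) seq.int(s, length.out = l),
                        starts, lengths, SIMPLIFY = FALSE))
    list(id = enc$id[i], pixels = as.integer(px), area_um2 = enc$area_um2[i],
         touches_border = enc$touches_border[i],
         dim = as.integer(enc$dim[[i]]), pixel_size = enc$pixel_size[i])
  })
}
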