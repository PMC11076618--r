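#' Multi-channel fluorescence image container
#'
#' Bundles the three biological channels of an immunofluorescence muscle
#' cross-section -- `slow` (red, myosin slow), `fast` (green, myosin fast)
#' and `collagen` (orange) -- together with the physical pixel size.
#' Channels are numeric matrices (rows = y, columns = x) holding integer
#' pixel values on the nominal range of `bit_depth`.
#'
#' @param slow,fast,collagen numeric matrices with identical dimensions.
#' @param pixel_size physical pixel size in micrometres per pixel.
#' @param bit_depth nominal bit depth of the pixel values (8 or 16).
#' @param provenance free-form provenance tag (source path or simulator
#'   seed); kept for run manifests.
#' @return An object of class `multichannel_image`.
#' @export
multichannel_image <- function(slow, fast, collagen, pixel_size,
                               bit_depth = 8L, provenance = NULL) {
  chans <- list(slow = slow, fast = fast, collagen = collagen)
  for (nm in names(chans)) {
    if (!is.matrix(chans[[nm]]) || !is.numeric(chans[[nm]])) {
      stop(sprintf("channel '%s' must be a numeric matrix", nm))
    }
  }
  dims <- vapply(chans, dim, integer(2))
  if (!all(dims == dims[, 1])) stop("all channels must share identical dimensions")
  stopifnot_scalar(pixel_size, "pixel_size")
  if (pixel_size <= 0) stop("'pixel_size' must be > 0")
  if (!bit_depth %in% c(8L, 16L)) stop("'bit_depth' must be 8 or 16")
  structure(
    list(channels = chans, pixel_size = pixel_size,
         bit_depth = as.integer(bit_depth), provenance = provenance),
    class = "multichannel_image"
  )
}

#' @export
print.multichannel_image <- function(x, ...) {
  d <- dim(x$channels$slow)
  cat(sprintf(
    "<multichannel_image> %d x %d px, %d-bit, %.3g um/px, channels: %s\n",
    d[2], d[1], x$bit_depth, x$pixel_size,
    paste(names(x$channels), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.multichannel_image <- function(x) dim(x$channels$slow)

#' Write a multi-channel image to TIFF
#'
#' Writes either the canonical multi-page dialect (one 8-bit page per
#' channel in the fixed order slow, fast, collagen) or an interleaved RGB
#' dialect (slow -> red, fast -> green, collagen -> blue plane). The pixel
#' size is recorded in a JSON sidecar `<path>.json`, since TIFF resolution
#' tags are not reliably preserved by all writers.
#'
#' @param image a [multichannel_image()].
#' @param path output file path.
#' @param layout `"multipage"` (default) or `"rgb"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path, layout = c("multipage", "rgb")) {
  layout <- match.arg(layout)
  stopifnot(inherits(image, "multichannel_image"))
  maxval <- 2^image$bit_depth - 1
  bits <- image$bit_depth
  if (layout == "multipage") {
    pages <- lapply(image$channels, function(ch) pmin(pmax(ch, 0), maxval) / maxval)
    tiff::writeTIFF(pages, path, bits.per.sample = bits)
  } else {
    d <- dim(image$channels$slow)
    arr <- array(0, dim = c(d[1], d[2], 3))
    arr[, , 1] <- image$channels$slow
    arr[, , 2] <- image$channels$fast
    arr[, , 3] <- image$channels$collagen
    tiff::writeTIFF(pmin(pmax(arr, 0), maxval) / maxval, path, bits.per.sample = bits)
  }
  sidecar <- paste0(path, ".json")
  jsonlite::write_json(
    list(pixel_size_um = image$pixel_size, bit_depth = image$bit_depth,
         channel_order = names(image$channels), layout = layout),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a multi-channel image from TIFF
#'
#' Accepts both dialects written by [write_image()]: a multi-page TIFF
#' (one page per channel) or a single interleaved RGB page. Pixel size is
#' taken from the TIFF resolution tags when present, else from the JSON
#' sidecar written alongside, else from the `pixel_size` argument.
#'
#' @param path TIFF file path.
#' @param channel_order names to assign to pages/planes in order; must
#'   cover `slow`, `fast` and `collagen`.
#' @param pixel_size fallback pixel size in micrometres per pixel.
#' @return A [multichannel_image()].
#' @export
load_image <- function(path, channel_order = c("slow", "fast", "collagen"),
                       pixel_size = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, info = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  first <- pages[[1]]
  chans <- if (length(pages) == 1L && length(dim(first)) == 3L) {
    lapply(seq_len(dim(first)[3]), function(k) first[, , k])
  } else {
    lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  }
  for (nm in c("slow", "fast", "collagen")) {
    if (!nm %in% channel_order[seq_along(chans)]) {
      stop(sprintf("missing channel: %s", nm))
    }
  }
  bits <- attr(first, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  maxval <- 2^bits - 1
  chans <- lapply(chans, function(p) {
    m <- round(p * maxval)
    attributes(m) <- list(dim = dim(m))   # drop TIFF tag attributes
    m
  })
  names(chans) <- channel_order[seq_along(chans)]

  if (is.null(pixel_size)) pixel_size <- pixel_size_from_tags(first)
  if (is.null(pixel_size)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      meta <- jsonlite::read_json(sidecar)
      pixel_size <- meta$pixel_size_um
    }
  }
  if (is.null(pixel_size)) {
    stop("pixel size not found in TIFF tags or sidecar; pass 'pixel_size'")
  }
  multichannel_image(chans$slow, chans$fast, chans$collagen,
                     pixel_size = pixel_size, bit_depth = as.integer(bits),
                     provenance = path)
}

# Pixel size (um/px) from TIFF resolution tags, NULL when absent.
pixel_size_from_tags <- function(page) {
  xres <- attr(page, "x.resolution")
  unit <- attr(page, "resolution.unit")
  if (is.null(xres) || is.null(unit) || xres <= 0) return(NULL)
  per_um <- switch(as.character(unit),
                   cm = xres / 1e4, inch = xres / 25400, NULL)
  if (is.null(per_um)) NULL else 1 / per_um
}

#' Write a label image as 16-bit TIFF
#'
#' @param labels integer matrix, 0 = background.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  if (max(labels) > 65535) stop("more than 65535 labels cannot be stored in 16-bit TIFF")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a label image from 16-bit TIFF
#'
#' @param path label TIFF written by [write_labels()] or an external tool.
#' @return integer matrix of instance labels.
#' @export
read_labels <- function(path) {
  p <- tiff::readTIFF(path)
  if (length(dim(p)) == 3L) p <- p[, , 1]
  matrix(as.integer(round(p * 65535)), nrow = nrow(p))
}
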