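#' Convert a channel to 8-bit grayscale
#'
#' Linearly rescales the input's full nominal range to \[0, 255\],
#' rounding half up. 8-bit input is returned unchanged.
#'
#' @param channel numeric matrix of non-negative integer pixel values.
#' @param bit_depth nominal bit depth of the input; inferred from the
#'   value range when missing (values above 255 imply 16-bit).
#' @return numeric matrix with values in \[0, 255\].
#' @export
to_grayscale8 <- function(channel, bit_depth = NULL) {
  if (is.null(bit_depth)) {
    bit_depth <- if (max(channel) > 255) 16L else 8L
  }
  if (bit_depth == 8L) return(channel)
  maxval <- 2^bit_depth - 1
  floor(channel * 255 / maxval + 0.5)
}

#' Enhance collagen by histogram stretching
#'
#' Maps intensities at or below the low percentile to 0 and at or above
#' the high percentile to 255, linearly in between. This accentuates the
#' interstitial collagen lattice of the orange channel before it is
#' subtracted from the myosin channels.
#'
#' @param channel 8-bit numeric matrix.
#' @param low,high stretch percentiles, `0 <= low < high <= 100`;
#'   defaults (1, 99).
#' @return stretched 8-bit matrix. A constant channel is returned
#'   unchanged with a warning (the percentiles coincide).
#' @export
enhance_collagen <- function(channel, low = 1, high = 99) {
  if (low < 0 || high > 100 || low >= high) {
    stop("require 0 <= low < high <= 100")
  }
  qs <- quantile(channel, c(low, high) / 100, names = FALSE)
  if (qs[2] <= qs[1]) {
    warning("channel is constant over the stretch percentiles; returned unchanged")
    return(channel)
  }
  out <- (channel - qs[1]) * 255 / (qs[2] - qs[1])
  floor(pmin(pmax(out, 0), 255) + 0.5)
}

#' Compose the segmentation input channel
#'
#' Pixelwise `clip(slow + fast - collagen, 0, 255)`: the enhanced collagen
#' lattice is subtracted from the sum of the two myosin channels, leaving
#' fibre interiors bright and fibre boundaries dark.
#'
#' @param slow_ch,fast_ch,enhanced_collagen 8-bit matrices of identical
#'   dimensions.
#' @return 8-bit matrix.
#' @export
compose_segmentation_input <- function(slow_ch, fast_ch, enhanced_collagen) {
  if (!all(dim(slow_ch) == dim(fast_ch)) ||
      !all(dim(slow_ch) == dim(enhanced_collagen))) {
    stop("channel dimensions must match")
  }
  pmin(pmax(slow_ch + fast_ch - enhanced_collagen, 0), 255)
}

#' Binarise a channel into foreground and background
#'
#' @param channel 8-bit numeric matrix.
#' @param method `"otsu"` (default) for Otsu's threshold, or a fixed
#'   numeric threshold (also accepted as a string `"fixed:128"`).
#'   Foreground is strictly above the threshold.
#' @return A `binary_mask`: list with logical `mask`, the `method` tag and
#'   the numeric `threshold` used. A constant channel yields an
#'   all-background mask with a warning.
#' @export
binarise_channel <- function(channel, method = "otsu") {
  if (is.character(method) && grepl("^fixed:", method)) {
    method <- as.numeric(sub("^fixed:", "", method))
  }
  if (is.numeric(method)) {
    thr <- method
    tag <- "fixed"
  } else if (identical(method, "otsu")) {
    if (max(channel) == min(channel)) {
      warning("constant channel; returning all-background mask")
      return(new_binary_mask(matrix(FALSE, nrow(channel), ncol(channel)),
                             "otsu", NA_real_))
    }
    thr <- EBImage::otsu(as_ebimage(channel), range = c(0, 1), levels = 256) * 255
    tag <- "otsu"
  } else {
    stop("method must be 'otsu', a number, or 'fixed:<t>'")
  }
  new_binary_mask(channel > thr, tag, thr)
}

new_binary_mask <- function(mask, method, threshold, source_channel = NULL) {
  structure(list(mask = mask, method = method, threshold = threshold,
                 source_channel = source_channel),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask> %d x %d px, %s threshold = %s, foreground %.1f%%\n",
              ncol(x$mask), nrow(x$mask), x$method, format(x$threshold),
              100 * mean(x$mask)))
  invisible(x)
}
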