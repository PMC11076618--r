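# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a reproducible stream of sub-seeds (< 2^31) from one master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stopifnot_scalar <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
}

# Convert a [0, 255] numeric matrix (rows = y) to an EBImage Image in [0, 1].
as_ebimage <- function(m) {
  EBImage::Image(t(m) / 255)
}

# Back-convert an EBImage object to a numeric matrix (rows = y) in [0, 255].
from_ebimage <- function(img) {
  t(EBImage::imageData(img)) * 255
}
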