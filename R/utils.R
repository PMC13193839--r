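#' @keywords internal
"_PACKAGE"

# Canonical class order used everywhere: alphabetical, fixed.
LUNG_CLASSES <- c("Benign", "Malignant", "Normal")

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

#' Validate a grayscale image matrix
#'
#' Images throughout the package are plain numeric matrices indexed
#' `[row, column]` (row 1 = top of the image) holding 8-bit intensities
#' in `[0, 255]`.
#'
#' @param x object to check.
#' @param name label used in error messages.
#' @return `x`, invisibly.
#' @keywords internal
assert_gray <- function(x, name = "image") {
  assert_that(is.matrix(x) && is.numeric(x), sprintf("%s must be a numeric matrix", name))
  assert_that(nrow(x) > 0 && ncol(x) > 0, sprintf("%s must have positive dimensions", name))
  rng <- range(x)
  assert_that(is.finite(rng[1]) && rng[1] >= 0 && rng[2] <= 255,
              sprintf("%s intensities must lie in [0, 255]", name))
  invisible(x)
}

#' @keywords internal
assert_mask <- function(x, name = "mask", shape_of = NULL) {
  assert_that(is.matrix(x) && is.numeric(x), sprintf("%s must be a numeric matrix", name))
  assert_that(all(x %in% c(0, 1)), sprintf("%s must contain only 0/1 values", name))
  if (!is.null(shape_of)) {
    assert_that(all(dim(x) == dim(shape_of)),
                sprintf("%s shape %dx%d does not match image shape %dx%d",
                        name, nrow(x), ncol(x), nrow(shape_of), ncol(shape_of)))
  }
  invisible(x)
}

# Clamp to [0,255]; matrix-first so dims survive.
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# Matrix [h,w] <-> EBImage Image (x = columns first).
as_ebi <- function(mat) EBImage::Image(t(mat) / 255)
from_ebi <- function(img) {
  m <- t(EBImage::imageData(img)) * 255
  clamp255(m)
}

# Derive a per-item 31-bit seed from a base seed; deterministic and collision
# free for the stream sizes used here.
derive_seed <- function(seed, stream, index = 0L) {
  s <- (as.numeric(seed) * 48271 + stream * 16807 + index) %% 2147483629
  as.integer(s) + 1L
}
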