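#' Load an image as 8-bit grayscale
#'
#' Reads a PNG or JPEG file and returns a grayscale intensity matrix in
#' `[0, 255]`. Colour inputs are reduced by ITU-R BT.601 luma weighting
#' (0.299 R + 0.587 G + 0.114 B), rounded to the nearest integer; an alpha
#' channel, if present, is ignored. Single-channel inputs pass through
#' unchanged.
#'
#' @param path path to a `.png`, `.jpg` or `.jpeg` file.
#' @return numeric matrix `[height, width]` with integer values in `[0, 255]`.
#' @examples
#' f <- tempfile(fileext = ".png")
#' write_grayscale(matrix(200, 10, 10), f)
#' img <- load_grayscale(f)
#' stopifnot(all(img == 200))
#' @export
load_grayscale <- function(path) {
  assert_that(is.character(path) && length(path) == 1, "path must be a single string")
  assert_that(file.exists(path), sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  arr <- tryCatch(
    switch(ext,
           png = png::readPNG(path),
           jpg = ,
           jpeg = jpeg::readJPEG(path),
           stop(sprintf("unsupported image format '%s' (PNG/JPG only): %s", ext, path),
                call. = FALSE)),
    error = function(e) stop(sprintf("cannot decode image %s: %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc >= 3) {
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  assert_that(length(arr) > 0 && nrow(arr) > 0 && ncol(arr) > 0,
              sprintf("zero-size image: %s", path))
  m <- round(arr * 255)
  assert_gray(m, path)
  m
}

#' Write a grayscale image (or binary mask) as PNG
#'
#' PNG is lossless, so `load_grayscale(write_grayscale(x))` round-trips
#' exactly. Masks in `{0,1}` are written as `{0,255}` when `as_mask = TRUE`.
#'
#' @param image numeric matrix in `[0, 255]` (or `{0,1}` with `as_mask`).
#' @param path output path.
#' @param as_mask scale `{0,1}` to `{0,255}` before writing.
#' @return `path`, invisibly.
#' @export
write_grayscale <- function(image, path, as_mask = FALSE) {
  if (as_mask) {
    assert_mask(image)
    image <- image * 255
  }
  assert_gray(image)
  png::writePNG(image / 255, target = path)
  invisible(path)
}

#' Resize a grayscale image
#'
#' Bilinear interpolation is the default for image content; use `nearest`
#' for binary masks so values never leave `{0,1}`.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param height,width positive target dimensions.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return resized matrix, intensities clamped to `[0, 255]` and rounded.
#' @export
resize_to <- function(image, height, width, interpolation = c("bilinear", "nearest")) {
  assert_gray(image)
  interpolation <- match.arg(interpolation)
  assert_that(height >= 1 && width >= 1, "target dimensions must be positive")
  if (nrow(image) == height && ncol(image) == width) return(image)
  filt <- if (interpolation == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(as_ebi(image), w = width, h = height, filter = filt)
  round(from_ebi(out))
}

#' Convert an image to the backbone input tensor
#'
#' Resizes to 224x224 (bilinear) and replicates the grayscale plane across
#' three identical channels, matching the input interface of ImageNet-style
#' convolutional backbones.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @return array `[224, 224, 3]`, all channels equal.
#' @export
to_backbone_input <- function(image) {
  assert_gray(image)
  m <- resize_to(image, 224L, 224L, "bilinear")
  array(rep(m, 3), dim = c(224L, 224L, 3L))
}
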