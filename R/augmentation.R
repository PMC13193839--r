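#' Training-time augmentation settings
#'
#' Mild geometric transforms applied to the training stream only: rotation
#' drawn uniformly from `rotation_deg`, translation up to
#' `shift_fraction` of each side (uniform, signed), x-shear from `shear_rad`,
#' isotropic zoom from `zoom`, and independent fair-coin horizontal/vertical
#' flips when enabled. Empty pixels created by a transform are filled by
#' nearest-edge replication.
#'
#' @param rotation_deg rotation range in degrees.
#' @param shift_fraction maximum absolute translation as a fraction of the
#'   image side, in `[0, 1)`.
#' @param shear_rad x-shear range in radians.
#' @param zoom zoom range; must contain 1.
#' @param hflip,vflip enable horizontal / vertical flips.
#' @return an `augment_config` list.
#' @export
augment_config <- function(rotation_deg = c(0, 30),
                           shift_fraction = 0.25,
                           shear_rad = c(0, 0.5),
                           zoom = c(0.975, 1.025),
                           hflip = TRUE,
                           vflip = TRUE) {
  assert_that(shift_fraction >= 0 && shift_fraction < 1,
              "shift_fraction must lie in [0, 1)")
  assert_that(zoom[1] <= 1 && zoom[2] >= 1, "zoom range must contain 1.0")
  cfg <- list(rotation_deg = rotation_deg, shift_fraction = shift_fraction,
              shear_rad = shear_rad, zoom = zoom, hflip = hflip, vflip = vflip)
  class(cfg) <- "augment_config"
  cfg
}

#' Augmentation configuration with every range collapsed to the identity
#' @return an `augment_config` producing only identity transforms.
#' @export
augment_off <- function() {
  augment_config(rotation_deg = c(0, 0), shift_fraction = 0,
                 shear_rad = c(0, 0), zoom = c(1, 1), hflip = FALSE, vflip = FALSE)
}

#' Draw one random transform
#'
#' Each parameter is drawn uniformly from its configured range using the
#' current RNG state; flips are independent fair coin flips when enabled.
#'
#' @param config an [augment_config()].
#' @param size image size `c(height, width)` used to convert the shift
#'   fraction to pixel offsets.
#' @return a `transform_sample` list with fields `angle` (degrees), `dx`,
#'   `dy` (pixel offsets along width / height), `shear` (radians), `scale`,
#'   `do_hflip`, `do_vflip`.
#' @export
sample_transform <- function(config = augment_config(), size = c(224L, 224L)) {
  t <- list(
    angle = stats::runif(1, config$rotation_deg[1], config$rotation_deg[2]),
    dx = stats::runif(1, -1, 1) * config$shift_fraction * size[2],
    dy = stats::runif(1, -1, 1) * config$shift_fraction * size[1],
    shear = stats::runif(1, config$shear_rad[1], config$shear_rad[2]),
    scale = stats::runif(1, config$zoom[1], config$zoom[2]),
    do_hflip = config$hflip && stats::runif(1) < 0.5,
    do_vflip = config$vflip && stats::runif(1) < 0.5
  )
  class(t) <- "transform_sample"
  t
}

#' The identity transform
#' @return a `transform_sample` that maps every image to itself.
#' @export
identity_transform <- function() {
  t <- list(angle = 0, dx = 0, dy = 0, shear = 0, scale = 1,
            do_hflip = FALSE, do_vflip = FALSE)
  class(t) <- "transform_sample"
  t
}

#' Apply an affine transform to a grayscale image
#'
#' Applies, about the image centre and in this fixed order: rotation, x-shear,
#' isotropic zoom, translation, then the optional flips. Implemented by
#' inverse mapping; source coordinates falling outside the frame are clamped
#' to the nearest edge pixel (nearest-edge replication fill). Image content is
#' interpolated bilinearly by default; `"nearest"` keeps values from the
#' input set (use it for masks and invertibility checks).
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param t a `transform_sample`.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return transformed image, same shape, integer intensities in `[0, 255]`.
#' @export
apply_transform <- function(image, t, interpolation = c("bilinear", "nearest")) {
  assert_gray(image)
  interpolation <- match.arg(interpolation)
  h <- nrow(image); w <- ncol(image)
  if (t$angle == 0 && t$dx == 0 && t$dy == 0 && t$shear == 0 && t$scale == 1 &&
      !t$do_hflip && !t$do_vflip) {
    return(image)
  }
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  # forward maps in centred (x=col, y=row) coordinates
  a <- t$angle * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  Sh <- matrix(c(1, 0, tan(t$shear), 1), 2, 2)        # x' = x + tan(shear) * y
  Z <- diag(c(t$scale, t$scale))
  Fl <- diag(c(if (t$do_hflip) -1 else 1, if (t$do_vflip) -1 else 1))
  A <- Fl %*% Z %*% Sh %*% Rm                          # rotate->shear->zoom->(shift)->flips
  b <- Fl %*% c(t$dx, t$dy)
  Ai <- solve(A)
  # output pixel grid -> source coordinates
  xo <- matrix(rep(seq_len(w), each = h), h, w) - cx
  yo <- matrix(rep(seq_len(h), w), h, w) - cy
  xs <- Ai[1, 1] * (xo - b[1]) + Ai[1, 2] * (yo - b[2]) + cx
  ys <- Ai[2, 1] * (xo - b[1]) + Ai[2, 2] * (yo - b[2]) + cy
  # nearest-edge replication fill
  xs <- pmin(pmax(xs, 1), w)
  ys <- pmin(pmax(ys, 1), h)
  if (interpolation == "nearest") {
    out <- image[cbind(as.vector(round(ys)), as.vector(round(xs)))]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
    fx <- xs - x0; fy <- ys - y0
    g <- function(r, c) image[cbind(as.vector(r), as.vector(c))]
    out <- (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x1) +
      (1 - fx) * fy * g(y1, x0) + fx * fy * g(y1, x1)
  }
  matrix(round(clamp255(out)), h, w)
}

#' Invert a transform sample
#'
#' Exact inverse of the affine part; only defined when both flips are off.
#' Useful for round-trip checks of the warp.
#'
#' @param t a `transform_sample` with `do_hflip = do_vflip = FALSE`.
#' @return an `affine_raw` object encoding the exact inverse map, to be
#'   applied with [apply_affine_raw()].
#' @export
invert_transform <- function(t) {
  assert_that(!t$do_hflip && !t$do_vflip, "only flip-free transforms are invertible here")
  a <- t$angle * pi / 180
  Rm <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  Sh <- matrix(c(1, 0, tan(t$shear), 1), 2, 2)
  Z <- diag(c(t$scale, t$scale))
  A <- Z %*% Sh %*% Rm
  # a general inverse is not expressible as a transform_sample (the inverse
  # of rotate->shear->zoom is not in that family), so return the raw map
  inv <- list(A = solve(A), b = -solve(A) %*% c(t$dx, t$dy))
  class(inv) <- "affine_raw"
  inv
}

#' Apply a raw affine map (as produced by [invert_transform()])
#' @param image grayscale matrix.
#' @param aff an `affine_raw` object.
#' @param interpolation `"bilinear"` or `"nearest"`.
#' @return transformed image.
#' @export
apply_affine_raw <- function(image, aff, interpolation = c("bilinear", "nearest")) {
  assert_gray(image)
  interpolation <- match.arg(interpolation)
  h <- nrow(image); w <- ncol(image)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  Ai <- solve(aff$A)
  bi <- aff$b
  xo <- matrix(rep(seq_len(w), each = h), h, w) - cx
  yo <- matrix(rep(seq_len(h), w), h, w) - cy
  xs <- Ai[1, 1] * (xo - bi[1]) + Ai[1, 2] * (yo - bi[2]) + cx
  ys <- Ai[2, 1] * (xo - bi[1]) + Ai[2, 2] * (yo - bi[2]) + cy
  xs <- pmin(pmax(xs, 1), w)
  ys <- pmin(pmax(ys, 1), h)
  if (interpolation == "nearest") {
    out <- image[cbind(as.vector(round(ys)), as.vector(round(xs)))]
  } else {
    x0 <- floor(xs); y0 <- floor(ys)
    x1 <- pmin(x0 + 1, w); y1 <- pmin(y0 + 1, h)
    fx <- xs - x0; fy <- ys - y0
    g <- function(r, c) image[cbind(as.vector(r), as.vector(c))]
    out <- (1 - fx) * (1 - fy) * g(y0, x0) + fx * (1 - fy) * g(y0, x1) +
      (1 - fx) * fy * g(y1, x0) + fx * fy * g(y1, x1)
  }
  matrix(round(clamp255(out)), h, w)
}
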