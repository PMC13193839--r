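#' Phantom generator settings
#'
#' Describes the synthetic axial lung-CT phantom: a dark background, a brighter
#' body ellipse, two low-intensity lung fields placed symmetrically about the
#' vertical midline (with seeded jitter), and a class-dependent nodule rendered
#' inside one lung. Benign nodules are small, circular and well circumscribed;
#' malignant nodules are larger with an irregular margin produced by seeded
#' low-frequency radial perturbation; normal phantoms carry no nodule.
#'
#' Intensity means are ordered background < lung < nodule < body so that
#' air-filled lungs binarise as dark foreground and the below-140 candidate
#' rule retains nodules while excluding the body wall.
#'
#' @param image_size side length in pixels.
#' @param body_intensity,lung_intensity,background_intensity,nodule_intensity
#'   mean intensities in `[0, 255]`.
#' @param noise_sd standard deviation of additive Gaussian intensity noise
#'   (clipped to `[0, 255]` after addition).
#' @param benign_nodule_radius,malignant_nodule_radius radius ranges in pixels.
#' @param malignant_irregularity relative amplitude of the radial margin
#'   perturbation of malignant nodules.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(image_size = 512L,
                         body_intensity = 180,
                         lung_intensity = 40,
                         background_intensity = 10,
                         nodule_intensity = 120,
                         noise_sd = 8,
                         benign_nodule_radius = c(6, 12),
                         malignant_nodule_radius = c(14, 28),
                         malignant_irregularity = 0.35) {
  spec <- list(image_size = as.integer(image_size),
               body_intensity = body_intensity,
               lung_intensity = lung_intensity,
               background_intensity = background_intensity,
               nodule_intensity = nodule_intensity,
               noise_sd = noise_sd,
               benign_nodule_radius = benign_nodule_radius,
               malignant_nodule_radius = malignant_nodule_radius,
               malignant_irregularity = malignant_irregularity)
  assert_that(spec$image_size >= 64, "image_size must be at least 64")
  ok <- background_intensity < lung_intensity &&
    lung_intensity < nodule_intensity && nodule_intensity < body_intensity
  assert_that(ok, "intensity means must be ordered background < lung < nodule < body")
  assert_that(all(diff(benign_nodule_radius) >= 0) && all(diff(malignant_nodule_radius) >= 0),
              "nodule radius ranges must be non-decreasing")
  class(spec) <- "phantom_spec"
  spec
}

# Ellipse membership helper on pixel-centre coordinates.
ellipse_mask <- function(size, cx, cy, rx, ry) {
  xx <- matrix(rep(seq_len(size), each = size), size, size)
  yy <- matrix(rep(seq_len(size), size), size, size)
  ((xx - cx) / rx)^2 + ((yy - cy) / ry)^2 <= 1
}

#' Generate one synthetic lung-CT phantom
#'
#' Deterministic for a fixed `(spec, label, seed)` triple. Ground-truth lung
#' and nodule masks are returned alongside the rendered image; the nodule mask
#' is always a subset of the lung mask and is empty exactly for `"Normal"`.
#'
#' @param spec a [phantom_spec()].
#' @param label one of `"Benign"`, `"Malignant"`, `"Normal"`.
#' @param seed integer RNG seed.
#' @return a `phantom_record` list with elements `image`, `label`,
#'   `lung_mask`, `nodule_mask`.
#' @export
generate_phantom <- function(spec = phantom_spec(), label, seed) {
  assert_that(inherits(spec, "phantom_spec"), "spec must be a phantom_spec")
  assert_that(label %in% LUNG_CLASSES,
              sprintf("label must be one of %s", paste(LUNG_CLASSES, collapse = ", ")))
  s <- spec$image_size
  withr::with_seed(as.integer(seed), {
    jit <- function(scale) stats::runif(1, -scale, scale)
    cx <- s / 2 + jit(0.02 * s)
    cy <- s / 2 + jit(0.02 * s)
    body_rx <- 0.39 * s * (1 + jit(0.04))
    body_ry <- 0.45 * s * (1 + jit(0.04))
    lung_ry <- 0.27 * s * (1 + jit(0.05))
    lung_rx <- 0.155 * s * (1 + jit(0.05))
    lung_off <- 0.19 * s * (1 + jit(0.05))

    body <- ellipse_mask(s, cx, cy, body_rx, body_ry)
    lungL <- ellipse_mask(s, cx - lung_off, cy, lung_rx, lung_ry)
    lungR <- ellipse_mask(s, cx + lung_off, cy, lung_rx, lung_ry)
    lung <- (lungL | lungR) & body

    img <- matrix(spec$background_intensity, s, s)
    img[body] <- spec$body_intensity
    img[lung] <- spec$lung_intensity

    nodule <- matrix(FALSE, s, s)
    if (label != "Normal") {
      rng <- if (label == "Benign") spec$benign_nodule_radius else spec$malignant_nodule_radius
      r0 <- stats::runif(1, rng[1], rng[2])
      assert_that(max(rng) < lung_rx,
                  "nodule radius range exceeds the lung ellipse minor axis")
      # nodule centre inside the left or right lung ellipse, shrunk so the
      # whole nodule (including margin perturbation) stays inside the lung
      side <- sample(c(-1, 1), 1)
      lcx <- cx + side * lung_off
      shrink_x <- max(lung_rx - 1.5 * r0, 1)
      shrink_y <- max(lung_ry - 1.5 * r0, 1)
      repeat {
        u <- stats::runif(1, -1, 1); v <- stats::runif(1, -1, 1)
        if (u^2 + v^2 <= 1) break
      }
      ncx <- lcx + u * shrink_x
      ncy <- cy + v * shrink_y

      xx <- matrix(rep(seq_len(s), each = s), s, s)
      yy <- matrix(rep(seq_len(s), s), s, s)
      dx <- xx - ncx; dy <- yy - ncy
      dist <- sqrt(dx^2 + dy^2)
      if (label == "Malignant") {
        # irregular margin: low-frequency sinusoidal perturbation of the radius
        theta <- atan2(dy, dx)
        k <- sample(2:5, 3, replace = TRUE)
        ph <- stats::runif(3, 0, 2 * pi)
        amp <- stats::runif(3, 0.3, 1)
        pert <- amp[1] * sin(k[1] * theta + ph[1]) +
          amp[2] * sin(k[2] * theta + ph[2]) +
          amp[3] * sin(k[3] * theta + ph[3])
        pert <- pert / max(abs(pert))
        rtheta <- r0 * (1 + spec$malignant_irregularity * pert)
      } else {
        rtheta <- r0
      }
      nodule <- (dist <= rtheta) & lung
      img[nodule] <- spec$nodule_intensity
    }

    noise <- matrix(stats::rnorm(s * s, 0, spec$noise_sd), s, s)
    img <- round(clamp255(img + noise))

    rec <- list(image = img,
                label = label,
                lung_mask = matrix(as.numeric(lung), s, s),
                nodule_mask = matrix(as.numeric(nodule), s, s))
    class(rec) <- "phantom_record"
    rec
  })
}

#' Generate a phantom set in memory
#'
#' Convenience wrapper producing `n_per_class` phantom records per class with
#' per-record seeds derived deterministically from `seed`.
#'
#' @inheritParams generate_phantom
#' @param n_per_class records per class.
#' @return list of `phantom_record`s, classes interleaved deterministically.
#' @export
generate_phantom_set <- function(spec = phantom_spec(), n_per_class, seed) {
  assert_that(n_per_class >= 1, "n_per_class must be at least 1")
  recs <- list()
  for (ci in seq_along(LUNG_CLASSES)) {
    for (k in seq_len(n_per_class)) {
      recs[[length(recs) + 1L]] <-
        generate_phantom(spec, LUNG_CLASSES[ci], derive_seed(seed, ci, k))
    }
  }
  recs
}

# Class sizes for generate_dataset: either n per class, or the reference
# dataset's 530/536/534 composition (1,600 images).
emulated_class_counts <- function(n_per_class, emulate_paper_counts) {
  if (emulate_paper_counts) {
    c(Benign = 530L, Malignant = 536L, Normal = 534L)
  } else {
    assert_that(n_per_class >= 1, "n_per_class must be at least 1")
    stats::setNames(rep(as.integer(n_per_class), 3), LUNG_CLASSES)
  }
}

#' Generate a phantom dataset on disk
#'
#' Writes class-labelled PNGs under `<out_dir>/<Class>/img_<k>.png` with
#' ground-truth masks under `<out_dir>/truth/<Class>/img_<k>_lung.png` and
#' `..._nodule.png`, and returns the corresponding manifest.
#'
#' @inheritParams generate_phantom_set
#' @param out_dir output directory (created if missing).
#' @param emulate_paper_counts if `TRUE`, ignore `n_per_class` and write the
#'   reference class sizes 530/536/534 (1,600 images total).
#' @return a manifest tibble (`path`, `label`, `split = "unsplit"`).
#' @export
generate_dataset <- function(spec = phantom_spec(), n_per_class, seed, out_dir,
                             emulate_paper_counts = FALSE) {
  counts <- emulated_class_counts(n_per_class, emulate_paper_counts)
  ok <- dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  assert_that(dir.exists(out_dir), sprintf("cannot create output directory %s", out_dir))
  paths <- character(0); labels <- character(0)
  for (ci in seq_along(LUNG_CLASSES)) {
    cl <- LUNG_CLASSES[ci]
    dir.create(file.path(out_dir, cl), showWarnings = FALSE, recursive = TRUE)
    dir.create(file.path(out_dir, "truth", cl), showWarnings = FALSE, recursive = TRUE)
    for (k in seq_len(counts[[cl]])) {
      rec <- generate_phantom(spec, cl, derive_seed(seed, ci, k))
      p <- file.path(out_dir, cl, sprintf("img_%04d.png", k))
      write_grayscale(rec$image, p)
      write_grayscale(rec$lung_mask, file.path(out_dir, "truth", cl,
                                               sprintf("img_%04d_lung.png", k)), as_mask = TRUE)
      write_grayscale(rec$nodule_mask, file.path(out_dir, "truth", cl,
                                                 sprintf("img_%04d_nodule.png", k)), as_mask = TRUE)
      paths <- c(paths, p); labels <- c(labels, cl)
    }
  }
  tibble::tibble(path = paths, label = labels, split = "unsplit")
}
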