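#' Lung-field segmentation parameters
#'
#' Parameters of the segmentation pipeline: CLAHE enhancement, fixed-threshold
#' binarisation (dark-foreground polarity: air-filled lungs are low intensity),
#' morphological refinement with disk structuring elements
#' (closing -> erosion -> larger closing), edge-guided hole filling and
#' component selection.
#'
#' The threshold, CLAHE settings and disk radii are configurable; defaults
#' follow common practice (clip limit 2.0, 8x8 tiles, threshold 128, disks
#' 3/2/7 preserving the closing < closing ordering).
#'
#' @param clahe_clip_limit CLAHE contrast clip limit (> 0).
#' @param clahe_tile_grid tiles per image side.
#' @param binarize_threshold fixed intensity threshold in `[0, 255]`.
#' @param lungs_are_dark if `TRUE` (default) pixels strictly below the
#'   threshold become foreground.
#' @param close1_radius,erode_radius,close2_radius disk radii in pixels;
#'   `close2_radius` must exceed `close1_radius`.
#' @param edge_method `"canny"` or `"sobel"`.
#' @param canny_low,canny_high hysteresis thresholds on gradient magnitude.
#' @param min_component_area smallest retained component, in pixels.
#' @param border_exclusion drop components touching the image border.
#' @param max_hole_fraction largest interior hole (as a fraction of the image
#'   area) that `edge_fill` will fill. Caps filling at nodule/vessel scale so
#'   that the enclosed body wall — a large zero-region of the dark-polarity
#'   mask — is not flooded.
#' @param use_enhanced_for_output if `TRUE`, the final mask is applied to the
#'   CLAHE-enhanced image instead of the raw input.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(clahe_clip_limit = 2.0,
                                clahe_tile_grid = 8L,
                                binarize_threshold = 128,
                                lungs_are_dark = TRUE,
                                close1_radius = 3L,
                                erode_radius = 2L,
                                close2_radius = 7L,
                                edge_method = c("canny", "sobel"),
                                canny_low = 50,
                                canny_high = 150,
                                min_component_area = 500L,
                                border_exclusion = TRUE,
                                max_hole_fraction = 0.05,
                                use_enhanced_for_output = FALSE) {
  p <- list(clahe_clip_limit = clahe_clip_limit,
            clahe_tile_grid = as.integer(clahe_tile_grid),
            binarize_threshold = binarize_threshold,
            lungs_are_dark = lungs_are_dark,
            close1_radius = as.integer(close1_radius),
            erode_radius = as.integer(erode_radius),
            close2_radius = as.integer(close2_radius),
            edge_method = match.arg(edge_method),
            canny_low = canny_low,
            canny_high = canny_high,
            min_component_area = as.integer(min_component_area),
            border_exclusion = border_exclusion,
            max_hole_fraction = max_hole_fraction,
            use_enhanced_for_output = use_enhanced_for_output)
  assert_that(p$clahe_clip_limit > 0, "clahe_clip_limit must be positive")
  assert_that(p$binarize_threshold >= 0 && p$binarize_threshold <= 255,
              "binarize_threshold must lie in [0, 255]")
  assert_that(p$close2_radius > p$close1_radius,
              "close2_radius must exceed close1_radius (second closing uses the larger disk)")
  assert_that(p$max_hole_fraction > 0 && p$max_hole_fraction < 1,
              "max_hole_fraction must lie in (0, 1)")
  class(p) <- "segmentation_params"
  p
}

disk_kernel <- function(radius) EBImage::makeBrush(2L * as.integer(radius) + 1L, shape = "disc")

#' Contrast-limited adaptive histogram equalisation
#'
#' Applies CLAHE tile-wise with the configured clip limit. Images whose sides
#' are not multiples of the tile grid are edge-padded to the next multiple and
#' cropped back after equalisation.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param params a [segmentation_params()].
#' @return enhanced image matrix in `[0, 255]`.
#' @export
apply_clahe <- function(image, params = segmentation_params()) {
  assert_gray(image)
  g <- params$clahe_tile_grid
  h <- nrow(image); w <- ncol(image)
  assert_that(g <= h && g <= w, "CLAHE tile grid is larger than the image")
  ph <- ceiling(h / g) * g
  pw <- ceiling(w / g) * g
  padded <- image
  if (ph > h) padded <- padded[c(seq_len(h), rep(h, ph - h)), , drop = FALSE]
  if (pw > w) padded <- padded[, c(seq_len(w), rep(w, pw - w)), drop = FALSE]
  out <- EBImage::clahe(as_ebi(padded), nx = g, ny = g,
                        limit = params$clahe_clip_limit)
  res <- round(from_ebi(out))
  res[seq_len(h), seq_len(w), drop = FALSE]
}

#' Fixed-threshold binarisation
#'
#' With `lungs_are_dark` (the default) a pixel becomes foreground iff its
#' intensity is strictly below the threshold; with the flag off, iff it is
#' greater than or equal to the threshold.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param threshold intensity threshold in `[0, 255]`.
#' @param lungs_are_dark polarity flag.
#' @return binary mask matrix.
#' @export
binarize <- function(image, threshold = 128, lungs_are_dark = TRUE) {
  assert_gray(image)
  assert_that(threshold >= 0 && threshold <= 255, "threshold must lie in [0, 255]")
  m <- if (lungs_are_dark) image < threshold else image >= threshold
  matrix(as.numeric(m), nrow(image), ncol(image))
}

#' Morphological mask refinement
#'
#' Applies, in order: closing with a small disk (bridges small gaps), erosion
#' (detaches spurious attachments), and closing with a larger disk (re-seals
#' discontinuities introduced by the erosion).
#'
#' @param mask binary matrix.
#' @param params a [segmentation_params()].
#' @return refined binary mask of the same shape.
#' @export
refine_mask <- function(mask, params = segmentation_params()) {
  assert_mask(mask)
  half <- min(dim(mask)) / 2
  assert_that(max(params$close1_radius, params$erode_radius, params$close2_radius) < half,
              "structuring-element radius must be below half the image side")
  x <- EBImage::Image(t(mask))
  x <- EBImage::closing(x, disk_kernel(params$close1_radius))
  x <- EBImage::erode(x, disk_kernel(params$erode_radius))
  x <- EBImage::closing(x, disk_kernel(params$close2_radius))
  matrix(as.numeric(t(EBImage::imageData(x)) > 0.5), nrow(mask), ncol(mask))
}

# Replicate-boundary 2-D correlation with a small kernel.
filter_replicate <- function(image, kern) {
  EBImage::imageData(EBImage::filter2(EBImage::Image(image), kern, boundary = "replicate"))
}

#' Edge detection on a grayscale image
#'
#' `"canny"` (default): Gaussian smoothing, Sobel gradients, non-maximum
#' suppression along the quantised gradient direction, then hysteresis
#' thresholding (weak-edge components are kept only when they contain a strong
#' pixel). `"sobel"`: gradient magnitude thresholded at `canny_high`.
#' Thresholds apply to the Sobel gradient magnitude of the 8-bit image.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param params a [segmentation_params()].
#' @return binary edge mask.
#' @export
detect_edges <- function(image, params = segmentation_params()) {
  assert_gray(image)
  h <- nrow(image); w <- ncol(image)
  gk <- outer(stats::dnorm(-2:2, sd = 1.2), stats::dnorm(-2:2, sd = 1.2))
  gk <- gk / sum(gk)
  sm <- filter_replicate(image, gk)
  sx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)  # d/drow
  sy <- t(sx)                                          # d/dcol
  gx <- filter_replicate(sm, sx)
  gy <- filter_replicate(sm, sy)
  mag <- sqrt(gx^2 + gy^2)
  if (params$edge_method == "sobel") {
    return(matrix(as.numeric(mag >= params$canny_high), h, w))
  }
  # non-maximum suppression: compare each pixel against its two neighbours
  # along the quantised gradient direction
  ang <- atan2(gy, gx)
  ang[ang < 0] <- ang[ang < 0] + pi
  sector <- findInterval(ang, c(pi / 8, 3 * pi / 8, 5 * pi / 8, 7 * pi / 8)) %% 4
  shift <- function(m, dr, dc) {
    out <- matrix(-Inf, h, w)
    rs <- seq_len(h) + dr; cs <- seq_len(w) + dc
    ok_r <- rs >= 1 & rs <= h; ok_c <- cs >= 1 & cs <= w
    out[ok_r, ok_c] <- m[rs[ok_r], cs[ok_c]]
    out
  }
  # gx varies along columns, gy along rows; sector 0 means gradient along the
  # column axis, sector 2 along the row axis, 1 and 3 the two diagonals
  nb <- list(`0` = list(c(0, 1), c(0, -1)),
             `1` = list(c(1, 1), c(-1, -1)),
             `2` = list(c(1, 0), c(-1, 0)),
             `3` = list(c(1, -1), c(-1, 1)))
  nms <- matrix(0, h, w)
  for (s in 0:3) {
    sel <- sector == s
    if (!any(sel)) next
    n1 <- shift(mag, nb[[as.character(s)]][[1]][1], nb[[as.character(s)]][[1]][2])
    n2 <- shift(mag, nb[[as.character(s)]][[2]][1], nb[[as.character(s)]][[2]][2])
    keep <- sel & mag >= n1 & mag >= n2
    nms[keep] <- mag[keep]
  }
  weak <- nms >= params$canny_low
  strong <- nms >= params$canny_high
  if (!any(strong)) return(matrix(0, h, w))
  lab <- EBImage::bwlabel(EBImage::Image(t(weak)))
  lab <- t(EBImage::imageData(lab))
  keep_labels <- unique(lab[strong])
  keep_labels <- keep_labels[keep_labels > 0]
  matrix(as.numeric(lab %in% keep_labels), h, w)
}

# Interior holes: background components not connected to the image border.
# Returns a logical matrix of hole pixels with component area <= max area.
interior_holes <- function(mask, max_area = Inf) {
  bg <- 1 - mask
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(bg)))))
  if (max(lab) == 0) return(matrix(FALSE, nrow(mask), ncol(mask)))
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  hole_ids <- setdiff(seq_len(max(lab)), border_labels)
  hole_ids <- hole_ids[areas[hole_ids] <= max_area]
  matrix(lab %in% hole_ids, nrow(mask), ncol(mask))
}

#' Edge-guided hole filling
#'
#' Fills interior holes of the mask — background regions not connected to
#' the image border — using the detected edges of the (enhanced) image to
#' seal boundary leaks: holes are identified on the union of the mask with
#' the edge map, so a cavity whose rim is breached but traced by an edge
#' still counts as interior. Only the hole pixels are added to the output;
#' the edge pixels themselves are not, so thin edge chains can never bridge
#' separate components (which would corrupt downstream component
#' selection). Filling is capped at `max_hole_fraction` of the image area.
#' The operation is extensive (output contains the input) and idempotent.
#'
#' @param mask binary matrix.
#' @param image grayscale image of the same shape (typically the CLAHE output).
#' @param params a [segmentation_params()].
#' @return binary mask with interior holes filled.
#' @export
edge_fill <- function(mask, image, params = segmentation_params()) {
  assert_mask(mask)
  assert_gray(image)
  assert_mask(mask, shape_of = image)
  edges <- detect_edges(image, params)
  out <- mask
  cap <- params$max_hole_fraction * length(mask)
  # Two hole notions are combined: plain interior holes of the mask, and
  # holes of the edge-sealed mask (cavities whose rim is breached in the
  # mask but traced closed by an edge). Filling a sealed-mask hole can
  # leave its edge ring as a new plain hole, so iterate to a fixpoint.
  repeat {
    sealed <- matrix(as.numeric(out + edges > 0), nrow(out), ncol(out))
    holes <- (interior_holes(out, max_area = cap) |
                interior_holes(sealed, max_area = cap)) & out == 0
    if (!any(holes)) break
    out[holes] <- 1
  }
  out
}

#' Select lung-field components
#'
#' Keeps up to the two largest connected components with area at least
#' `min_component_area`, excluding components that touch the image border when
#' `border_exclusion` is on (the two air-filled lung fields of an axial slice
#' are interior blobs; the surrounding dark background touches the border).
#'
#' @param mask binary matrix.
#' @param params a [segmentation_params()].
#' @return binary mask containing the selected components (possibly empty).
#' @export
select_lung_components <- function(mask, params = segmentation_params()) {
  assert_mask(mask)
  lab <- t(EBImage::imageData(EBImage::bwlabel(EBImage::Image(t(mask)))))
  n <- max(lab)
  if (n == 0) return(mask * 0)
  areas <- tabulate(lab[lab > 0], nbins = n)
  cand <- seq_len(n)
  if (params$border_exclusion) {
    border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    cand <- setdiff(cand, border_labels)
  }
  cand <- cand[areas[cand] >= params$min_component_area]
  if (length(cand) == 0) return(mask * 0)
  keep <- cand[order(areas[cand], decreasing = TRUE)][seq_len(min(2L, length(cand)))]
  matrix(as.numeric(lab %in% keep), nrow(mask), ncol(mask))
}

#' Superimpose a binary mask on an image
#'
#' Elementwise gate: output pixel equals the input pixel where the mask is 1
#' and 0 elsewhere.
#'
#' @param image numeric matrix in `[0, 255]`.
#' @param mask binary matrix of the same shape.
#' @return masked image.
#' @export
apply_mask <- function(image, mask) {
  assert_gray(image)
  assert_mask(mask, shape_of = image)
  image * mask
}

#' Full lung-field segmentation pipeline
#'
#' Composition `apply_clahe` -> `binarize` -> `refine_mask` -> `edge_fill` ->
#' `select_lung_components` -> `apply_mask`. If the final mask is empty a
#' warning is raised and the masked image is all zeros; the pipeline
#' continues so that downstream stages (and ablations) still run.
#'
#' @param image grayscale matrix, conventionally 512x512.
#' @param params a [segmentation_params()].
#' @return list with elements `image` (masked image) and `mask` (final
#'   binary lung mask).
#' @export
segment_lungs <- function(image, params = segmentation_params()) {
  assert_gray(image)
  enhanced <- apply_clahe(image, params)
  m <- binarize(enhanced, params$binarize_threshold, params$lungs_are_dark)
  m <- refine_mask(m, params)
  m <- edge_fill(m, enhanced, params)
  m <- select_lung_components(m, params)
  if (sum(m) == 0) warning("segmentation produced an empty lung mask", call. = FALSE)
  base <- if (params$use_enhanced_for_output) enhanced else image
  list(image = apply_mask(base, m), mask = m)
}
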