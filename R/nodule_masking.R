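#' Nodule-candidate masking parameters
#'
#' The candidate rule marks pixels whose intensity is strictly below
#' `candidate_threshold` (default 140) as potential nodule regions. Because
#' segmentation zeroes everything outside the lung fields — and zeros are
#' trivially below any threshold — the rule is by default restricted to the
#' lung mask and to strictly positive intensities, so the candidate mask
#' describes tissue, not suppressed background.
#'
#' @param candidate_threshold intensity threshold in `(0, 255]`.
#' @param restrict_to_lung require the lung-field mask to be 1.
#' @param exclude_zero_background require intensity strictly above 0.
#' @return a `nodule_mask_params` list.
#' @export
nodule_mask_params <- function(candidate_threshold = 140,
                               restrict_to_lung = TRUE,
                               exclude_zero_background = TRUE) {
  assert_that(candidate_threshold > 0 && candidate_threshold <= 255,
              "candidate_threshold must lie in (0, 255]")
  p <- list(candidate_threshold = candidate_threshold,
            restrict_to_lung = restrict_to_lung,
            exclude_zero_background = exclude_zero_background)
  class(p) <- "nodule_mask_params"
  p
}

#' Nodule-candidate mask
#'
#' A pixel is a candidate iff its intensity is strictly below the threshold,
#' strictly positive (when `exclude_zero_background` is on) and inside the
#' lung mask (when `restrict_to_lung` is on). Raising the threshold never
#' shrinks the mask.
#'
#' @param segmented grayscale matrix (typically the lung-masked image).
#' @param lung_mask binary lung-field mask of the same shape.
#' @param params a [nodule_mask_params()].
#' @return binary candidate mask.
#' @export
candidate_mask <- function(segmented, lung_mask, params = nodule_mask_params()) {
  assert_gray(segmented)
  assert_mask(lung_mask, shape_of = segmented)
  m <- segmented < params$candidate_threshold
  if (params$exclude_zero_background) m <- m & segmented > 0
  if (params$restrict_to_lung) m <- m & lung_mask == 1
  matrix(as.numeric(m), nrow(segmented), ncol(segmented))
}

#' Apply a nodule-candidate mask
#'
#' Elementwise gate: pixels meeting the candidate criterion are retained,
#' all others are set to zero.
#'
#' @param segmented grayscale matrix.
#' @param mask binary mask of the same shape.
#' @return masked image.
#' @export
apply_candidate_mask <- function(segmented, mask) {
  apply_mask(segmented, mask)
}
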