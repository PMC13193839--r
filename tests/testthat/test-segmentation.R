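test_that("CLAHE preserves constants and does not shrink inter-region contrast", {
  p <- segmentation_params(clahe_tile_grid = 4)
  cst <- apply_clahe(matrix(100, 64, 64), p)
  expect_equal(stats::sd(cst), 0)
  expect_true(all(cst >= 0 & cst <= 255))
  # two-region image: the 40-vs-60 gap does not shrink
  two <- matrix(40, 64, 64); two[, 33:64] <- 60
  e <- apply_clahe(two, p)
  gap <- mean(e[, 33:64]) - mean(e[, 1:32])
  expect_gte(gap, 20)
  # local contrast inside a phantom lung increases
  rec <- generate_phantom(phantom_spec(), "Normal", seed = 5)
  enh <- apply_clahe(rec$image, segmentation_params())
  expect_gt(stats::sd(enh[rec$lung_mask == 1]), stats::sd(rec$image[rec$lung_mask == 1]))
  expect_error(apply_clahe(matrix(1, 4, 4), segmentation_params(clahe_tile_grid = 8)),
               "larger than the image")
})

test_that("binarisation uses a strict threshold with dark-foreground polarity", {
  img <- matrix(c(10, 128, 200, 127), 2, 2)  # [[10,200],[128,127]]
  expect_identical(binarize(img, 128, lungs_are_dark = TRUE),
                   matrix(c(1, 0, 0, 1), 2, 2))
  expect_identical(binarize(img, 128, lungs_are_dark = FALSE),
                   matrix(c(0, 1, 1, 0), 2, 2))
  expect_true(all(binarize(matrix(255, 4, 4), 255) == 0))
  # phantom: nearly all true lung pixels are below the default threshold
  rec <- generate_phantom(phantom_spec(), "Normal", seed = 2)
  enh <- apply_clahe(rec$image, segmentation_params())
  m <- binarize(enh, 128)
  expect_gte(mean(m[rec$lung_mask == 1]), 0.95)
})

test_that("morphological refinement closes cracks and shrinks only by the erosion ring", {
  p <- segmentation_params()
  expect_equal(sum(refine_mask(matrix(0, 64, 64), p)), 0)
  # disk with a 1-px crack: refinement bridges it into one component
  cracked <- disk_mask(128, 64, 64, 50)
  cracked[, 64] <- 0
  expect_gt(max(flood_label(cracked)), 1)
  ref <- refine_mask(cracked, p)
  expect_equal(max(flood_label(ref)), 1)
  # solid disk: closings leave it alone, erosion removes roughly a 2-px ring
  solid <- disk_mask(128, 64, 64, 50)
  ref2 <- refine_mask(solid, p)
  expected <- sum(disk_mask(128, 64, 64, 48))
  expect_lt(abs(sum(ref2) - expected) / expected, 0.02)
  expect_error(refine_mask(matrix(0, 10, 10), p), "half the image side")
})

test_that("closing is idempotent for each structuring element", {
  withr::with_seed(3, {
    for (i in 1:3) {
      m <- matrix(as.numeric(matrix(runif(64 * 64), 64) > 0.6), 64, 64)
      for (r in c(2L, 5L)) {
        k <- lungct:::disk_kernel(r)
        once <- EBImage::closing(EBImage::Image(t(m)), k)
        twice <- EBImage::closing(once, k)
        expect_identical(EBImage::imageData(once), EBImage::imageData(twice))
      }
    }
  })
})

test_that("edge_fill fills interior holes, is extensive and idempotent", {
  p <- segmentation_params()
  flat <- matrix(100, 64, 64)  # constant image -> no edges contributed
  sq <- matrix(0, 64, 64); sq[20:44, 20:44] <- 1
  hole <- sq; hole[30:34, 30:34] <- 0
  filled <- edge_fill(hole, flat, p)
  expect_equal(sum(filled) - sum(hole), 25)
  # no holes: output contains input and adds nothing on a flat image
  expect_identical(edge_fill(sq, flat, p), sq)
  # all-ones fixed point
  ones <- matrix(1, 32, 32)
  expect_identical(edge_fill(ones, matrix(0, 32, 32), p), ones)
  # extensive + idempotent on random masks
  withr::with_seed(9, {
    m <- matrix(as.numeric(matrix(runif(64 * 64), 64) > 0.7), 64, 64)
    img <- matrix(round(runif(64 * 64) * 255), 64, 64)
    f1 <- edge_fill(m, img, p)
    expect_true(all(f1 >= m))
    expect_identical(edge_fill(f1, img, p), f1)
  })
})

test_that("hole filling is capped so enclosed anatomy-scale regions are not flooded", {
  p <- segmentation_params()
  big <- matrix(0, 128, 128)
  big[10:118, 10:118] <- 1
  big[30:98, 30:98] <- 0   # 69x69 enclosed region, ~29% of the frame
  out <- edge_fill(big, matrix(100, 128, 128), p)
  expect_identical(out, big)
})

test_that("component selection keeps the two largest interior components", {
  p <- segmentation_params()
  m <- matrix(0, 256, 256)
  m[10:60, 10:109] <- 1    # 51x100 = 5100
  m[100:149, 10:89] <- 1   # 50x80 = 4000
  m[200:223, 10:34] <- 1   # 24x25 = 600
  sel <- select_lung_components(m, p)
  expect_equal(sum(sel), 5100 + 4000)
  # border-touching frame is removed even though it is large
  fr <- matrix(0, 256, 256)
  fr[1, ] <- 1; fr[256, ] <- 1; fr[, 1] <- 1; fr[, 256] <- 1
  fr[50:99, 50:99] <- 1
  fr[150:199, 150:199] <- 1
  sel2 <- select_lung_components(fr, p)
  expect_equal(sum(sel2), 2 * 50 * 50)
  expect_equal(sum(select_lung_components(matrix(0, 64, 64), p)), 0)
})

test_that("mask superposition is an elementwise gate", {
  img <- matrix(c(50, 70, 60, 80), 2, 2)
  expect_identical(apply_mask(img, matrix(1, 2, 2)), img)
  expect_true(all(apply_mask(img, matrix(0, 2, 2)) == 0))
  expect_identical(apply_mask(img, matrix(c(1, 0, 0, 1), 2, 2)),
                   matrix(c(50, 0, 0, 80), 2, 2))
  expect_error(apply_mask(img, matrix(1, 3, 3)), "shape")
})

test_that("the full segmentation recovers phantom lung fields", {
  rec <- generate_phantom(phantom_spec(), "Malignant", seed = 3)
  seg <- segment_lungs(rec$image)
  expect_true(all(seg$mask %in% c(0, 1)))
  expect_equal(dim(seg$mask), dim(rec$image))
  expect_gte(mask_iou(seg$mask, rec$lung_mask), 0.8)
  # masked image is zero exactly outside the final mask
  expect_true(all(seg$image[seg$mask == 0] == 0))
})

test_that("a structureless image yields an empty mask and an all-zero output", {
  expect_warning(seg <- segment_lungs(matrix(90, 512, 512)), "empty lung mask")
  expect_equal(sum(seg$mask), 0)
  expect_true(all(seg$image == 0))
})

test_that("parameter validation enforces the disk-size ordering", {
  expect_error(segmentation_params(close1_radius = 5, close2_radius = 4),
               "close2_radius must exceed")
  expect_error(segmentation_params(binarize_threshold = 300), "\\[0, 255\\]")
})
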