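test_that("phantom records satisfy their structural invariants", {
  for (lab in c("Benign", "Malignant", "Normal")) {
    rec <- generate_phantom(phantom_spec(), lab, seed = 10)
    expect_equal(dim(rec$image), c(512, 512))
    expect_true(all(rec$image >= 0 & rec$image <= 255))
    # nodule mask is inside the lung mask; Normal means empty nodule mask
    expect_true(all(rec$nodule_mask <= rec$lung_mask))
    if (lab == "Normal") {
      expect_equal(sum(rec$nodule_mask), 0)
    } else {
      expect_gt(sum(rec$nodule_mask), 0)
    }
  }
})

test_that("phantom generation is deterministic in (spec, label, seed)", {
  a <- generate_phantom(phantom_spec(), "Benign", seed = 1)
  b <- generate_phantom(phantom_spec(), "Benign", seed = 1)
  expect_identical(a, b)
  c <- generate_phantom(phantom_spec(), "Benign", seed = 2)
  expect_false(identical(a$image, c$image))
})

test_that("malignant nodules are larger than benign nodules at matched seeds", {
  wins <- 0
  for (s in 1:20) {
    ab <- sum(generate_phantom(phantom_spec(), "Benign", seed = s)$nodule_mask)
    am <- sum(generate_phantom(phantom_spec(), "Malignant", seed = s)$nodule_mask)
    if (am > ab) wins <- wins + 1
  }
  expect_equal(wins, 20)
})

test_that("phantom intensity structure supports the downstream thresholds", {
  for (s in 1:5) {
    rec <- generate_phantom(phantom_spec(), "Malignant", seed = s)
    lung <- rec$lung_mask == 1
    # body ring: everything bright enough to be body, outside lungs
    body_ring <- rec$image > 100 & !lung
    expect_lt(mean(rec$image[lung]), mean(rec$image[body_ring]))
    # nodule pixels stay under the candidate threshold
    expect_gt(mean(rec$image[rec$nodule_mask == 1] < 140), 0.9)
  }
})

test_that("nodule radii that cannot fit the lung ellipse are rejected", {
  bad <- phantom_spec(image_size = 128, malignant_nodule_radius = c(30, 40))
  expect_error(generate_phantom(bad, "Malignant", seed = 1), "minor axis")
})

test_that("dataset generation writes class folders, truth masks and an exact manifest", {
  d <- withr::local_tempdir()
  man <- generate_dataset(small_spec(), n_per_class = 3, seed = 7, out_dir = d)
  expect_equal(unname(manifest_counts(man)), c(3L, 3L, 3L))
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(d, "truth", "Benign", "img_0001_lung.png")))
  expect_true(file.exists(file.path(d, "truth", "Normal", "img_0002_nodule.png")))
  # determinism: regenerating produces identical files
  d2 <- withr::local_tempdir()
  man2 <- generate_dataset(small_spec(), n_per_class = 3, seed = 7, out_dir = d2)
  expect_identical(man$label, man2$label)
  f1 <- load_grayscale(man$path[1])
  f2 <- load_grayscale(man2$path[1])
  expect_identical(f1, f2)
})

test_that("paper-count emulation yields the 530/536/534 class sizes", {
  # counts logic exercised without writing 1,600 images
  counts <- lungct:::emulated_class_counts(n_per_class = 534, emulate_paper_counts = TRUE)
  expect_equal(unname(counts), c(530L, 536L, 534L))
  expect_equal(sum(counts), 1600L)
  expect_equal(unname(lungct:::emulated_class_counts(10, FALSE)), rep(10L, 3))
})
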