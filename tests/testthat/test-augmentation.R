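test_that("collapsed ranges produce the identity transform and a bit-identical image", {
  off <- augment_off()
  withr::with_seed(1, t <- sample_transform(off, size = c(64, 64)))
  expect_equal(t$angle, 0)
  expect_equal(t$dx, 0); expect_equal(t$dy, 0)
  expect_equal(t$shear, 0); expect_equal(t$scale, 1)
  expect_false(t$do_hflip); expect_false(t$do_vflip)
  m <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  expect_identical(apply_transform(m, t), m)
})

test_that("transform sampling is deterministic under a fixed seed", {
  cfg <- augment_config()
  withr::with_seed(5, a <- replicate(10, sample_transform(cfg), simplify = FALSE))
  withr::with_seed(5, b <- replicate(10, sample_transform(cfg), simplify = FALSE))
  expect_identical(a, b)
})

test_that("sampled parameters are uniform over their configured ranges", {
  cfg <- augment_config()
  withr::with_seed(11, {
    ts <- replicate(10000, sample_transform(cfg, size = c(224, 224)), simplify = FALSE)
  })
  ang <- vapply(ts, `[[`, numeric(1), "angle")
  expect_gte(min(ang), 0); expect_lte(max(ang), 30)
  expect_lt(abs(mean(ang) - 15), 0.5)
  sc <- vapply(ts, `[[`, numeric(1), "scale")
  expect_gte(min(sc), 0.975); expect_lte(max(sc), 1.025)
  dx <- vapply(ts, `[[`, numeric(1), "dx")
  expect_lte(max(abs(dx)), 0.25 * 224)
  hf <- vapply(ts, `[[`, logical(1), "do_hflip")
  expect_lt(abs(mean(hf) - 0.5), 0.03)
})

test_that("flip semantics and constant invariance hold", {
  t <- identity_transform()
  t$do_hflip <- TRUE
  expect_identical(apply_transform(matrix(c(1, 3, 2, 4), 2, 2), t),
                   matrix(c(2, 4, 1, 3), 2, 2))  # [[1,2],[3,4]] -> [[2,1],[4,3]]
  cfg <- augment_config()
  withr::with_seed(2, {
    for (i in 1:5) {
      tr <- sample_transform(cfg, size = c(32, 32))
      out <- apply_transform(matrix(77, 32, 32), tr)
      expect_true(all(out == 77))
      expect_equal(dim(out), c(32, 32))
    }
  })
})

test_that("warped output always stays 8-bit with the input shape", {
  cfg <- augment_config()
  withr::with_seed(21, {
    m <- matrix(sample(0:255, 48 * 64, TRUE), 48, 64)
    for (i in 1:10) {
      tr <- sample_transform(cfg, size = dim(m))
      out <- apply_transform(m, tr)
      expect_equal(dim(out), c(48, 64))
      expect_true(all(out >= 0 & out <= 255))
      expect_true(all(out == round(out)))
    }
  })
})

test_that("a transform composed with its inverse recovers a smooth image", {
  spec <- phantom_spec(image_size = 128, noise_sd = 0.01,
                       benign_nodule_radius = c(2, 4),
                       malignant_nodule_radius = c(5, 9))
  img <- generate_phantom(spec, "Malignant", seed = 4)$image
  cfg <- augment_config(hflip = FALSE, vflip = FALSE)
  withr::with_seed(8, tr <- sample_transform(cfg, size = dim(img)))
  fwd <- apply_transform(img, tr, interpolation = "nearest")
  back <- apply_affine_raw(fwd, invert_transform(tr), interpolation = "nearest")
  # ignore a border band where clamped (edge-replicated) pixels cannot return
  core <- expand.grid(r = 40:88, c = 40:88)
  diffs <- abs(img[as.matrix(core)] - back[as.matrix(core)])
  expect_gte(mean(diffs <= 2), 0.95)
})
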