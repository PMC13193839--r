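test_that("confusion matrices count true-vs-predicted pairs in fixed order", {
  cm <- confusion(c("Benign", "Malignant", "Normal"),
                  c("Benign", "Malignant", "Normal"))
  expect_equal(unname(diag(cm)), c(1L, 1L, 1L))
  expect_equal(sum(cm), 3)
  expect_true(all(confusion(character(0), character(0)) == 0))
  # the reference error pattern reconstructed from labels
  labs <- cm_to_labels(reference_cm())
  expect_equal(unname(confusion(labs$truth, labs$pred)), unname(reference_cm()))
  expect_error(confusion("Benign", c("Benign", "Normal")), "equal length")
  expect_error(confusion("Benign", "Weird"), "unknown")
})

test_that("metrics on the reference confusion matrix match the published values", {
  m <- compute_metrics(reference_cm())
  expect_equal(m$accuracy, 431 / 450)
  expect_equal(round(100 * m$accuracy, 1), 95.8)
  pc <- m$per_class
  expect_equal(pc$precision, c(146 / 157, 140 / 141, 145 / 152))
  expect_equal(pc$recall, c(146 / 150, 140 / 150, 145 / 150))
  expect_equal(round(100 * pc$precision, 1), c(93.0, 99.3, 95.4))
  expect_equal(round(100 * pc$recall, 1), c(97.3, 93.3, 96.7))
  expect_equal(round(100 * pc$f1, 1), c(95.1, 96.2, 96.0))
  # one-vs-rest tallies partition every sample
  expect_true(all(pc$Tp + pc$Fp + pc$Fn + pc$Tn == 450))
})

test_that("perfect and degenerate matrices behave as specified", {
  perfect <- diag(c(10L, 10L, 10L))
  m <- compute_metrics(perfect)
  expect_true(all(m$per_class$precision == 1))
  expect_true(all(m$per_class$f1 == 1))
  expect_equal(m$accuracy, 1)
  expect_error(compute_metrics(matrix(0L, 3, 3)), "all zero")
  # an empty class: flagged, metric sentinel 0 / NA
  cm <- matrix(c(5L, 0L, 0L, 0L, 0L, 0L, 0L, 0L, 4L), 3, 3, byrow = TRUE)
  m2 <- compute_metrics(cm)
  expect_true(m2$per_class$undefined[2])
  expect_equal(m2$per_class$recall[2], 0)
  expect_true(is.na(classwise_accuracy(cm)[2]))
})

test_that("metrics agree with a per-sample brute-force tally on random matrices", {
  withr::with_seed(99, {
    for (i in 1:25) {
      cm <- matrix(rpois(9, 20) + 1L, 3, 3,
                   dimnames = list(true = c("Benign", "Malignant", "Normal"),
                                   predicted = c("Benign", "Malignant", "Normal")))
      m <- compute_metrics(cm)
      bf <- brute_force_metrics(cm)
      expect_equal(m$accuracy, bf$accuracy, tolerance = 1e-12)
      for (k in 1:3) {
        expect_equal(m$per_class$precision[k], unname(bf$per_class[[k]]["precision"]),
                     tolerance = 1e-12)
        expect_equal(m$per_class$recall[k], unname(bf$per_class[[k]]["recall"]),
                     tolerance = 1e-12)
        expect_equal(m$per_class$f1[k], unname(bf$per_class[[k]]["f1"]),
                     tolerance = 1e-12)
      }
      # class-wise accuracy is per-class recall
      expect_equal(unname(classwise_accuracy(cm)), m$per_class$recall)
    }
  })
})

test_that("micro-averaged recall equals overall accuracy for balanced classes", {
  cm <- reference_cm()
  m <- compute_metrics(cm)
  expect_equal(mean(m$per_class$recall), m$accuracy)
})

test_that("reports render published rounding and survive a JSON round trip", {
  cm <- reference_cm()
  m <- compute_metrics(cm)
  rep <- render_report(m, cm)
  expect_true(any(grepl("95\\.8", rep$text)))
  expect_true(any(grepl("97\\.33", rep$text)))
  parsed <- jsonlite::fromJSON(rep$json, simplifyVector = TRUE)
  expect_equal(parsed$overall_accuracy, m$accuracy)
  expect_equal(unname(as.matrix(parsed$confusion)), unname(cm))
  expect_equal(parsed$per_class$precision, m$per_class$precision)
  # undefined metric renders as n/a
  cmz <- matrix(c(5L, 0L, 0L, 1L, 0L, 0L, 0L, 0L, 4L), 3, 3, byrow = TRUE)
  repz <- render_report(compute_metrics(cmz), cmz)
  expect_true(any(grepl("n/a", repz$text)))
})
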