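test_that("the default head follows the 1024-512-256-256-128-3 width contract", {
  m <- build_model(model_config(), seed = 1)
  x <- matrix(sample(0:255, 224 * 224, TRUE), 224, 224)
  fw <- lungct:::forward_one(m, x)
  expect_equal(unname(fw$widths),
               c(1024L, 512L, 256L, 256L, 128L, 3L))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
})

test_that("the toy configuration builds the same topology at small scale, quickly", {
  cfg <- toy_model_config()
  m <- build_model(cfg, seed = 2)
  x <- matrix(sample(0:255, 224 * 224, TRUE), 224, 224)
  t0 <- Sys.time()
  fw <- lungct:::forward_one(m, x)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(unname(fw$widths), c(32L, 16L, 8L, 16L, 8L, 3L))
  expect_equal(sum(fw$probs), 1, tolerance = 1e-6)
})

test_that("a pretrained-only backbone name is rejected with a clear error", {
  expect_error(build_model(model_config(backbone = "densenet201")),
               "pretrained ImageNet weights")
  expect_error(model_config(backbone = "resnet50"), "should be one of")
})

test_that("feature extraction is deterministic, wide as configured, and non-degenerate", {
  m <- build_model(model_config(), seed = 3)
  imgs <- list(matrix(10, 224, 224), matrix(10, 224, 224),
               matrix(sample(0:255, 224 * 224, TRUE), 224, 224),
               matrix(200, 224, 224), matrix(0, 224, 224))
  f <- extract_features(m, imgs)
  expect_equal(dim(f), c(5L, 1024L))
  expect_identical(f[1, ], f[2, ])          # identical inputs, identical rows
  expect_false(isTRUE(all.equal(f[3, ], f[4, ])))  # distinct inputs differ
})

test_that("predictions are normalised probabilities with argmax labels in class order", {
  m <- build_model(toy_model_config(), seed = 4)
  imgs <- replicate(4, matrix(sample(0:255, 224 * 224, TRUE), 224, 224),
                    simplify = FALSE)
  pr <- predict(m, imgs)
  expect_equal(dim(pr$prob), c(4L, 3L))
  expect_equal(unname(rowSums(pr$prob)), rep(1, 4), tolerance = 1e-9)
  expect_length(pr$label, 4)
  expect_identical(pr$label,
                   c("Benign", "Malignant", "Normal")[apply(pr$prob, 1, which.max)])
})

test_that("analytic gradients match finite differences through every layer type", {
  m <- build_model(toy_model_config(tiny_channels = c(2L, 3L, 4L), feature_dim = 6L,
                                    gru_units = c(3L, 2L), dense_units = c(5L, 4L)),
                   seed = 5)
  withr::with_seed(6, x <- matrix(runif(224 * 224) * 255, 224, 224))
  y <- c(0, 1, 0)
  lossfn <- function(mm) {
    p <- lungct:::forward_one(mm, x)$probs
    -sum(y * log(p + 1e-12))
  }
  fw <- lungct:::forward_one(m, x, train = FALSE, keep_cache = TRUE)
  g <- lungct:::backward_one(m, fw, fw$probs - y, need_conv12 = TRUE)
  eps <- 1e-5
  withr::with_seed(7, {
    for (nm in c("conv1.W", "conv2.W", "conv3.W", "proj.W", "gru1.f.Wz",
                 "gru1.b.Wc", "gru2.f.Wc", "dense1.W", "dense2.W", "out.W", "out.b")) {
      i <- sample(length(m$params[[nm]]), 1)
      m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
      m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
      num <- (lossfn(m2) - lossfn(m3)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4, label = nm)
    }
    # the reset gate cannot influence a one-step, zero-state GRU
    expect_true(all(g$gru1.f.Wr == 0))
  })
})

test_that("early stopping arithmetic matches the patience rule", {
  # best at epoch 2, strictly increasing afterwards, patience 5 -> stop at 7
  tr <- early_stop_trace(c(1.0, 0.8, 0.81, 0.82, 0.83, 0.84, 0.85, 0.86), patience = 5)
  expect_equal(tr$best_epoch, 2)
  expect_equal(tr$stopped_epoch, 7)
  # monotone improvement never stops early
  tr2 <- early_stop_trace(seq(1, 0.1, length.out = 10), patience = 3)
  expect_equal(tr2$best_epoch, 10)
  expect_equal(tr2$stopped_epoch, 10)
  # plateau from the start
  tr3 <- early_stop_trace(rep(1, 6), patience = 2)
  expect_equal(tr3$best_epoch, 1)
  expect_equal(tr3$stopped_epoch, 3)
})

test_that("the freeze policy keeps frozen backbone blocks untouched while the head moves", {
  d <- make_toy_training_set(2)
  m <- build_model(toy_model_config(), seed = 8)
  before <- m$params
  tcfg <- train_config(learning_rate = 1e-3, max_epochs = 6L, patience = 5L,
                       batch_size = 6L, freeze_policy = "final_block", seed = 1L)
  fit <- train_model(m, d$images, d$labels, d$images, d$labels, tcfg)
  after <- fit$model$params
  expect_identical(before$conv1.W, after$conv1.W)
  expect_identical(before$conv2.W, after$conv2.W)
  expect_false(identical(before$conv3.W, after$conv3.W))
  expect_false(identical(before$out.W, after$out.W))
})

test_that("training is reproducible and restores the best-epoch weights", {
  d <- make_toy_training_set(2)
  tcfg <- train_config(learning_rate = 1e-3, max_epochs = 4L, patience = 3L,
                       batch_size = 6L, freeze_policy = "none", seed = 9L)
  f1 <- train_model(build_model(toy_model_config(), seed = 10),
                    d$images, d$labels, d$images, d$labels, tcfg,
                    aug = augment_config())
  f2 <- train_model(build_model(toy_model_config(), seed = 10),
                    d$images, d$labels, d$images, d$labels, tcfg,
                    aug = augment_config())
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model$params, f2$model$params)
  # restored weights reproduce the best monitored loss exactly
  ev <- lungct:::eval_model(f1$model, d$images, encode_labels(d$labels))
  expect_equal(ev$loss, min(f1$history$val_loss), tolerance = 1e-12)
  expect_equal(f1$best_epoch, which.min(f1$history$val_loss))
})
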