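#' Hybrid model architecture configuration
#'
#' The classifier couples a convolutional backbone with a recurrent gating
#' head: backbone -> global average pooling -> linear projection to
#' `feature_dim` -> reshape to a one-step sequence -> two stacked
#' bidirectional GRU layers (outputs concatenated, so widths `2 * units`) ->
#' two ReLU dense layers with dropout -> 3-way softmax. With the defaults the
#' widths along the head are 1024 -> 512 -> 256 -> 256 -> 128 -> 3.
#'
#' The only backbone shipped is `"tiny_cnn"`: an average-pool stem followed by
#' three 3x3 convolution + ReLU + max-pool blocks and global average pooling.
#' It trains from scratch on a CPU in minutes. `"densenet201"` is recognised
#' as a name but rejected at build time: its value comes entirely from
#' ImageNet pretraining, and pretrained weights are not bundled with this
#' package. The 1024-wide projected feature interface is identical for any
#' backbone, so the head contract does not depend on the backbone choice.
#'
#' With a one-step sequence and a zero initial state the GRU recurrence
#' carries no temporal information: the update gate acts as a learned,
#' input-conditional feature-weighting (`h = z * candidate`). Recurrent
#' kernels are therefore not allocated, and the reset gate, though present,
#' receives no gradient.
#'
#' @param backbone `"tiny_cnn"` (implemented) or `"densenet201"` (rejected at
#'   build time; see Details).
#' @param feature_dim width of the projected feature vector.
#' @param gru_units units of the two BiGRU layers (per direction).
#' @param gru_dropout input-dropout rate applied before each BiGRU layer
#'   during training (the recurrent-connection dropout of a one-step sequence
#'   is vacuous).
#' @param dense_units widths of the two ReLU dense layers.
#' @param head_dropout dropout rates after the two dense layers.
#' @param n_classes number of output classes.
#' @param use_bigru_head if `FALSE`, the two BiGRU layers are replaced by
#'   plain ReLU dense layers of matched widths (`2 * gru_units`), the
#'   dense-head ablation baseline.
#' @param tiny_channels channel widths of the three tiny_cnn blocks.
#' @param global_pool `"avg"` (default, the standard global average pooling)
#'   or `"sum"` (area-scaled) pooling over the final feature map.
#' @param input_scale `"unit"` (default; pixels mapped to `[0, 1]`, so
#'   masked-out background stays exactly inactive) or `"centered"`
#'   (`[-1, 1]`, the common convention for unmasked photographic input).
#' @param stem_pool if `TRUE` (default) the tiny_cnn backbone opens with a
#'   2x average-pool stem (halves compute); `FALSE` keeps full 224
#'   resolution into the first convolution, preserving the contrast of
#'   small nodules at the cost of roughly double the runtime.
#' @param block_norm if `TRUE` (default) each tiny_cnn convolution is
#'   followed by affine-free instance normalisation before the ReLU.
#'   Per-sample channel statistics condition from-scratch optimisation the
#'   way batch normalisation does, but deterministically and without batch
#'   coupling.
#' @return a `model_config` list.
#' @export
model_config <- function(backbone = c("tiny_cnn", "densenet201"),
                         feature_dim = 1024L,
                         gru_units = c(256L, 128L),
                         gru_dropout = 0.3,
                         dense_units = c(256L, 128L),
                         head_dropout = c(0.5, 0.3),
                         n_classes = 3L,
                         use_bigru_head = TRUE,
                         tiny_channels = c(8L, 16L, 32L),
                         global_pool = c("avg", "sum"),
                         input_scale = c("unit", "centered"),
                         stem_pool = TRUE,
                         block_norm = TRUE) {
  backbone <- match.arg(backbone)
  cfg <- list(backbone = backbone,
              feature_dim = as.integer(feature_dim),
              gru_units = as.integer(gru_units),
              gru_dropout = gru_dropout,
              dense_units = as.integer(dense_units),
              head_dropout = head_dropout,
              n_classes = as.integer(n_classes),
              use_bigru_head = isTRUE(use_bigru_head),
              tiny_channels = as.integer(tiny_channels),
              global_pool = match.arg(global_pool),
              input_scale = match.arg(input_scale),
              stem_pool = isTRUE(stem_pool),
              block_norm = isTRUE(block_norm))
  assert_that(cfg$feature_dim >= 1 && all(cfg$gru_units >= 1) && all(cfg$dense_units >= 1),
              "layer widths must be positive")
  assert_that(length(cfg$gru_units) == 2 && length(cfg$dense_units) == 2,
              "gru_units and dense_units must each have length 2")
  assert_that(cfg$n_classes >= 2, "n_classes must be at least 2")
  class(cfg) <- "model_config"
  cfg
}

#' A toy-scale model configuration
#'
#' tiny_cnn backbone with a narrow head (`feature_dim = 32`,
#' `gru_units = c(8, 4)`, `dense_units = c(16, 8)`), small channel widths and
#' the same topology as the default configuration. Builds and runs on a CPU
#' in well under a second per batch.
#' @param ... overrides forwarded to [model_config()].
#' @return a `model_config`.
#' @export
toy_model_config <- function(...) {
  defaults <- list(backbone = "tiny_cnn", feature_dim = 32L,
                   gru_units = c(8L, 4L), dense_units = c(16L, 8L),
                   tiny_channels = c(6L, 12L, 24L))
  args <- utils::modifyList(defaults, list(...))
  do.call(model_config, args)
}

#' Training protocol configuration
#'
#' Adam with categorical cross-entropy, mini-batches of 32, at most 30
#' epochs, and early stopping that monitors the held-out loss with a patience
#' of 5 epochs and restores the best-epoch weights. The default learning rate
#' (1e-5) and freeze policy (`"final_block"`: all backbone blocks frozen
#' except the last) describe a fine-tuning protocol; when training the
#' tiny_cnn backbone from scratch use `freeze_policy = "none"` and a larger
#' learning rate (around 1e-3).
#'
#' @param learning_rate positive Adam step size.
#' @param batch_size mini-batch size.
#' @param max_epochs maximum epochs.
#' @param patience early-stopping patience (must be below `max_epochs`).
#' @param restore_best restore the weights of the minimum-monitor-loss epoch.
#' @param freeze_policy `"final_block"`, `"none"` or `"backbone_all"`.
#' @param lr_plateau_factor multiplier applied to the learning rate when the
#'   monitor loss has not improved for `lr_plateau_patience` epochs (dynamic
#'   learning-rate scheduling). The default 1 disables the schedule: on
#'   short from-scratch runs the monitor loss is noisy near chance level and
#'   premature decay freezes the model; enable it (e.g. 0.5) for longer
#'   fine-tuning runs.
#' @param lr_plateau_patience epochs without improvement before the learning
#'   rate is reduced.
#' @param seed RNG seed governing shuffling, augmentation and dropout.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 1e-5,
                         batch_size = 32L,
                         max_epochs = 30L,
                         patience = 5L,
                         restore_best = TRUE,
                         freeze_policy = c("final_block", "none", "backbone_all"),
                         lr_plateau_factor = 1,
                         lr_plateau_patience = 3L,
                         seed = 42L) {
  assert_that(learning_rate > 0, "learning_rate must be positive")
  assert_that(patience < max_epochs, "patience must be below max_epochs")
  assert_that(lr_plateau_factor > 0 && lr_plateau_factor <= 1,
              "lr_plateau_factor must lie in (0, 1]")
  cfg <- list(optimizer = "adam", loss = "categorical_crossentropy",
              learning_rate = learning_rate, batch_size = as.integer(batch_size),
              max_epochs = as.integer(max_epochs), patience = as.integer(patience),
              restore_best = isTRUE(restore_best),
              freeze_policy = match.arg(freeze_policy),
              lr_plateau_factor = lr_plateau_factor,
              lr_plateau_patience = as.integer(lr_plateau_patience),
              seed = as.integer(seed))
  class(cfg) <- "train_config"
  cfg
}

gru_view <- function(params, prefix) {
  list(Wz = params[[paste0(prefix, ".Wz")]], bz = params[[paste0(prefix, ".bz")]],
       Wr = params[[paste0(prefix, ".Wr")]], br = params[[paste0(prefix, ".br")]],
       Wc = params[[paste0(prefix, ".Wc")]], bc = params[[paste0(prefix, ".bc")]])
}

gru_store <- function(params, prefix, p) {
  for (nm in names(p)) params[[paste0(prefix, ".", nm)]] <- p[[nm]]
  params
}

#' Build the hybrid classifier
#'
#' Initialises all weights with the given seed (He initialisation for
#' convolution and ReLU dense layers, Glorot for the GRU gates and the
#' output layer). The returned model accepts 224x224x3 inputs.
#'
#' @param config a [model_config()].
#' @param seed integer seed for weight initialisation.
#' @return a `lungct_model` list with elements `config` and `params`.
#' @export
build_model <- function(config = model_config(), seed = 1L) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  if (config$backbone == "densenet201") {
    stop(paste("backbone 'densenet201' requires pretrained ImageNet weights,",
               "which are not bundled with this package; use backbone 'tiny_cnn'"),
         call. = FALSE)
  }
  ch <- config$tiny_channels
  fd <- config$feature_dim
  u <- config$gru_units
  du <- config$dense_units
  withr::with_seed(as.integer(seed), {
    params <- list(
      conv1.W = init_he(9L * 3L, ch[1]), conv1.b = numeric(ch[1]),
      conv2.W = init_he(9L * ch[1], ch[2]), conv2.b = numeric(ch[2]),
      conv3.W = init_he(9L * ch[2], ch[3]), conv3.b = numeric(ch[3]),
      proj.W = init_glorot(ch[3], fd), proj.b = numeric(fd)
    )
    if (config$use_bigru_head) {
      params <- gru_store(params, "gru1.f", init_gru_dir(fd, u[1]))
      params <- gru_store(params, "gru1.b", init_gru_dir(fd, u[1]))
      params <- gru_store(params, "gru2.f", init_gru_dir(2L * u[1], u[2]))
      params <- gru_store(params, "gru2.b", init_gru_dir(2L * u[1], u[2]))
    } else {
      params$alt1.W <- init_he(fd, 2L * u[1]); params$alt1.b <- numeric(2L * u[1])
      params$alt2.W <- init_he(2L * u[1], 2L * u[2]); params$alt2.b <- numeric(2L * u[2])
    }
    params$dense1.W <- init_he(2L * u[2], du[1]); params$dense1.b <- numeric(du[1])
    params$dense2.W <- init_he(du[1], du[2]); params$dense2.b <- numeric(du[2])
    params$out.W <- init_glorot(du[2], config$n_classes)
    params$out.b <- numeric(config$n_classes)
  })
  model <- list(config = config, params = params,
                idx_cache = new.env(parent = emptyenv()))
  class(model) <- "lungct_model"
  model
}

# Parameter names moved by the optimizer under a freeze policy. The backbone
# partition is conv1..conv3; "final_block" keeps only the last convolution
# block (and the whole head) trainable, mirroring a conv5-only fine-tune.
trainable_param_names <- function(params, freeze_policy) {
  nms <- names(params)
  frozen <- switch(freeze_policy,
                   none = character(0),
                   final_block = c("conv1.W", "conv1.b", "conv2.W", "conv2.b"),
                   backbone_all = c("conv1.W", "conv1.b", "conv2.W", "conv2.b",
                                    "conv3.W", "conv3.b"))
  setdiff(nms, frozen)
}

# Full forward pass for one sample. `x` is either a 224x224 grayscale matrix
# (replicated to three channels here) or a 224x224x3 array. Returns class
# probabilities plus, optionally, the cache needed for backprop and the
# intermediate widths.
forward_one <- function(model, x, train = FALSE, keep_cache = FALSE) {
  p <- model$params
  cfg <- model$config
  if (is.matrix(x)) x <- array(rep(x, 3L), c(dim(x), 3L))
  assert_that(all(dim(x) == c(224L, 224L, 3L)), "model input must be 224x224x3")
  x <- if (cfg$input_scale == "centered") (x - 127.5) / 127.5 else x / 255

  x0 <- if (cfg$stem_pool) avgpool2_forward(x) else x
  c1 <- conv3x3_forward(x0, p$conv1.W, p$conv1.b, model$idx_cache)
  n1 <- if (cfg$block_norm) instnorm_forward(c1$out) else list(out = c1$out)
  r1 <- pmax(n1$out, 0)
  p1 <- maxpool2_forward(r1)
  c2 <- conv3x3_forward(p1$out, p$conv2.W, p$conv2.b, model$idx_cache)
  n2 <- if (cfg$block_norm) instnorm_forward(c2$out) else list(out = c2$out)
  r2 <- pmax(n2$out, 0)
  p2 <- maxpool2_forward(r2)
  c3 <- conv3x3_forward(p2$out, p$conv3.W, p$conv3.b, model$idx_cache)
  n3 <- if (cfg$block_norm) instnorm_forward(c3$out) else list(out = c3$out)
  r3 <- pmax(n3$out, 0)
  p3 <- maxpool2_forward(r3)
  d3 <- dim(p3$out)
  pooled <- if (cfg$global_pool == "sum") {
    colSums(matrix(p3$out, d3[1] * d3[2], d3[3]))
  } else {
    colMeans(matrix(p3$out, d3[1] * d3[2], d3[3]))
  }

  feat <- as.vector(pooled %*% p$proj.W) + p$proj.b

  drop_in1 <- if (train) dropout_mask(length(feat), cfg$gru_dropout) else rep(1, length(feat))
  h0 <- feat * drop_in1
  if (cfg$use_bigru_head) {
    g1f <- gru_dir_forward(h0, gru_view(p, "gru1.f"))
    g1b <- gru_dir_forward(h0, gru_view(p, "gru1.b"))
    g1 <- c(g1f$h, g1b$h)
  } else {
    a1pre <- as.vector(h0 %*% p$alt1.W) + p$alt1.b
    g1 <- pmax(a1pre, 0)
  }
  drop_in2 <- if (train) dropout_mask(length(g1), cfg$gru_dropout) else rep(1, length(g1))
  h1 <- g1 * drop_in2
  if (cfg$use_bigru_head) {
    g2f <- gru_dir_forward(h1, gru_view(p, "gru2.f"))
    g2b <- gru_dir_forward(h1, gru_view(p, "gru2.b"))
    g2 <- c(g2f$h, g2b$h)
  } else {
    a2pre <- as.vector(h1 %*% p$alt2.W) + p$alt2.b
    g2 <- pmax(a2pre, 0)
  }

  d1pre <- as.vector(g2 %*% p$dense1.W) + p$dense1.b
  d1 <- pmax(d1pre, 0)
  drop1 <- if (train) dropout_mask(length(d1), cfg$head_dropout[1]) else rep(1, length(d1))
  d1d <- d1 * drop1
  d2pre <- as.vector(d1d %*% p$dense2.W) + p$dense2.b
  d2 <- pmax(d2pre, 0)
  drop2 <- if (train) dropout_mask(length(d2), cfg$head_dropout[2]) else rep(1, length(d2))
  d2d <- d2 * drop2
  logits <- as.vector(d2d %*% p$out.W) + p$out.b
  probs <- softmax_row(logits)

  res <- list(probs = probs, feature = feat,
              widths = c(feature = length(feat), block1 = length(g1),
                         block2 = length(g2), dense1 = length(d1),
                         dense2 = length(d2), out = length(probs)))
  if (keep_cache) {
    res$cache <- list(x0 = x0, c1 = c1, n1 = n1, r1mask = n1$out > 0, p1 = p1,
                      c2 = c2, n2 = n2, r2mask = n2$out > 0, p2 = p2,
                      c3 = c3, n3 = n3, r3mask = n3$out > 0, p3 = p3,
                      pooled = pooled, d3 = d3,
                      drop_in1 = drop_in1, h0 = h0,
                      g1f = if (cfg$use_bigru_head) g1f else NULL,
                      g1b = if (cfg$use_bigru_head) g1b else NULL,
                      a1pre = if (!cfg$use_bigru_head) a1pre else NULL,
                      g1 = g1, drop_in2 = drop_in2, h1 = h1,
                      g2f = if (cfg$use_bigru_head) g2f else NULL,
                      g2b = if (cfg$use_bigru_head) g2b else NULL,
                      a2pre = if (!cfg$use_bigru_head) a2pre else NULL,
                      g2 = g2, d1pre = d1pre, d1 = d1, drop1 = drop1, d1d = d1d,
                      d2pre = d2pre, d2 = d2, drop2 = drop2, d2d = d2d)
  }
  res
}

# Gradients of the mean cross-entropy for one sample given dlogits
# (probs - y, already divided by the batch size). Returns a flat named list
# aligned with model$params; frozen entries are still computed cheaply
# upstream of the last needed dx.
backward_one <- function(model, fw, dlogits, need_conv12 = TRUE) {
  p <- model$params
  cfg <- model$config
  cc <- fw$cache
  g <- list()

  g$out.W <- outer(cc$d2d, dlogits)
  g$out.b <- dlogits
  dd2d <- as.vector(p$out.W %*% dlogits)
  dd2 <- dd2d * cc$drop2
  dd2pre <- dd2 * (cc$d2pre > 0)
  g$dense2.W <- outer(cc$d1d, dd2pre)
  g$dense2.b <- dd2pre
  dd1d <- as.vector(p$dense2.W %*% dd2pre)
  dd1 <- dd1d * cc$drop1
  dd1pre <- dd1 * (cc$d1pre > 0)
  g$dense1.W <- outer(cc$g2, dd1pre)
  g$dense1.b <- dd1pre
  dg2 <- as.vector(p$dense1.W %*% dd1pre)

  if (cfg$use_bigru_head) {
    u2 <- cfg$gru_units[2]
    bf <- gru_dir_backward(dg2[seq_len(u2)], cc$g2f, gru_view(p, "gru2.f"))
    bb <- gru_dir_backward(dg2[u2 + seq_len(u2)], cc$g2b, gru_view(p, "gru2.b"))
    for (nm in c("Wz", "bz", "Wr", "br", "Wc", "bc")) {
      g[[paste0("gru2.f.", nm)]] <- bf[[paste0("d", nm)]]
      g[[paste0("gru2.b.", nm)]] <- bb[[paste0("d", nm)]]
    }
    dh1 <- bf$dx + bb$dx
  } else {
    da2pre <- dg2 * (cc$a2pre > 0)
    g$alt2.W <- outer(cc$h1, da2pre)
    g$alt2.b <- da2pre
    dh1 <- as.vector(p$alt2.W %*% da2pre)
  }
  dg1 <- dh1 * cc$drop_in2
  if (cfg$use_bigru_head) {
    u1 <- cfg$gru_units[1]
    bf <- gru_dir_backward(dg1[seq_len(u1)], cc$g1f, gru_view(p, "gru1.f"))
    bb <- gru_dir_backward(dg1[u1 + seq_len(u1)], cc$g1b, gru_view(p, "gru1.b"))
    for (nm in c("Wz", "bz", "Wr", "br", "Wc", "bc")) {
      g[[paste0("gru1.f.", nm)]] <- bf[[paste0("d", nm)]]
      g[[paste0("gru1.b.", nm)]] <- bb[[paste0("d", nm)]]
    }
    dh0 <- bf$dx + bb$dx
  } else {
    da1pre <- dg1 * (cc$a1pre > 0)
    g$alt1.W <- outer(cc$h0, da1pre)
    g$alt1.b <- da1pre
    dh0 <- as.vector(p$alt1.W %*% da1pre)
  }
  dfeat <- dh0 * cc$drop_in1

  g$proj.W <- outer(cc$pooled, dfeat)
  g$proj.b <- dfeat
  dpooled <- as.vector(p$proj.W %*% dfeat)

  d3 <- cc$d3
  denom <- if (cfg$global_pool == "sum") 1 else d3[1] * d3[2]
  dgap <- array(rep(dpooled / denom, each = d3[1] * d3[2]), d3)
  dr3 <- maxpool2_backward(dgap, cc$p3)
  dn3 <- dr3 * cc$r3mask
  dc3 <- if (cfg$block_norm) instnorm_backward(dn3, cc$n3) else dn3
  b3 <- conv3x3_backward(dc3, cc$c3, p$conv3.W, model$idx_cache, want_dx = need_conv12)
  g$conv3.W <- b3$dW; g$conv3.b <- b3$db
  if (need_conv12) {
    dr2 <- maxpool2_backward(b3$dx, cc$p2)
    dn2 <- dr2 * cc$r2mask
    dc2 <- if (cfg$block_norm) instnorm_backward(dn2, cc$n2) else dn2
    b2 <- conv3x3_backward(dc2, cc$c2, p$conv2.W, model$idx_cache, want_dx = TRUE)
    g$conv2.W <- b2$dW; g$conv2.b <- b2$db
    dr1 <- maxpool2_backward(b2$dx, cc$p1)
    dn1 <- dr1 * cc$r1mask
    dc1 <- if (cfg$block_norm) instnorm_backward(dn1, cc$n1) else dn1
    b1 <- conv3x3_backward(dc1, cc$c1, p$conv1.W, model$idx_cache, want_dx = FALSE)
    g$conv1.W <- b1$dW; g$conv1.b <- b1$db
  }
  g
}

#' Extract projected backbone features
#'
#' Runs the backbone, global average pooling and the linear projection in
#' inference mode (no dropout), one row per image; deterministic for fixed
#' weights.
#'
#' @param model a built `lungct_model`.
#' @param images list of 224x224 grayscale matrices or 224x224x3 arrays.
#' @return numeric matrix `length(images)` x `feature_dim`.
#' @export
extract_features <- function(model, images) {
  assert_that(inherits(model, "lungct_model"), "model must be a lungct_model")
  rows <- lapply(images, function(x) forward_one(model, x)$feature)
  do.call(rbind, rows)
}

#' Predict class probabilities and labels
#'
#' @param object a `lungct_model`.
#' @param images list of 224x224 grayscale matrices or 224x224x3 arrays.
#' @param ... unused.
#' @return list with `prob` (matrix, rows sum to 1, columns in the fixed class
#'   order Benign, Malignant, Normal) and `label` (character vector via
#'   row-wise argmax).
#' @export
predict.lungct_model <- function(object, images, ...) {
  probs <- t(vapply(images, function(x) forward_one(object, x)$probs,
                    numeric(object$config$n_classes)))
  colnames(probs) <- LUNG_CLASSES[seq_len(object$config$n_classes)]
  list(prob = probs, label = LUNG_CLASSES[max.col(probs, ties.method = "first")])
}

#' Early-stopping bookkeeping on a loss trace
#'
#' Pure arithmetic of the stopping rule: training halts at the first epoch
#' whose distance from the best (minimum) monitored loss reaches `patience`;
#' if the trace ends first, the last epoch is the stopping epoch.
#'
#' @param losses numeric vector of per-epoch monitored losses.
#' @param patience integer patience.
#' @return list with `best_epoch` and `stopped_epoch`.
#' @export
early_stop_trace <- function(losses, patience) {
  best <- Inf; best_epoch <- 0L; wait <- 0L
  stopped <- length(losses)
  for (e in seq_along(losses)) {
    if (losses[e] < best) {
      best <- losses[e]; best_epoch <- e; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= patience) { stopped <- e; break }
    }
  }
  list(best_epoch = best_epoch, stopped_epoch = stopped)
}

eval_model <- function(model, images, Y) {
  n <- length(images)
  loss <- 0; correct <- 0
  truth <- max.col(Y)
  for (i in seq_len(n)) {
    pr <- forward_one(model, images[[i]])$probs
    loss <- loss - sum(Y[i, ] * log(pr + 1e-12))
    if (which.max(pr) == truth[i]) correct <- correct + 1
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train the hybrid classifier
#'
#' Mini-batch Adam with categorical cross-entropy. Augmentation, when given,
#' is applied to the training stream only — monitor images are evaluated
#' untouched, in inference mode. After each epoch the monitor loss is
#' evaluated; training stops at `max_epochs` or when the monitor loss has
#' not improved for `patience` epochs, and the best-epoch weights are
#' restored when `restore_best` is on. All shuffling, augmentation draws and
#' dropout masks are seeded from `tcfg$seed`, so identical calls produce
#' identical histories and weights.
#'
#' @param model a built `lungct_model`.
#' @param train_images,monitor_images lists of 224x224 grayscale matrices.
#' @param train_labels,monitor_labels character class labels.
#' @param tcfg a [train_config()].
#' @param aug optional [augment_config()] for the training stream.
#' @return a `lungct_fit` list: `model` (trained), `history` (per-epoch
#'   data.frame with `loss`, `acc`, `val_loss`, `val_acc`), `best_epoch`,
#'   `stopped_epoch`.
#' @export
train_model <- function(model, train_images, train_labels,
                        monitor_images, monitor_labels,
                        tcfg = train_config(), aug = NULL) {
  assert_that(inherits(model, "lungct_model"), "model must be a lungct_model")
  assert_that(length(train_images) > 0, "training set is empty")
  assert_that(length(train_images) == length(train_labels),
              "train images/labels length mismatch")
  Y <- encode_labels(train_labels)
  Ym <- encode_labels(monitor_labels)
  upd <- trainable_param_names(model$params, tcfg$freeze_policy)
  state <- adam_state()
  hist <- data.frame(epoch = integer(0), loss = numeric(0), acc = numeric(0),
                     val_loss = numeric(0), val_acc = numeric(0), lr = numeric(0))
  best_loss <- Inf; best_epoch <- 0L; wait <- 0L; stopped <- 0L
  lr_wait <- 0L
  lr <- tcfg$learning_rate
  best_params <- model$params
  n <- length(train_images)
  truth <- max.col(Y)

  for (epoch in seq_len(tcfg$max_epochs)) {
    epoch_loss <- 0; epoch_correct <- 0
    withr::with_seed(derive_seed(tcfg$seed, 7L, epoch), {
      ord <- sample.int(n)
      starts <- seq(1, n, by = tcfg$batch_size)
      for (s in starts) {
        bidx <- ord[s:min(s + tcfg$batch_size - 1, n)]
        bs <- length(bidx)
        grads <- NULL
        for (i in bidx) {
          img <- train_images[[i]]
          if (!is.null(aug)) {
            tr <- sample_transform(aug, size = dim(img))
            img <- apply_transform(img, tr)
          }
          fw <- forward_one(model, img, train = TRUE, keep_cache = TRUE)
          yi <- Y[i, ]
          epoch_loss <- epoch_loss - sum(yi * log(fw$probs + 1e-12))
          if (which.max(fw$probs) == truth[i]) epoch_correct <- epoch_correct + 1
          dlogits <- (fw$probs - yi) / bs
          gi <- backward_one(model, fw, dlogits,
                             need_conv12 = tcfg$freeze_policy == "none")
          if (is.null(grads)) {
            grads <- gi
          } else {
            for (nm in names(gi)) grads[[nm]] <- grads[[nm]] + gi[[nm]]
          }
        }
        if (any(!is.finite(unlist(lapply(grads, range))))) {
          stop(sprintf("non-finite loss/gradient at epoch %d", epoch), call. = FALSE)
        }
        model$params <- adam_step(model$params, grads, state, intersect(upd, names(grads)),
                                  lr)
      }
    })
    ev <- eval_model(model, monitor_images, Ym)
    hist <- rbind(hist, data.frame(epoch = epoch, loss = epoch_loss / n,
                                   acc = epoch_correct / n,
                                   val_loss = ev$loss, val_acc = ev$acc,
                                   lr = lr))
    if (ev$loss < best_loss) {
      best_loss <- ev$loss; best_epoch <- epoch; wait <- 0L; lr_wait <- 0L
      best_params <- model$params
    } else {
      wait <- wait + 1L
      lr_wait <- lr_wait + 1L
      if (tcfg$lr_plateau_factor < 1 && lr_wait >= tcfg$lr_plateau_patience) {
        lr <- lr * tcfg$lr_plateau_factor
        lr_wait <- 0L
      }
      if (wait >= tcfg$patience) { stopped <- epoch; break }
    }
    stopped <- epoch
  }
  if (tcfg$restore_best && best_epoch > 0) model$params <- best_params
  fit <- list(model = model, history = hist,
              best_epoch = best_epoch, stopped_epoch = stopped)
  class(fit) <- "lungct_fit"
  fit
}
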