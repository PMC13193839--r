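# Shared fixtures and independent oracles used across the suite.

# Phantom spec scaled down for fast unit tests (nodule radii scaled with the
# frame so geometry stays valid).
small_spec <- function(size = 128L) {
  phantom_spec(image_size = size,
               benign_nodule_radius = c(2, 4),
               malignant_nodule_radius = c(5, 9))
}

# Independent connected-component labelling (BFS flood fill, 8-connectivity),
# deliberately not the routine the package uses.
flood_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  cur <- 0L
  for (start in which(mask == 1 & lab == 0)) {
    if (lab[start] != 0) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% h + 1L
      cc <- (q - 1L) %/% h + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc2 <- cc + dc
        if (rr >= 1 && rr <= h && cc2 >= 1 && cc2 <= w) {
          j <- rr + (cc2 - 1L) * h
          if (mask[j] == 1 && lab[j] == 0L) {
            lab[j] <- cur
            queue <- c(queue, j)
          }
        }
      }
    }
  }
  lab
}

# Filled disk mask by direct pixel accounting.
disk_mask <- function(size, cx, cy, r) {
  xx <- matrix(rep(seq_len(size), each = size), size, size)
  yy <- matrix(rep(seq_len(size), size), size, size)
  matrix(as.numeric((xx - cx)^2 + (yy - cy)^2 <= r^2), size, size)
}

mask_iou <- function(a, b) {
  sum(a * b) / sum((a + b) > 0)
}

# Brute-force one-vs-rest metrics: expand the confusion matrix into
# per-sample (true, predicted) pairs and tally counts by explicit loops.
brute_force_metrics <- function(cm) {
  pairs <- NULL
  for (i in 1:3) for (j in 1:3) {
    if (cm[i, j] > 0) {
      pairs <- rbind(pairs, matrix(rep(c(i, j), cm[i, j]), ncol = 2, byrow = TRUE))
    }
  }
  out <- list()
  for (k in 1:3) {
    tp <- fp <- fn <- tn <- 0
    for (s in seq_len(nrow(pairs))) {
      truth <- pairs[s, 1] == k
      pred <- pairs[s, 2] == k
      if (truth && pred) tp <- tp + 1
      else if (!truth && pred) fp <- fp + 1
      else if (truth && !pred) fn <- fn + 1
      else tn <- tn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    out[[k]] <- c(Tp = tp, Fp = fp, Fn = fn, Tn = tn,
                  precision = p, recall = r, f1 = f)
  }
  acc <- sum(pairs[, 1] == pairs[, 2]) / nrow(pairs)
  list(per_class = out, accuracy = acc)
}

# The confusion counts of the reference evaluation (450 balanced test
# images): row = true class, column = predicted class.
reference_cm <- function() {
  matrix(c(146L, 1L, 3L,
           6L, 140L, 4L,
           5L, 0L, 145L),
         3, 3, byrow = TRUE,
         dimnames = list(true = c("Benign", "Malignant", "Normal"),
                         predicted = c("Benign", "Malignant", "Normal")))
}

# Expand a confusion matrix into label vectors.
cm_to_labels <- function(cm) {
  classes <- rownames(cm)
  truth <- character(0); pred <- character(0)
  for (i in 1:3) for (j in 1:3) {
    truth <- c(truth, rep(classes[i], cm[i, j]))
    pred <- c(pred, rep(classes[j], cm[i, j]))
  }
  list(truth = truth, pred = pred)
}

# Small labelled phantom set resized to the backbone frame.
make_toy_training_set <- function(n = 4) {
  imgs <- list(); labs <- character(0)
  k <- 0
  for (cl in c("Benign", "Malignant", "Normal")) {
    for (i in seq_len(n)) {
      k <- k + 1
      rec <- generate_phantom(small_spec(), cl, seed = 100 + k)
      imgs[[k]] <- resize_to(rec$image, 224, 224)
      labs <- c(labs, cl)
    }
  }
  list(images = imgs, labels = labs)
}
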