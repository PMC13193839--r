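# Minimal dense/convolutional network engine used by the hybrid classifier.
# Convolutions are evaluated as im2col patch-matrix products so the heavy
# lifting runs through BLAS; gradients are analytic. Everything is double
# precision and single threaded, so repeated runs with the same seeds are
# bit-identical.

sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_row <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# ---- im2col index cache ------------------------------------------------

# Linear indices into a 1-padded (h+2, w+2, c) array for all 3x3 patches.
# Column order: (dr, dc, channel), row order: output positions column-major.
conv_idx <- function(h, w, c, cache) {
  key <- paste(h, w, c, sep = "_")
  if (!is.null(cache[[key]])) return(cache[[key]])
  out_i <- rep(seq_len(h), w)
  out_j <- rep(seq_len(w), each = h)
  drs <- rep(0:2, times = 3 * c)
  dcs <- rep(rep(0:2, each = 3), times = c)
  chs <- rep(seq_len(c), each = 9)
  ph <- h + 2L; pw <- w + 2L
  idx <- outer(out_i, drs, "+") +
    (outer(out_j, dcs, "+") - 1L) * ph +
    matrix((chs - 1L) * ph * pw, h * w, 9L * c, byrow = TRUE)
  cache[[key]] <- idx
  idx
}

# ---- layer forwards/backwards (single sample) --------------------------

conv3x3_forward <- function(x, Wm, b, cache_env) {
  d <- dim(x)
  h <- d[1]; w <- d[2]; c <- d[3]
  idx <- conv_idx(h, w, c, cache_env)
  xp <- array(0, c(h + 2L, w + 2L, c))
  xp[2:(h + 1), 2:(w + 1), ] <- x
  patches <- xp[idx]
  dim(patches) <- dim(idx)
  out <- patches %*% Wm
  out <- out + rep(b, each = h * w)
  list(out = array(out, c(h, w, ncol(Wm))), patches = patches,
       in_dim = d)
}

conv3x3_backward <- function(dout, fw, Wm, cache_env, want_dx = TRUE) {
  d <- fw$in_dim
  h <- d[1]; w <- d[2]; c <- d[3]
  dout2 <- matrix(dout, h * w, dim(dout)[3])
  dW <- crossprod(fw$patches, dout2)
  db <- colSums(dout2)
  dx <- NULL
  if (want_dx) {
    idx <- conv_idx(h, w, c, cache_env)
    dpatches <- dout2 %*% t(Wm)
    dxp <- numeric((h + 2L) * (w + 2L) * c)
    # within one patch-offset column all target positions are distinct, so
    # the col2im scatter-add can run column by column as plain vector adds
    for (k in seq_len(ncol(idx))) {
      dxp[idx[, k]] <- dxp[idx[, k]] + dpatches[, k]
    }
    dxp <- array(dxp, c(h + 2L, w + 2L, c))
    dx <- dxp[2:(h + 1), 2:(w + 1), , drop = FALSE]
  }
  list(dW = dW, db = db, dx = dx)
}

avgpool2_forward <- function(x) {
  d <- dim(x)
  oi <- seq(1, d[1], 2); ei <- oi + 1
  oj <- seq(1, d[2], 2); ej <- oj + 1
  (x[oi, oj, , drop = FALSE] + x[ei, oj, , drop = FALSE] +
     x[oi, ej, , drop = FALSE] + x[ei, ej, , drop = FALSE]) / 4
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  oi <- seq(1, d[1], 2); ei <- oi + 1
  oj <- seq(1, d[2], 2); ej <- oj + 1
  x11 <- x[oi, oj, , drop = FALSE]; x21 <- x[ei, oj, , drop = FALSE]
  x12 <- x[oi, ej, , drop = FALSE]; x22 <- x[ei, ej, , drop = FALSE]
  out <- pmax(x11, x21, x12, x22)
  # route the gradient to the first maximal entry only (fixed tie-break)
  m11 <- x11 == out
  m21 <- (x21 == out) & !m11
  m12 <- (x12 == out) & !m11 & !m21
  m22 <- !m11 & !m21 & !m12
  list(out = out, masks = list(m11, m21, m12, m22), in_dim = d)
}

maxpool2_backward <- function(dout, fw) {
  d <- fw$in_dim
  dx <- array(0, d)
  oi <- seq(1, d[1], 2); ei <- oi + 1
  oj <- seq(1, d[2], 2); ej <- oj + 1
  dx[oi, oj, ] <- dout * fw$masks[[1]]
  dx[ei, oj, ] <- dx[ei, oj, ] + dout * fw$masks[[2]]
  dx[oi, ej, ] <- dx[oi, ej, ] + dout * fw$masks[[3]]
  dx[ei, ej, ] <- dx[ei, ej, ] + dout * fw$masks[[4]]
  dx
}

# One-step GRU direction: zero initial state, so h = z * candidate and the
# reset gate / recurrent kernels cannot influence the output. Input kernels
# for all three gates are allocated to keep the standard parameterisation;
# the reset-gate kernel receives an exactly-zero gradient.
gru_dir_forward <- function(x, p) {
  z <- sigmoid(as.vector(x %*% p$Wz) + p$bz)
  cc <- tanh(as.vector(x %*% p$Wc) + p$bc)
  list(h = z * cc, z = z, cc = cc, x = x)
}

gru_dir_backward <- function(dh, fw, p) {
  dz <- dh * fw$cc
  dcc <- dh * fw$z
  dpz <- dz * fw$z * (1 - fw$z)
  dpc <- dcc * (1 - fw$cc^2)
  list(dWz = outer(fw$x, dpz), dbz = dpz,
       dWc = outer(fw$x, dpc), dbc = dpc,
       dWr = p$Wr * 0, dbr = p$br * 0,
       dx = as.vector(p$Wz %*% dpz) + as.vector(p$Wc %*% dpc))
}

# Affine-free instance normalisation: each channel of one sample is
# standardised over its spatial extent. Uses the same statistics at train
# and inference time, so it is deterministic and batch-free.
instnorm_forward <- function(x, eps = 1e-5) {
  d <- dim(x)
  n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  mu <- colMeans(xm)
  v <- colMeans(xm^2) - mu^2
  sd_c <- sqrt(v + eps)
  xhat <- (xm - rep(mu, each = n)) / rep(sd_c, each = n)
  list(out = array(xhat, d), xhat = xhat, sd = sd_c, n = n)
}

instnorm_backward <- function(dout, fw) {
  d <- dim(dout)
  dym <- matrix(dout, fw$n, d[3])
  m1 <- colMeans(dym)
  m2 <- colMeans(dym * fw$xhat)
  dx <- (dym - rep(m1, each = fw$n) - fw$xhat * rep(m2, each = fw$n)) /
    rep(fw$sd, each = fw$n)
  array(dx, d)
}

dropout_mask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}

# ---- initialisers ------------------------------------------------------

init_he <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

init_glorot <- function(fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
}

init_gru_dir <- function(d_in, units) {
  list(Wz = init_glorot(d_in, units), bz = numeric(units),
       Wr = init_glorot(d_in, units), br = numeric(units),
       Wc = init_glorot(d_in, units), bc = numeric(units))
}

# ---- Adam --------------------------------------------------------------

adam_state <- function() new.env(parent = emptyenv())

# params/grads are flat named lists of numeric arrays; only `names_upd` move.
adam_step <- function(params, grads, state, names_upd, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- (if (is.null(state$t)) 0 else state$t) + 1
  b1t <- 1 - beta1^state$t
  b2t <- 1 - beta2^state$t
  for (nm in names_upd) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state[[nm]])) state[[nm]] <- list(m = g * 0, v = g * 0)
    s <- state[[nm]]
    s$m <- beta1 * s$m + (1 - beta1) * g
    s$v <- beta2 * s$v + (1 - beta2) * g^2
    state[[nm]] <- s
    params[[nm]] <- params[[nm]] - lr * (s$m / b1t) / (sqrt(s$v / b2t) + eps)
  }
  params
}
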