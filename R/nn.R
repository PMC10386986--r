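# Minimal dense/convolutional network machinery used by the tile classifier
# and the prognostic risk network. Batches are stored as N x (H*W*C)
# matrices in R array order (row fastest, then column, then channel);
# convolutions use im2col gathers so all heavy work is BLAS matrix products.

# ---- squeeze-and-excitation (single feature map, exported surface) --------

#' Channel squeeze: global average per channel
#' @param x H x W x C numeric array.
#' @return Numeric vector of length C (channel means).
#' @export
se_squeeze <- function(x) {
  stopifnot(length(dim(x)) == 3)
  apply(x, 3, mean)
}

#' Squeeze-and-excitation block
#'
#' Channel attention: the squeeze is the global average per channel; the
#' excitation is a two-layer bottleneck `C -> C/reduction -> C` (ReLU then
#' sigmoid) whose output gates each channel multiplicatively.
#'
#' @param x H x W x C numeric array.
#' @param reduction Bottleneck reduction ratio (>= 1, <= C).
#' @param weights List with `W1` (C x Cr), `b1` (Cr), `W2` (Cr x C),
#'   `b2` (C); if `NULL`, He-initialized deterministically from `seed`.
#' @param seed Seed for default weight initialization.
#' @return Array like `x`, each channel scaled by its gate; the gate is
#'   attached as attribute `"gate"`.
#' @export
se_block <- function(x, reduction, weights = NULL, seed = 1L) {
  stopifnot(length(dim(x)) == 3)
  C <- dim(x)[3]
  if (reduction > C) stop("reduction (", reduction, ") exceeds channels (",
                          C, ")")
  cr <- max(1L, as.integer(floor(C / reduction)))
  if (is.null(weights)) {
    weights <- withr_seed(seed, list(
      W1 = matrix(stats::rnorm(C * cr, sd = sqrt(2 / C)), C, cr),
      b1 = rep(0, cr),
      W2 = matrix(stats::rnorm(cr * C, sd = sqrt(2 / cr)), cr, C),
      b2 = rep(0, C)))
  }
  s <- se_squeeze(x)
  h1 <- pmax(drop(s %*% weights$W1) + weights$b1, 0)
  gate <- 1 / (1 + exp(-(drop(h1 %*% weights$W2) + weights$b2)))
  out <- x
  for (c in seq_len(C)) out[, , c] <- x[, , c] * gate[c]
  attr(out, "gate") <- gate
  out
}

# ---- batched layer primitives --------------------------------------------

# Precompute im2col gather indices for a 3x3 convolution with padding 1.
conv_geom <- function(H, W, C, K = 3L, stride = 1L, pad = 1L) {
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (H + 2L * pad - K) %/% stride + 1L
  Wo <- (W + 2L * pad - K) %/% stride + 1L
  P <- Ho * Wo
  kkc <- K * K * C
  idx <- integer(kkc * P)
  pos <- 0L
  for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
    # column for output position (ho, wo); ho fastest overall => pos order
    base <- pos * kkc
    ent <- 0L
    for (c in seq_len(C)) for (kc in seq_len(K)) for (kr in seq_len(K)) {
      r <- (ho - 1L) * stride + kr
      cc <- (wo - 1L) * stride + kc
      idx[base + ent + 1L] <- (c - 1L) * Hp * Wp + (cc - 1L) * Hp + r
      ent <- ent + 1L
    }
    pos <- pos + 1L
  }
  # interior (unpadded) positions within the padded vector
  interior <- integer(H * W * C)
  k <- 0L
  for (c in seq_len(C)) for (w in seq_len(W)) for (h in seq_len(H)) {
    k <- k + 1L
    interior[k] <- (c - 1L) * Hp * Wp + (w + pad - 1L) * Hp + (h + pad)
  }
  list(H = H, W = W, C = C, K = K, stride = stride, pad = pad,
       Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo, P = P, kkc = kkc,
       gather = idx, interior = interior,
       scatter_groups = sort(unique(idx)))
}

conv_fw <- function(X, Wt, b, geom) {
  N <- nrow(X)
  Xp <- matrix(0, N, geom$Hp * geom$Wp * geom$C)
  Xp[, geom$interior] <- X
  G <- Xp[, geom$gather, drop = FALSE]
  arr <- array(G, c(N, geom$kkc, geom$P))
  Pm <- matrix(aperm(arr, c(1, 3, 2)), N * geom$P, geom$kkc)
  Y <- Pm %*% Wt
  Y <- sweep(Y, 2, b, "+")
  out <- matrix(Y, N, geom$P * ncol(Wt))
  list(out = out, Pm = Pm)
}

conv_bw <- function(dOut, Wt, geom, Pm) {
  N <- nrow(dOut)
  Cout <- ncol(Wt)
  dY <- matrix(array(dOut, c(N, geom$P, Cout)), N * geom$P, Cout)
  dW <- crossprod(Pm, dY)
  db <- colSums(dY)
  dPm <- dY %*% t(Wt)
  arr <- array(dPm, c(N, geom$P, geom$kkc))
  dG <- matrix(aperm(arr, c(1, 3, 2)), N, geom$kkc * geom$P)
  sums <- rowsum(t(dG), group = geom$gather)       # |unique| x N
  dXp <- matrix(0, N, geom$Hp * geom$Wp * geom$C)
  dXp[, geom$scatter_groups] <- t(sums)
  list(dX = dXp[, geom$interior, drop = FALSE], dW = dW, db = db)
}

# 2x2 average pooling (stride 2); H and W must be even.
pool_geom <- function(H, W, C) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  n <- Ho * Wo * C
  i <- matrix(0L, n, 4)
  k <- 0L
  for (c in seq_len(C)) for (wo in seq_len(Wo)) for (ho in seq_len(Ho)) {
    k <- k + 1L
    h <- 2L * ho - 1L; w <- 2L * wo - 1L
    base <- (c - 1L) * H * W
    i[k, ] <- base + c((w - 1L) * H + h, (w - 1L) * H + h + 1L,
                       w * H + h, w * H + h + 1L)
  }
  list(idx = i, H = H, W = W, C = C, Ho = Ho, Wo = Wo)
}

pool_fw <- function(X, pg) {
  (X[, pg$idx[, 1], drop = FALSE] + X[, pg$idx[, 2], drop = FALSE] +
   X[, pg$idx[, 3], drop = FALSE] + X[, pg$idx[, 4], drop = FALSE]) / 4
}

pool_bw <- function(dOut, pg) {
  dX <- matrix(0, nrow(dOut), pg$H * pg$W * pg$C)
  for (j in 1:4) dX[, pg$idx[, j]] <- dOut / 4
  dX
}

gap_fw <- function(X, HW, C) {
  out <- matrix(0, nrow(X), C)
  for (c in seq_len(C)) {
    out[, c] <- rowMeans(X[, ((c - 1) * HW + 1):(c * HW), drop = FALSE])
  }
  out
}

gap_bw <- function(dOut, HW, C) {
  dX <- matrix(0, nrow(dOut), HW * C)
  for (c in seq_len(C)) {
    dX[, ((c - 1) * HW + 1):(c * HW)] <- dOut[, c] / HW
  }
  dX
}

relu_fw <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Batched SE over N x (HW*C); returns out plus backward cache.
se_fw <- function(X, p, HW, C) {
  s <- gap_fw(X, HW, C)
  z1 <- sweep(s %*% p$W1, 2, p$b1, "+")
  h1 <- relu_fw(z1)
  gate <- sigmoid(sweep(h1 %*% p$W2, 2, p$b2, "+"))
  out <- X
  for (c in seq_len(C)) {
    cols <- ((c - 1) * HW + 1):(c * HW)
    out[, cols] <- X[, cols] * gate[, c]
  }
  list(out = out, s = s, h1 = h1, gate = gate)
}

se_bw <- function(dOut, X, p, cache, HW, C) {
  gate <- cache$gate
  dgate <- matrix(0, nrow(X), C)
  dX <- dOut
  for (c in seq_len(C)) {
    cols <- ((c - 1) * HW + 1):(c * HW)
    dgate[, c] <- rowSums(dOut[, cols, drop = FALSE] *
                          X[, cols, drop = FALSE])
    dX[, cols] <- dOut[, cols] * gate[, c]
  }
  dz2 <- dgate * gate * (1 - gate)
  dW2 <- crossprod(cache$h1, dz2)
  db2 <- colSums(dz2)
  dh1 <- dz2 %*% t(p$W2)
  dz1 <- dh1 * (cache$h1 > 0)
  dW1 <- crossprod(cache$s, dz1)
  db1 <- colSums(dz1)
  ds <- dz1 %*% t(p$W1)
  for (c in seq_len(C)) {
    cols <- ((c - 1) * HW + 1):(c * HW)
    dX[, cols] <- dX[, cols] + ds[, c] / HW
  }
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

he_mat <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
}
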