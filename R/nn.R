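# Minimal dense/conv neural-network machinery with explicit backward
# passes. Everything here is internal: layers operate on plain arrays and
# matrices so the whole model stays differentiable down to the sub-band
# filter parameters.
#
# Layout conventions:
#   images     : array (H, W, N, C), column-major, channel LAST so that
#                the im2col output needs no transposition
#   features   : matrix (N, D)
#   conv weight: matrix (9*C_in, C_out); row (c-1)*9 + k corresponds to
#                input channel c and kernel offset k = 1 + di + 3*dj,
#                di, dj in 0..2 (3x3 kernels, zero padding 1)

.nn_cache <- new.env(parent = emptyenv())

# im2col index matrix for a 3x3/pad-1 convolution on (H, W, N, C) input.
# Element (r, col) of the returned integer matrix indexes the padded
# (H+2, W+2, N, C) array feeding output position r = pos + (n-1)*H*W and
# column col = (c-1)*9 + k. Within any fixed kernel offset k the indices
# are unique, which the backward scatter relies on.
.im2col_idx <- function(H, W, C, N) {
  key <- paste(H, W, C, N, sep = "x")
  hit <- .nn_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L; Wp <- W + 2L
  HW <- H * W
  i <- rep(seq_len(H), times = W)
  j <- rep(seq_len(W), each = H)
  P <- matrix(0L, HW, 9L)
  for (dj in 0:2) for (di in 0:2) {
    P[, 1L + di + 3L * dj] <- (i + di) + (j + dj - 1L) * Hp
  }
  plane <- Hp * Wp
  noff <- rep((seq_len(N) - 1L) * plane, each = HW)   # per-image offset
  idx <- matrix(0L, HW * N, 9L * C)
  for (c in seq_len(C)) {
    coff <- (c - 1L) * plane * N
    for (k in 1:9) {
      idx[, (c - 1L) * 9L + k] <- rep(P[, k], times = N) + noff + coff
    }
  }
  if (length(ls(.nn_cache)) > 12L) rm(list = ls(.nn_cache), envir = .nn_cache)
  .nn_cache[[key]] <- idx
  idx
}

.conv_forward <- function(X, Wmat, b) {
  d <- dim(X); H <- d[1L]; W <- d[2L]; N <- d[3L]; C <- d[4L]
  Xp <- array(0, dim = c(H + 2L, W + 2L, N, C))
  Xp[2:(H + 1L), 2:(W + 1L), , ] <- X
  idx <- .im2col_idx(H, W, C, N)
  colmat <- Xp[idx]
  dim(colmat) <- dim(idx)
  Y <- colmat %*% Wmat
  Y <- sweep(Y, 2L, b, `+`)
  dim(Y) <- c(H, W, N, length(b))
  list(out = Y, colmat = colmat, dims = d)
}

.conv_backward <- function(dY, cache, Wmat) {
  d <- cache$dims; H <- d[1L]; W <- d[2L]; N <- d[3L]; C <- d[4L]
  Cout <- dim(dY)[4L]
  dYmat <- dY
  dim(dYmat) <- c(H * W * N, Cout)
  dW <- crossprod(cache$colmat, dYmat)
  db <- colSums(dYmat)
  dcol <- tcrossprod(dYmat, Wmat)        # (HWN) x (9C)
  dXp <- numeric((H + 2L) * (W + 2L) * C * N)
  idx <- .im2col_idx(H, W, C, N)
  for (k in 1:9) {
    cols <- (seq_len(C) - 1L) * 9L + k   # unique indices for fixed k
    ii <- as.vector(idx[, cols])
    dXp[ii] <- dXp[ii] + as.vector(dcol[, cols])
  }
  dim(dXp) <- c(H + 2L, W + 2L, N, C)
  list(dX = dXp[2:(H + 1L), 2:(W + 1L), , , drop = FALSE], dW = dW, db = db)
}

.pool_forward <- function(X) {
  d <- dim(X); Ho <- d[1L] %/% 2L; Wo <- d[2L] %/% 2L
  o1 <- seq(1L, 2L * Ho, by = 2L); o2 <- o1 + 1L
  c1 <- seq(1L, 2L * Wo, by = 2L); c2 <- c1 + 1L
  Y <- (X[o1, c1, , , drop = FALSE] + X[o2, c1, , , drop = FALSE] +
        X[o1, c2, , , drop = FALSE] + X[o2, c2, , , drop = FALSE]) / 4
  list(out = Y, in_dim = d)
}

.pool_backward <- function(dY, cache) {
  d <- cache$in_dim
  dX <- array(0, dim = d)
  Ho <- dim(dY)[1L]; Wo <- dim(dY)[2L]
  o1 <- seq(1L, 2L * Ho, by = 2L); o2 <- o1 + 1L
  c1 <- seq(1L, 2L * Wo, by = 2L); c2 <- c1 + 1L
  q <- dY / 4
  dX[o1, c1, , ] <- q; dX[o2, c1, , ] <- q
  dX[o1, c2, , ] <- q; dX[o2, c2, , ] <- q
  dX
}

.gap_forward <- function(X) {
  d <- dim(X); HW <- d[1L] * d[2L]
  Xm <- X; dim(Xm) <- c(HW, d[3L] * d[4L])
  list(out = matrix(colMeans(Xm), nrow = d[3L], ncol = d[4L]),  # N x C
       in_dim = d)
}

.gap_backward <- function(dF, cache) {
  d <- cache$in_dim; HW <- d[1L] * d[2L]
  array(rep(as.vector(dF) / HW, each = HW), dim = d)
}

.relu_forward <- function(X) {
  mask <- X > 0
  list(out = X * mask, mask = mask)
}

.bn_forward <- function(X, gamma, beta, running, train, momentum = 0.1,
                        eps = 1e-5) {
  if (train) {
    mu <- colMeans(X)
    xc <- sweep(X, 2L, mu)
    v <- colMeans(xc^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    xc <- sweep(X, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  Y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  list(out = Y, xhat = xhat, inv_sd = inv_sd, running = running)
}

.bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dxhat <- sweep(dY, 2L, gamma, `*`)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * cache$xhat)
  dX <- sweep(dxhat, 2L, s1 / n) - sweep(cache$xhat, 2L, s2 / n, `*`)
  dX <- sweep(dX, 2L, cache$inv_sd, `*`)
  list(dX = dX,
       dgamma = colSums(dY * cache$xhat),
       dbeta = colSums(dY))
}

.l2norm_forward <- function(V) {
  nrm <- sqrt(rowSums(V^2)) + 1e-12
  list(out = V / nrm, nrm = nrm)
}

.l2norm_backward <- function(dZ, cache) {
  Z <- cache$out
  (dZ - Z * rowSums(dZ * Z)) / cache$nrm
}

# Adam optimizer state and update. `lr` is a named list mapping each
# parameter name to its learning rate (per-group rates).
.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr[[nm]] * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
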