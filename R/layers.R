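# Internal layer primitives for the 1-D network.
#
# A batch of feature maps is a (B*T) x C matrix in sample-major row order
# (sample 1 occupies rows 1..T). Every forward returns what its matching
# backward needs; backward returns gradients with the same shapes as the
# inputs. All heavy lifting is im2col + BLAS matrix multiplication.

bcast_row <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

# Row indices of the time-shifted copy of a (B*T)-row map; out-of-range
# positions point at row B*T + 1 (an appended zero/-Inf row).
shift_index <- function(B, T, d) {
  t <- rep(seq_len(T), times = B) + d
  off <- rep((seq_len(B) - 1L) * T, each = T)
  idx <- t + off
  idx[t < 1L | t > T] <- B * T + 1L
  as.integer(idx)
}

## ---- convolution (length-preserving, odd kernel, zero padding) ----

conv1d_forward <- function(X, W, b, B, T) {
  C_in <- ncol(X)
  k <- nrow(W) %/% C_in
  half <- (k - 1L) %/% 2L
  if (nrow(X) == 0) stop_invalid("zero-length feature map")
  Xz <- rbind(X, 0)
  n <- B * T
  cols <- matrix(0, n, k * C_in)
  idxs <- vector("list", k)
  for (q in seq_len(k)) {
    idx <- shift_index(B, T, q - 1L - half)
    idxs[[q]] <- idx
    cols[, ((q - 1L) * C_in + 1L):(q * C_in)] <- Xz[idx, , drop = FALSE]
  }
  Y <- cols %*% W
  if (!is.null(b)) Y <- Y + bcast_row(b, n)    # NULL: BN follows, bias inert
  list(Y = Y, cols = cols, idxs = idxs, C_in = C_in, k = k,
       has_bias = !is.null(b))
}

conv1d_backward <- function(dY, cache, W) {
  dW <- crossprod(cache$cols, dY)
  db <- if (cache$has_bias) colSums(dY)
  dcols <- dY %*% t(W)
  n <- nrow(dY)
  dX <- matrix(0, n + 1L, cache$C_in)  # last row absorbs padding positions
  for (q in seq_len(cache$k)) {
    block <- dcols[, ((q - 1L) * cache$C_in + 1L):(q * cache$C_in),
                   drop = FALSE]
    idx <- cache$idxs[[q]]
    dX[idx, ] <- dX[idx, , drop = FALSE] + block
  }
  list(dX = dX[seq_len(n), , drop = FALSE], dW = dW, db = db)
}

## ---- batch normalization (per channel over batch x time) ----

bn_forward <- function(X, gamma, beta, rm, rv, training,
                       momentum = 0.1, eps = 1e-5) {
  n <- nrow(X)
  if (training) {
    mu <- colMeans(X)
    va <- colMeans(X * X) - mu^2       # biased variance, standard for BN
    va <- pmax(va, 0)
    rm <- (1 - momentum) * rm + momentum * mu
    rv <- (1 - momentum) * rv + momentum * va
  } else {
    mu <- rm; va <- rv
  }
  inv_sd <- 1 / sqrt(va + eps)
  xhat <- (X - bcast_row(mu, n)) * bcast_row(inv_sd, n)
  Y <- xhat * bcast_row(gamma, n) + bcast_row(beta, n)
  list(Y = Y, xhat = xhat, inv_sd = inv_sd, rm = rm, rv = rv,
       training = training)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * bcast_row(gamma, n)
  if (cache$training) {
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * cache$xhat)
    dX <- bcast_row(cache$inv_sd, n) *
      (dxhat - bcast_row(m1, n) - cache$xhat * bcast_row(m2, n))
  } else {
    dX <- dxhat * bcast_row(cache$inv_sd, n)
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

## ---- activations ----

relu_forward <- function(X) list(Y = pmax(X, 0), mask = X > 0)
relu_backward <- function(dY, cache) dY * cache$mask
sigmoid <- function(z) 1 / (1 + exp(-z))

## ---- max pooling, kernel 2 stride 2 (halves the time axis) ----

maxpool_forward <- function(X, B, T) {
  if (T %% 2L) stop_invalid("max pooling needs an even map length, got ", T)
  o <- seq(1L, B * T, by = 2L)
  Xo <- X[o, , drop = FALSE]
  Xe <- X[o + 1L, , drop = FALSE]
  take_o <- Xo >= Xe                   # ties go to the earlier sample
  Y <- Xe
  Y[take_o] <- Xo[take_o]
  list(Y = Y, take_o = take_o)
}

maxpool_backward <- function(dY, cache) {
  n2 <- nrow(dY)
  dX <- matrix(0, 2L * n2, ncol(dY))
  o <- seq(1L, 2L * n2, by = 2L)
  dX[o, ] <- dY * cache$take_o
  dX[o + 1L, ] <- dY * !cache$take_o
  dX
}

## ---- nearest-neighbour up-sampling (doubles the time axis) ----

upsample_forward <- function(X) X[rep(seq_len(nrow(X)), each = 2L), ,
                                  drop = FALSE]

upsample_backward <- function(dY) {
  o <- seq(1L, nrow(dY), by = 2L)
  dY[o, , drop = FALSE] + dY[o + 1L, , drop = FALSE]
}

## ---- max pooling, kernel 3 stride 1, length-preserving (inception) ----

maxpool3_forward <- function(X, B, T) {
  n <- B * T
  Xpad <- rbind(X, -Inf)
  idx <- lapply(c(-1L, 0L, 1L), function(d) shift_index(B, T, d))
  A <- Xpad[idx[[1]], , drop = FALSE]
  Bm <- Xpad[idx[[2]], , drop = FALSE]
  Cm <- Xpad[idx[[3]], , drop = FALSE]
  Y <- pmax(A, Bm, Cm)
  t1 <- A >= Bm & A >= Cm
  t2 <- !t1 & Bm >= Cm
  t3 <- !(t1 | t2)
  list(Y = Y, idx = idx, picks = list(t1, t2, t3))
}

maxpool3_backward <- function(dY, cache) {
  n <- nrow(dY)
  dX <- matrix(0, n + 1L, ncol(dY))
  for (q in 1:3) {
    contrib <- dY * cache$picks[[q]]
    idx <- cache$idx[[q]]
    dX[idx, ] <- dX[idx, , drop = FALSE] + contrib
  }
  dX[seq_len(n), , drop = FALSE]
}

## ---- global average pooling over time ----

gap_forward <- function(X, B, T) {
  g <- rep(seq_len(B), each = T)
  rowsum(X, g) / T
}

gap_backward <- function(dF, B, T) {
  dF[rep(seq_len(B), each = T), , drop = FALSE] / T
}

## ---- squeeze-and-excitation gate ----

se_forward <- function(X, W1, b1, W2, b2, B, T) {
  S <- gap_forward(X, B, T)                       # squeeze: B x C
  Z1 <- S %*% W1 + bcast_row(b1, B)               # bottleneck
  A1 <- pmax(Z1, 0)
  Z2 <- A1 %*% W2 + bcast_row(b2, B)
  G <- sigmoid(Z2)                                # gate in (0,1), B x C
  gidx <- rep(seq_len(B), each = T)
  Y <- X * G[gidx, , drop = FALSE]
  list(Y = Y, S = S, Z1 = Z1, A1 = A1, G = G, gidx = gidx)
}

se_backward <- function(dY, X, cache, W1, W2, B, T) {
  Gexp <- cache$G[cache$gidx, , drop = FALSE]
  dX <- dY * Gexp
  dG <- rowsum(dY * X, cache$gidx)
  dZ2 <- dG * cache$G * (1 - cache$G)
  dW2 <- crossprod(cache$A1, dZ2)
  db2 <- colSums(dZ2)
  dA1 <- dZ2 %*% t(W2)
  dZ1 <- dA1 * (cache$Z1 > 0)
  dW1 <- crossprod(cache$S, dZ1)
  db1 <- colSums(dZ1)
  dS <- dZ1 %*% t(W1)
  dX <- dX + gap_backward(dS, B, T)
  list(dX = dX, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}
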