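#' Network architecture configuration
#'
#' All architecture hyperparameters of the 1-D UNet++ classifier. The
#' defaults follow the reference design: encoder depth 4 with channel widths
#' doubling from 16 to 256, length-preserving convolutions of width 3,
#' max-pooling by 2 for down-sampling, nearest-neighbour doubling for
#' up-sampling, squeeze-and-excitation residual blocks with reduction ratio
#' 16, and a global-average-pooling head with one logistic output unit.
#'
#' @param depth Encoder depth `L` (number of down-sampling stages).
#' @param channels Channel widths per pyramid level, length `depth + 1`.
#' @param kernel Convolution kernel width (odd).
#' @param se_ratio Squeeze-and-excitation bottleneck reduction ratio.
#' @param block Convolution block kind: `"se_residual"` (default),
#'   `"residual"`, or `"inception"`.
#' @return A list of class `network_config`.
#' @examples
#' network_config(depth = 2, channels = c(8, 16, 32))
#' @export
network_config <- function(depth = 4L,
                           channels = c(16L, 32L, 64L, 128L, 256L),
                           kernel = 3L, se_ratio = 16L,
                           block = c("se_residual", "residual",
                                     "inception")) {
  block <- match.arg(block)
  if (depth < 1 || depth != round(depth))
    stop_invalid("depth must be an integer >= 1")
  if (length(channels) != depth + 1)
    stop_invalid("channels must have length depth + 1 (one per level)")
  if (any(channels < 1)) stop_invalid("channel counts must be >= 1")
  if (kernel %% 2 != 1 || kernel < 1)
    stop_invalid("kernel width must be odd and positive")
  structure(list(depth = as.integer(depth), channels = as.integer(channels),
                 kernel = as.integer(kernel), se_ratio = as.integer(se_ratio),
                 block = block),
            class = "network_config")
}

node_key <- function(i, j) sprintf("n%d_%d", i, j)

# Channel count entering node X(i, j)'s block.
node_in_channels <- function(cfg, i, j) {
  ch <- cfg$channels
  if (i == 0 && j == 0) return(1L)
  if (j == 0) return(ch[i])                 # down-sampled X(i-1,0)
  j * ch[i + 1] + ch[i + 2]                 # skips + up-sampled map
}

# Initialize all trainable state; fully determined by `seed`.
network_init <- function(cfg, seed = 1L) {
  grid <- build_topology(cfg$depth)
  with_seed(seed, {
    blocks <- list()
    for (r in seq_len(nrow(grid$nodes))) {
      i <- grid$nodes$i[r]; j <- grid$nodes$j[r]
      blocks[[node_key(i, j)]] <-
        block_init(cfg$block, node_in_channels(cfg, i, j),
                   cfg$channels[i + 1], cfg$kernel, cfg$se_ratio)
    }
    C0 <- cfg$channels[1]
    head <- list(W = matrix(stats::rnorm(C0, 0, sqrt(1 / C0)), C0, 1),
                 b = 0)
    list(cfg = cfg, grid = grid, blocks = blocks, head = head)
  })
}

# Forward pass over a batch. `Xb` is a B x M matrix of padded segments.
# Returns scores, per-node caches (for backward) and the model with BN
# running statistics advanced when `training`.
network_forward <- function(model, Xb, training = TRUE,
                            keep_cache = training, bn_momentum = 0.1) {
  cfg <- model$cfg
  B <- nrow(Xb); M <- ncol(Xb); L <- cfg$depth
  if (M %% (2L^L) != 0)
    stop_invalid("input length ", M, " is not a multiple of 2^depth = ", 2^L)
  maps <- list(); caches <- list(); pool_caches <- list()
  nodes <- model$grid$nodes
  Xin <- matrix(as.vector(t(Xb)), ncol = 1)    # sample-major (B*M) x 1
  for (r in seq_len(nrow(nodes))) {
    i <- nodes$i[r]; j <- nodes$j[r]
    Ti <- M %/% (2L^i)
    key <- node_key(i, j)
    if (i == 0 && j == 0) {
      inp <- Xin
    } else if (j == 0) {
      mp <- maxpool_forward(maps[[node_key(i - 1, 0)]], B, 2L * Ti)
      pool_caches[[key]] <- mp
      inp <- mp$Y
    } else {
      skips <- lapply(0:(j - 1), function(k) maps[[node_key(i, k)]])
      up <- upsample_forward(maps[[node_key(i + 1, j - 1)]])
      inp <- do.call(cbind, c(skips, list(up)))
    }
    bf <- block_forward(model$blocks[[key]], inp, B, Ti, training,
                        bn_momentum = bn_momentum)
    model$blocks[[key]] <- bf$par
    maps[[key]] <- bf$Y
    if (keep_cache) caches[[key]] <- bf$cache
  }
  Fmat <- gap_forward(maps[[node_key(0, L)]], B, M)
  z <- Fmat %*% model$head$W + model$head$b
  p <- sigmoid(as.vector(z))
  list(scores = p, model = model,
       cache = if (keep_cache)
         list(maps = maps, caches = caches, pool_caches = pool_caches,
              Fmat = Fmat, p = p, B = B, M = M))
}

# Backward pass for the (optionally sample-weighted) mean-squared-error
# objective; returns gradients for every trainable parameter, keyed like
# the model.
network_backward <- function(model, fwd, y, weights = NULL) {
  cfg <- model$cfg; L <- cfg$depth
  cache <- fwd$cache
  B <- cache$B; M <- cache$M
  p <- cache$p
  dz <- (2 / B) * (p - y) * p * (1 - p)        # d(mean (y-p)^2) / dz
  if (!is.null(weights)) dz <- dz * weights
  grads <- list(head = list(
    W = crossprod(cache$Fmat, dz), b = sum(dz)))
  dmap <- list()
  dmap[[node_key(0, L)]] <- gap_backward(dz %*% t(model$head$W), B, M)

  nodes <- model$grid$nodes
  for (r in rev(seq_len(nrow(nodes)))) {
    i <- nodes$i[r]; j <- nodes$j[r]
    key <- node_key(i, j)
    dY <- dmap[[key]]
    if (is.null(dY)) next                       # node unused by the head? no:
    bb <- block_backward(model$blocks[[key]], cache$caches[[key]], dY)
    grads[[key]] <- bb$grads
    dIn <- bb$dX
    if (i == 0 && j == 0) next
    if (j == 0) {
      dPrev <- maxpool_backward(dIn, cache$pool_caches[[key]])
      pk <- node_key(i - 1, 0)
      dmap[[pk]] <- (dmap[[pk]] %||% 0) + dPrev
    } else {
      ch <- cfg$channels[i + 1]
      for (k in 0:(j - 1)) {
        cols <- (k * ch + 1):((k + 1) * ch)
        sk <- node_key(i, k)
        dmap[[sk]] <- (dmap[[sk]] %||% 0) +
          dIn[, cols, drop = FALSE]
      }
      up_cols <- (j * ch + 1):ncol(dIn)
      uk <- node_key(i + 1, j - 1)
      dmap[[uk]] <- (dmap[[uk]] %||% 0) +
        upsample_backward(dIn[, up_cols, drop = FALSE])
    }
  }
  grads
}

#' Mean squared error between labels and prediction scores
#'
#' The training objective: `mean((y - p)^2)` over a batch of binary labels
#' and logistic prediction scores.
#'
#' @param y Binary labels (0/1).
#' @param p Prediction scores in `[0, 1]`.
#' @return Non-negative scalar; zero iff `y == p` elementwise.
#' @examples
#' mse_loss(c(1, 0), c(0, 1))  # 1
#' @export
mse_loss <- function(y, p) {
  if (!length(y) || length(y) != length(p))
    stop_invalid("y and p must be non-empty and of equal length")
  mean((y - p)^2)
}
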