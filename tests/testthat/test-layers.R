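# Internal numerics: these address chfnet's own layer implementations
# (reached via :::), which carry the whole network.

test_that("max pooling halves the axis by windowed maxima", {
  X <- matrix(c(1, 3, 2, 4), ncol = 1)
  mp <- chfnet:::maxpool_forward(X, B = 1L, T = 4L)
  expect_equal(as.vector(mp$Y), c(3, 4))
  expect_equal(nrow(chfnet:::maxpool_forward(matrix(rnorm(512), ncol = 1),
                                             1L, 512L)$Y), 256)
  expect_equal(nrow(chfnet:::maxpool_forward(matrix(c(5, 1), ncol = 1),
                                             1L, 2L)$Y), 1)
  expect_error(chfnet:::maxpool_forward(matrix(1:3, ncol = 1), 1L, 3L),
               "even")
})

test_that("up-sampling doubles the axis by nearest-neighbour repetition", {
  X <- matrix(c(1, 2), ncol = 1)
  expect_equal(as.vector(chfnet:::upsample_forward(X)), c(1, 1, 2, 2))
  expect_equal(nrow(chfnet:::upsample_forward(matrix(rnorm(256), ncol = 1))),
               512)
  expect_equal(as.vector(chfnet:::upsample_forward(matrix(7, 1, 1))), c(7, 7))
})

test_that("pooling and up-sampling backward passes route gradients", {
  X <- matrix(c(1, 3, 2, 4, 9, 0), ncol = 1)
  mp <- chfnet:::maxpool_forward(X, 1L, 6L)
  dX <- chfnet:::maxpool_backward(matrix(c(10, 20, 30), ncol = 1), mp)
  expect_equal(as.vector(dX), c(0, 10, 0, 20, 30, 0))
  dU <- chfnet:::upsample_backward(matrix(c(1, 2, 3, 4), ncol = 1))
  expect_equal(as.vector(dU), c(3, 7))
})

test_that("im2col convolution matches a naive sliding-window oracle", {
  set.seed(42)
  B <- 2L; T <- 9L; C_in <- 3L; C_out <- 2L; k <- 3L
  X <- matrix(rnorm(B * T * C_in), B * T, C_in)
  W <- matrix(rnorm(k * C_in * C_out), k * C_in, C_out)
  b <- rnorm(C_out)
  out <- chfnet:::conv1d_forward(X, W, b, B, T)$Y
  # oracle: direct loops over samples, positions and kernel taps; tap d
  # (-1, 0, 1) uses weight rows (d+1)*C_in + 1 .. (d+2)*C_in
  for (s in 1:B) for (t in 1:T) for (co in 1:C_out) {
    acc <- b[co]
    for (d in -1:1) {
      tt <- t + d
      if (tt >= 1 && tt <= T) {
        row <- (s - 1) * T + tt
        wrows <- (d + 1) * C_in + seq_len(C_in)
        acc <- acc + sum(X[row, ] * W[wrows, co])
      }
    }
    expect_equal(out[(s - 1) * T + t, co], acc, tolerance = 1e-12)
  }
})

test_that("batch normalization matches its closed form and running stats", {
  set.seed(3)
  X <- matrix(rnorm(40, 5, 2), 20, 2)
  g <- c(1.5, 0.7); be <- c(-1, 2)
  bn <- chfnet:::bn_forward(X, g, be, rm = c(0, 0), rv = c(1, 1),
                            training = TRUE, momentum = 0.1)
  mu <- colMeans(X); va <- colMeans(X^2) - mu^2
  want <- sweep(sweep(X, 2, mu), 2, sqrt(va + 1e-5), "/")
  want <- sweep(sweep(want, 2, g, "*"), 2, be, "+")
  expect_equal(bn$Y, want, tolerance = 1e-12)
  expect_equal(bn$rm, 0.1 * mu, tolerance = 1e-12)
  expect_equal(bn$rv, 0.9 + 0.1 * va, tolerance = 1e-12)
  # evaluation mode uses the supplied running stats, ignores the batch
  ev <- chfnet:::bn_forward(X, g, be, rm = mu, rv = va, training = FALSE)
  expect_equal(ev$Y, want, tolerance = 1e-12)
})

test_that("backprop matches central-difference gradients for every block", {
  set.seed(99)
  for (block in c("se_residual", "residual", "inception")) {
    cfg <- network_config(depth = 2, channels = c(3L, 4L, 5L), block = block)
    model <- chfnet:::network_init(cfg, seed = 7)
    B <- 3L; M <- 8L
    X <- matrix(rnorm(B * M, 0.8, 0.3), B, M)
    y <- c(1, 0, 1)
    lossf <- function(m)
      mse_loss(y, chfnet:::network_forward(m, X, training = TRUE)$scores)
    fwd <- chfnet:::network_forward(model, X, training = TRUE)
    gr <- chfnet:::network_backward(model, fwd, y)
    eps <- 1e-6
    n_checked <- 0L
    for (bk in names(gr)) {
      if (bk == "head") next
      for (pn in names(gr[[bk]])) {
        p <- model$blocks[[bk]][[pn]]
        for (ii in sample(length(p), min(3, length(p)))) {
          m1 <- model; m1$blocks[[bk]][[pn]][ii] <- p[ii] + eps
          m2 <- model; m2$blocks[[bk]][[pn]][ii] <- p[ii] - eps
          num <- (lossf(m1) - lossf(m2)) / (2 * eps)
          ana <- gr[[bk]][[pn]][ii]
          if (abs(num) + abs(ana) > 1e-7) {
            expect_equal(ana, num, tolerance = 1e-4,
                         label = sprintf("%s %s %s[%d]", block, bk, pn, ii))
            n_checked <- n_checked + 1L
          }
        }
      }
    }
    # the head too
    for (ii in seq_along(model$head$W)) {
      m1 <- model; m1$head$W[ii] <- m1$head$W[ii] + eps
      m2 <- model; m2$head$W[ii] <- m2$head$W[ii] - eps
      expect_equal(gr$head$W[ii], (lossf(m1) - lossf(m2)) / (2 * eps),
                   tolerance = 1e-4)
    }
    expect_gt(n_checked, 20)
  }
})
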