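# Convolution blocks: the H(.) unit placed at every UNet++ node.
#
# residual:    h1 = conv1(x); y = relu( h1 + BN2(conv2(relu(BN1(h1)))) )
#              -- the additive shortcut is taken from the first
#              convolution's output, so shortcut and branch channel counts
#              always agree.
# se_residual: the residual branch is rescaled per channel by a
#              squeeze-and-excitation gate before the addition.
# inception:   parallel length-preserving convolutions of widths 1/3/5 plus
#              a max-pooled branch, channel-concatenated and projected back
#              to the target width, then BN + relu.

init_conv_w <- function(k, C_in, C_out) {
  matrix(stats::rnorm(k * C_in * C_out, 0, sqrt(2 / (k * C_in))),
         k * C_in, C_out)
}

block_init <- function(kind, C_in, C_out, kernel = 3L, se_ratio = 16L) {
  kind <- match.arg(kind, c("se_residual", "residual", "inception"))
  p <- list(kind = kind, C_in = C_in, C_out = C_out, kernel = kernel)
  if (kind %in% c("se_residual", "residual")) {
    p$conv1_W <- init_conv_w(kernel, C_in, C_out)
    p$conv1_b <- numeric(C_out)
    p$bn1_gamma <- rep(1, C_out); p$bn1_beta <- numeric(C_out)
    p$bn1_rm <- numeric(C_out);   p$bn1_rv <- rep(1, C_out)
    p$conv2_W <- init_conv_w(kernel, C_out, C_out)  # no bias: BN follows
    p$bn2_gamma <- rep(1, C_out); p$bn2_beta <- numeric(C_out)
    p$bn2_rm <- numeric(C_out);   p$bn2_rv <- rep(1, C_out)
    if (kind == "se_residual") {
      Cr <- max(1L, C_out %/% se_ratio)
      p$se_W1 <- matrix(stats::rnorm(C_out * Cr, 0, sqrt(2 / C_out)),
                        C_out, Cr)
      p$se_b1 <- numeric(Cr)
      p$se_W2 <- matrix(stats::rnorm(Cr * C_out, 0, sqrt(1 / Cr)),
                        Cr, C_out)
      p$se_b2 <- numeric(C_out)
    }
  } else {
    for (k in c(1L, 3L, 5L)) {
      p[[paste0("br", k, "_W")]] <- init_conv_w(k, C_in, C_out)
      p[[paste0("br", k, "_b")]] <- numeric(C_out)
    }
    p$brp_W <- init_conv_w(1L, C_in, C_out)
    p$brp_b <- numeric(C_out)
    p$proj_W <- init_conv_w(1L, 4L * C_out, C_out)  # no bias: BN follows
    p$bn_gamma <- rep(1, C_out); p$bn_beta <- numeric(C_out)
    p$bn_rm <- numeric(C_out);   p$bn_rv <- rep(1, C_out)
  }
  p
}

block_param_names <- function(p) {
  if (p$kind == "inception") {
    c("br1_W", "br1_b", "br3_W", "br3_b", "br5_W", "br5_b",
      "brp_W", "brp_b", "proj_W", "bn_gamma", "bn_beta")
  } else {
    nm <- c("conv1_W", "conv1_b", "bn1_gamma", "bn1_beta",
            "conv2_W", "bn2_gamma", "bn2_beta")
    if (p$kind == "se_residual")
      nm <- c(nm, "se_W1", "se_b1", "se_W2", "se_b2")
    nm
  }
}

# gate_override = 1 freezes the SE gate at identity (diagnostic hook used
# to check the se_residual -> residual reduction).
block_forward <- function(p, X, B, T, training = TRUE, gate_override = NULL,
                          bn_momentum = 0.1) {
  if (nrow(X) == 0) stop_invalid("zero-length feature map")
  if (p$kind == "inception")
    return(incep_forward(p, X, B, T, training, bn_momentum))
  c1 <- conv1d_forward(X, p$conv1_W, p$conv1_b, B, T)
  bn1 <- bn_forward(c1$Y, p$bn1_gamma, p$bn1_beta, p$bn1_rm, p$bn1_rv,
                    training, bn_momentum)
  r1 <- relu_forward(bn1$Y)
  c2 <- conv1d_forward(r1$Y, p$conv2_W, NULL, B, T)
  bn2 <- bn_forward(c2$Y, p$bn2_gamma, p$bn2_beta, p$bn2_rm, p$bn2_rv,
                    training, bn_momentum)
  use_se <- p$kind == "se_residual" && is.null(gate_override)
  if (use_se) {
    se <- se_forward(bn2$Y, p$se_W1, p$se_b1, p$se_W2, p$se_b2, B, T)
    branch <- se$Y
  } else {
    se <- NULL
    branch <- bn2$Y
  }
  s <- c1$Y + branch
  out <- relu_forward(s)
  p$bn1_rm <- bn1$rm; p$bn1_rv <- bn1$rv
  p$bn2_rm <- bn2$rm; p$bn2_rv <- bn2$rv
  list(Y = out$Y, par = p,
       cache = list(c1 = c1, bn1 = bn1, r1 = r1, c2 = c2, bn2 = bn2,
                    se = se, use_se = use_se, out_mask = out$mask,
                    B = B, T = T))
}

block_backward <- function(p, cache, dY) {
  if (p$kind == "inception") return(incep_backward(p, cache, dY))
  ds <- dY * cache$out_mask
  if (cache$use_se) {
    seb <- se_backward(ds, cache$bn2$Y, cache$se, p$se_W1, p$se_W2,
                       cache$B, cache$T)
    dbranch <- seb$dX
  } else {
    dbranch <- ds
  }
  b2 <- bn_backward(dbranch, cache$bn2, p$bn2_gamma)
  cb2 <- conv1d_backward(b2$dX, cache$c2, p$conv2_W)
  da1 <- relu_backward(cb2$dX, cache$r1)
  b1 <- bn_backward(da1, cache$bn1, p$bn1_gamma)
  dh1 <- ds + b1$dX                      # shortcut + main branch
  cb1 <- conv1d_backward(dh1, cache$c1, p$conv1_W)
  g <- list(conv1_W = cb1$dW, conv1_b = cb1$db,
            bn1_gamma = b1$dgamma, bn1_beta = b1$dbeta,
            conv2_W = cb2$dW,
            bn2_gamma = b2$dgamma, bn2_beta = b2$dbeta)
  if (cache$use_se) {
    g$se_W1 <- seb$dW1; g$se_b1 <- seb$db1
    g$se_W2 <- seb$dW2; g$se_b2 <- seb$db2
  }
  list(dX = cb1$dX, grads = g)
}

incep_forward <- function(p, X, B, T, training, bn_momentum = 0.1) {
  b1 <- conv1d_forward(X, p$br1_W, p$br1_b, B, T)
  b3 <- conv1d_forward(X, p$br3_W, p$br3_b, B, T)
  b5 <- conv1d_forward(X, p$br5_W, p$br5_b, B, T)
  mp <- maxpool3_forward(X, B, T)
  bp <- conv1d_forward(mp$Y, p$brp_W, p$brp_b, B, T)
  r1 <- relu_forward(b1$Y); r3 <- relu_forward(b3$Y)
  r5 <- relu_forward(b5$Y); rp <- relu_forward(bp$Y)
  Z <- cbind(r1$Y, r3$Y, r5$Y, rp$Y)
  pr <- conv1d_forward(Z, p$proj_W, NULL, B, T)
  bn <- bn_forward(pr$Y, p$bn_gamma, p$bn_beta, p$bn_rm, p$bn_rv, training,
                   bn_momentum)
  out <- relu_forward(bn$Y)
  p$bn_rm <- bn$rm; p$bn_rv <- bn$rv
  list(Y = out$Y, par = p,
       cache = list(b1 = b1, b3 = b3, b5 = b5, mp = mp, bp = bp,
                    r1 = r1, r3 = r3, r5 = r5, rp = rp,
                    pr = pr, bn = bn, out_mask = out$mask, B = B, T = T))
}

incep_backward <- function(p, cache, dY) {
  dbn <- dY * cache$out_mask
  bb <- bn_backward(dbn, cache$bn, p$bn_gamma)
  pb <- conv1d_backward(bb$dX, cache$pr, p$proj_W)
  C <- p$C_out
  dZ <- pb$dX
  d1 <- relu_backward(dZ[, 1:C, drop = FALSE], cache$r1)
  d3 <- relu_backward(dZ[, (C + 1):(2 * C), drop = FALSE], cache$r3)
  d5 <- relu_backward(dZ[, (2 * C + 1):(3 * C), drop = FALSE], cache$r5)
  dp <- relu_backward(dZ[, (3 * C + 1):(4 * C), drop = FALSE], cache$rp)
  c1 <- conv1d_backward(d1, cache$b1, p$br1_W)
  c3 <- conv1d_backward(d3, cache$b3, p$br3_W)
  c5 <- conv1d_backward(d5, cache$b5, p$br5_W)
  cp <- conv1d_backward(dp, cache$bp, p$brp_W)
  dXp <- maxpool3_backward(cp$dX, cache$mp)
  list(dX = c1$dX + c3$dX + c5$dX + dXp,
       grads = list(br1_W = c1$dW, br1_b = c1$db,
                    br3_W = c3$dW, br3_b = c3$db,
                    br5_W = c5$dW, br5_b = c5$db,
                    brp_W = cp$dW, brp_b = cp$db,
                    proj_W = pb$dW,
                    bn_gamma = bb$dgamma, bn_beta = bb$dbeta))
}
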