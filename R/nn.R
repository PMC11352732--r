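# Minimal CPU convolutional-network engine used by the slice-to-map estimator.
# Tensors are (H, W, C, B) double arrays; 3x3 convolutions run through the
# compiled im2col/GEMM kernels in src/conv.cpp, everything else is vectorised R.

relu <- function(x) {
  x[x < 0] <- 0
  x
}

conv3x3 <- function(x, layer) {
  .cpp_conv3x3_fwd(x, dim(x), layer$W, layer$b)
}

conv3x3_bwd <- function(x, layer, dy) {
  .cpp_conv3x3_bwd(x, dim(x), layer$W, dy)
}

conv1x1 <- function(x, layer) {
  d <- dim(x)
  cout <- ncol(layer$W)
  y <- array(0, c(d[1], d[2], cout, d[4]))
  for (bi in seq_len(d[4])) {
    xm <- x[, , , bi]
    dim(xm) <- c(d[1] * d[2], d[3])
    y[, , , bi] <- xm %*% layer$W + rep(layer$b, each = d[1] * d[2])
  }
  y
}

conv1x1_bwd <- function(x, layer, dy) {
  d <- dim(x)
  cout <- ncol(layer$W)
  dx <- array(0, d)
  dW <- matrix(0, d[3], cout)
  db <- numeric(cout)
  for (bi in seq_len(d[4])) {
    xm <- x[, , , bi]; dim(xm) <- c(d[1] * d[2], d[3])
    dym <- dy[, , , bi]; dim(dym) <- c(d[1] * d[2], cout)
    dW <- dW + crossprod(xm, dym)
    db <- db + colSums(dym)
    dxm <- dym %*% t(layer$W)
    dx[, , , bi] <- array(dxm, c(d[1], d[2], d[3]))
  }
  list(dx = dx, dw = dW, db = db)
}

pool2_reduce <- function(x, op = pmax) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(2, d[1] / 2, d[2], d[3] * d[4])
  a <- op(xr[1, , , , drop = TRUE], xr[2, , , , drop = TRUE])
  dim(a) <- c(d[1] / 2, 2, d[2] / 2, d[3] * d[4])
  y <- op(a[, 1, , , drop = TRUE], a[, 2, , , drop = TRUE])
  dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
  y
}

maxpool2 <- function(x) pool2_reduce(x, pmax)
sumpool2 <- function(x) pool2_reduce(x, `+`)

upsample2 <- function(y) {
  d <- dim(y)
  y[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , ,
    drop = FALSE]
}

maxpool2_bwd <- function(x, y, dy) {
  mask <- (x == upsample2(y)) * 1
  cnt <- sumpool2(mask)
  mask * upsample2(dy / cnt)
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

split_ch <- function(x, ca) {
  list(x[, , seq_len(ca), , drop = FALSE],
       x[, , -seq_len(ca), , drop = FALSE])
}

init_conv <- function(cin, cout, k = 3L) {
  fan_in <- k * k * cin
  list(W = matrix(rnorm(k * k * cin * cout, sd = sqrt(2 / fan_in)),
                  k * k * cin, cout),
       b = numeric(cout))
}

# Encoder-decoder with 4 resolution levels (3 max-poolings), skip connections
# at every level, channel width doubling per level, and a linear 1x1 output.
unet_params <- function(n_in, n_out, base_width) {
  w <- base_width * c(1L, 2L, 4L, 8L)
  list(
    enc1a = init_conv(n_in, w[1]),        enc1b = init_conv(w[1], w[1]),
    enc2a = init_conv(w[1], w[2]),        enc2b = init_conv(w[2], w[2]),
    enc3a = init_conv(w[2], w[3]),        enc3b = init_conv(w[3], w[3]),
    bota  = init_conv(w[3], w[4]),        botb  = init_conv(w[4], w[4]),
    dec3a = init_conv(w[4] + w[3], w[3]), dec3b = init_conv(w[3], w[3]),
    dec2a = init_conv(w[3] + w[2], w[2]), dec2b = init_conv(w[2], w[2]),
    dec1a = init_conv(w[2] + w[1], w[1]), dec1b = init_conv(w[1], w[1]),
    out   = init_conv(w[1], n_out, k = 1L)
  )
}

n_params <- function(params) {
  sum(vapply(params, function(l) length(l$W) + length(l$b), numeric(1)))
}

conv_block <- function(x, la, lb, cache) {
  a1 <- relu(conv3x3(x, la))
  a2 <- relu(conv3x3(a1, lb))
  if (cache) list(out = a2, x = x, a1 = a1) else list(out = a2)
}

conv_block_bwd <- function(blk, la, lb, dout, grads, na, nb) {
  dout <- dout * (blk$out > 0)
  gb <- conv3x3_bwd(blk$a1, lb, dout)
  grads[[nb]] <- list(W = gb$dw, b = gb$db)
  da1 <- gb$dx * (blk$a1 > 0)
  ga <- conv3x3_bwd(blk$x, la, da1)
  grads[[na]] <- list(W = ga$dw, b = ga$db)
  list(dx = ga$dx, grads = grads)
}

unet_forward <- function(params, x, cache = FALSE) {
  d <- dim(x)
  check_that(d[1] %% 8 == 0 && d[2] %% 8 == 0,
             "input height/width must be divisible by 8")
  c1 <- conv_block(x, params$enc1a, params$enc1b, cache)
  p1 <- maxpool2(c1$out)
  c2 <- conv_block(p1, params$enc2a, params$enc2b, cache)
  p2 <- maxpool2(c2$out)
  c3 <- conv_block(p2, params$enc3a, params$enc3b, cache)
  p3 <- maxpool2(c3$out)
  cb <- conv_block(p3, params$bota, params$botb, cache)
  u3 <- concat_ch(upsample2(cb$out), c3$out)
  d3 <- conv_block(u3, params$dec3a, params$dec3b, cache)
  u2 <- concat_ch(upsample2(d3$out), c2$out)
  d2 <- conv_block(u2, params$dec2a, params$dec2b, cache)
  u1 <- concat_ch(upsample2(d2$out), c1$out)
  d1 <- conv_block(u1, params$dec1a, params$dec1b, cache)
  y <- conv1x1(d1$out, params$out)
  if (!cache) return(y)
  list(y = y, c1 = c1, p1 = p1, c2 = c2, p2 = p2, c3 = c3, p3 = p3,
       cb = cb, u3 = u3, d3 = d3, u2 = u2, d2 = d2, u1 = u1, d1 = d1)
}

unet_backward <- function(params, fw, dy) {
  grads <- vector("list", length(params))
  names(grads) <- names(params)

  go <- conv1x1_bwd(fw$d1$out, params$out, dy)
  grads$out <- list(W = go$dw, b = go$db)

  r <- conv_block_bwd(fw$d1, params$dec1a, params$dec1b, go$dx, grads,
                      "dec1a", "dec1b")
  grads <- r$grads
  s1 <- split_ch(r$dx, dim(fw$d2$out)[3])
  dd2 <- sumpool2(s1[[1]])
  dc1_skip <- s1[[2]]

  r <- conv_block_bwd(fw$d2, params$dec2a, params$dec2b, dd2, grads,
                      "dec2a", "dec2b")
  grads <- r$grads
  s2 <- split_ch(r$dx, dim(fw$d3$out)[3])
  dd3 <- sumpool2(s2[[1]])
  dc2_skip <- s2[[2]]

  r <- conv_block_bwd(fw$d3, params$dec3a, params$dec3b, dd3, grads,
                      "dec3a", "dec3b")
  grads <- r$grads
  s3 <- split_ch(r$dx, dim(fw$cb$out)[3])
  dcb <- sumpool2(s3[[1]])
  dc3_skip <- s3[[2]]

  r <- conv_block_bwd(fw$cb, params$bota, params$botb, dcb, grads,
                      "bota", "botb")
  grads <- r$grads
  dp3 <- r$dx

  dc3 <- maxpool2_bwd(fw$c3$out, fw$p3, dp3) + dc3_skip
  r <- conv_block_bwd(fw$c3, params$enc3a, params$enc3b, dc3, grads,
                      "enc3a", "enc3b")
  grads <- r$grads
  dp2 <- r$dx

  dc2 <- maxpool2_bwd(fw$c2$out, fw$p2, dp2) + dc2_skip
  r <- conv_block_bwd(fw$c2, params$enc2a, params$enc2b, dc2, grads,
                      "enc2a", "enc2b")
  grads <- r$grads
  dp1 <- r$dx

  dc1 <- maxpool2_bwd(fw$c1$out, fw$p1, dp1) + dc1_skip
  r <- conv_block_bwd(fw$c1, params$enc1a, params$enc1b, dc1, grads,
                      "enc1a", "enc1b")
  r$grads
}

adam_init <- function(params) {
  lapply(params, function(l) list(mW = l$W * 0, vW = l$W * 0,
                                  mb = l$b * 0, vb = l$b * 0))
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]; s <- state[[nm]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    params[[nm]]$W <- params[[nm]]$W - lr * (s$mW / bc1) /
      (sqrt(s$vW / bc2) + eps)
    params[[nm]]$b <- params[[nm]]$b - lr * (s$mb / bc1) /
      (sqrt(s$vb / bc2) + eps)
    state[[nm]] <- s
  }
  list(params = params, state = state)
}
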