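# Low-level network operations.
#
# Activations are numeric 4-D arrays with dim (H, W, C, N): column-major, so
# reshapes that split H or W into (2, H/2) blocks are free. All forward ops
# return a list(out = ..., cache = ...) and each backward op consumes its
# cache plus the upstream gradient; convolution is expressed as an im2col
# patch matrix times a (k*k*Cin) x Cout weight matrix so the heavy lifting
# is a single BLAS gemm per layer.

pad_hw <- function(x, p) {
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

# (H*W*N) x (k*k*Cin) patch matrix for a 3x3, pad-1, stride-1 convolution
im2col3 <- function(x) {
  d <- dim(x); h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  p <- pad_hw(x, 1L)
  cols <- matrix(0, h * w * n, 9L * cin)
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    block <- p[(1 + di):(h + di), (1 + dj):(w + dj), , , drop = FALSE]
    bp <- aperm(block, c(1, 2, 4, 3))
    dim(bp) <- c(h * w * n, cin)
    cols[, ((k - 1L) * cin + 1L):(k * cin)] <- bp
  }
  cols
}

# scatter-add of patch-matrix gradients back onto the (padded, then cropped) input
col2im3 <- function(dcols, h, w, cin, n) {
  dp <- array(0, c(h + 2L, w + 2L, cin, n))
  k <- 0L
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1L
    seg <- dcols[, ((k - 1L) * cin + 1L):(k * cin), drop = FALSE]
    dim(seg) <- c(h, w, n, cin)
    seg <- aperm(seg, c(1, 2, 4, 3))
    dp[(1 + di):(h + di), (1 + dj):(w + dj), , ] <-
      dp[(1 + di):(h + di), (1 + dj):(w + dj), , ] + seg
  }
  dp[2:(h + 1), 2:(w + 1), , , drop = FALSE]
}

conv3_forward <- function(x, weight, bias) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[4]
  cout <- length(bias)
  cols <- im2col3(x)
  outm <- sweep(cols %*% weight, 2L, bias, `+`)
  dim(outm) <- c(h, w, n, cout)
  list(out = aperm(outm, c(1, 2, 4, 3)),
       cache = list(cols = cols, dims = d, weight = weight))
}

conv3_backward <- function(dout, cache) {
  d <- cache$dims; h <- d[1]; w <- d[2]; cin <- d[3]; n <- d[4]
  dm <- aperm(dout, c(1, 2, 4, 3))
  dim(dm) <- c(h * w * n, dim(dout)[3])
  dweight <- crossprod(cache$cols, dm)
  dbias <- colSums(dm)
  dcols <- tcrossprod(dm, cache$weight)
  list(dx = col2im3(dcols, h, w, cin, n), dweight = dweight, dbias = dbias)
}

bn_forward <- function(x, gamma, beta, run_mean, run_var, training,
                       momentum = 0.1, eps = 1e-5) {
  d <- dim(x); m <- d[1] * d[2] * d[4]
  xp <- aperm(x, c(1, 2, 4, 3))
  dim(xp) <- c(m, d[3])
  if (training) {
    mu <- colMeans(xp)
    xc <- sweep(xp, 2L, mu)
    v <- colMeans(xc * xc)
    run_mean <- (1 - momentum) * run_mean + momentum * mu
    run_var <- (1 - momentum) * run_var + momentum * v * m / max(m - 1, 1)
  } else {
    mu <- run_mean
    v <- run_var
    xc <- sweep(xp, 2L, mu)
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- sweep(xc, 2L, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2L, gamma, `*`), 2L, beta, `+`)
  dim(y) <- c(d[1], d[2], d[4], d[3])
  list(out = aperm(y, c(1, 2, 4, 3)),
       cache = list(xhat = xhat, inv_sd = inv_sd, gamma = gamma, dims = d),
       run_mean = run_mean, run_var = run_var)
}

bn_backward <- function(dout, cache) {
  d <- cache$dims; m <- d[1] * d[2] * d[4]
  dy <- aperm(dout, c(1, 2, 4, 3))
  dim(dy) <- c(m, d[3])
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2L, cache$gamma, `*`)
  # dx = inv_sd/m * (m*dxhat - sum(dxhat) - xhat * sum(dxhat*xhat))
  t1 <- sweep(dxhat, 2L, colSums(dxhat) / m)
  t2 <- sweep(xhat, 2L, colSums(dxhat * xhat) / m, `*`)
  dx <- sweep(t1 - t2, 2L, cache$inv_sd, `*`)
  dim(dx) <- c(d[1], d[2], d[4], d[3])
  list(dx = aperm(dx, c(1, 2, 4, 3)), dgamma = dgamma, dbeta = dbeta)
}

relu_forward <- function(x) list(out = pmax(x, 0), cache = x > 0)

relu_backward <- function(dout, cache) dout * cache

# squeeze-and-excitation: global channel statistics gate the channels
se_forward <- function(x, w1, b1, w2, b2) {
  d <- dim(x)
  z <- apply(x, c(3, 4), mean)                       # C x N channel means
  dim(z) <- c(d[3], d[4])
  a1 <- crossprod(w1, z) + b1                        # Cr x N
  r1 <- pmax(a1, 0)
  a2 <- crossprod(w2, r1) + b2                       # C x N
  g <- 1 / (1 + exp(-a2))
  gate <- array(rep(g, each = d[1] * d[2]), dim = d)
  list(out = x * gate,
       cache = list(x = x, z = z, a1 = a1, r1 = r1, g = g, gate = gate,
                    w1 = w1, w2 = w2, dims = d))
}

se_backward <- function(dout, cache) {
  d <- cache$dims
  dx <- dout * cache$gate
  dg <- apply(dout * cache$x, c(3, 4), sum)
  dim(dg) <- c(d[3], d[4])
  da2 <- dg * cache$g * (1 - cache$g)
  dw2 <- tcrossprod(cache$r1, da2)
  db2 <- rowSums(da2)
  dr1 <- cache$w2 %*% da2
  da1 <- dr1 * (cache$a1 > 0)
  dw1 <- tcrossprod(cache$z, da1)
  db1 <- rowSums(da1)
  dz <- cache$w1 %*% da1
  dx <- dx + array(rep(dz / (d[1] * d[2]), each = d[1] * d[2]), dim = d)
  list(dx = dx, dw1 = dw1, db1 = db1, dw2 = dw2, db2 = db2)
}

maxpool2_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop("maxpool2 needs even spatial dims")
  x6 <- x
  dim(x6) <- c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4])
  s <- list(x6[1, , 1, , , , drop = FALSE], x6[2, , 1, , , , drop = FALSE],
            x6[1, , 2, , , , drop = FALSE], x6[2, , 2, , , , drop = FALSE])
  s <- lapply(s, function(a) { dim(a) <- c(d[1] %/% 2L, d[2] %/% 2L, d[3], d[4]); a })
  out <- pmax(pmax(s[[1]], s[[2]]), pmax(s[[3]], s[[4]]))
  list(out = out, cache = list(slices = s, out = out, dims = d))
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$dims
  claimed <- array(FALSE, dim = dim(cache$out))
  dx6 <- array(0, c(2L, d[1] %/% 2L, 2L, d[2] %/% 2L, d[3], d[4]))
  pos <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
  for (k in 1:4) {
    hit <- (cache$slices[[k]] == cache$out) & !claimed
    claimed <- claimed | hit
    dx6[pos[[k]][1], , pos[[k]][2], , , ] <- dout * hit
  }
  dim(dx6) <- d
  dx6
}

gap_forward <- function(x) {
  d <- dim(x)
  feat <- apply(x, c(3, 4), mean)
  dim(feat) <- c(d[3], d[4])
  list(out = feat, cache = d)
}

gap_backward <- function(dfeat, dims) {
  array(rep(dfeat / (dims[1] * dims[2]), each = dims[1] * dims[2]), dim = dims)
}

dense_forward <- function(feat, weight, bias) {
  list(out = crossprod(weight, feat) + bias,    # K x N
       cache = list(feat = feat, weight = weight))
}

dense_backward <- function(dout, cache) {
  list(dx = cache$weight %*% dout,
       dweight = tcrossprod(cache$feat, dout),
       dbias = rowSums(dout))
}

# stable softmax over columns of a K x N logit matrix
softmax_cols <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

# mean cross-entropy and its logit gradient; y is an integer class vector
softmax_xent <- function(logits, y) {
  n <- ncol(logits)
  p <- softmax_cols(logits)
  picked <- p[cbind(y, seq_len(n))]
  loss <- -mean(log(pmax(picked, 1e-12)))
  dlogits <- p
  dlogits[cbind(y, seq_len(n))] <- dlogits[cbind(y, seq_len(n))] - 1
  list(loss = loss, probs = p, dlogits = dlogits / n)
}
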