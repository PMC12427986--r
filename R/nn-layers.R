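# Neural-network primitives: forward/backward pairs over batch arrays of
# dimension (n, L, C). Everything funnels through BLAS matmuls via im2col,
# so plain R is fast enough for the desk-scale networks used here.

.flat <- function(x) {          # (n, L, C) -> (n*L, C)
  d <- dim(x)
  dim(x) <- c(d[1] * d[2], d[3])
  x
}

.unflat <- function(x, n, L) {  # (n*L, C) -> (n, L, C)
  dim(x) <- c(n, L, ncol(x))
  x
}

# --- length-preserving convolution, kernel k, stride 1 -----------------
# W has dim (Cin, k, F): first-base-of-patch channels vary fastest, matching
# the im2col column blocks below.
nnConvFwd <- function(x, W, b) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  k <- dim(W)[2]; p <- (k - 1L) %/% 2L
  xp <- array(0, c(n, L + 2L * p, C))
  xp[, (p + 1L):(p + L), ] <- x
  Xcol <- matrix(0, n * L, k * C)
  for (m in seq_len(k))
    Xcol[, ((m - 1L) * C + 1L):(m * C)] <- .flat(
      xp[, m:(m + L - 1L), , drop = FALSE])
  Wmat <- matrix(W, C * k, dim(W)[3])
  out <- Xcol %*% Wmat
  out <- out + rep(b, each = n * L)
  dim(out) <- c(n, L, length(b))
  list(out = out, cache = list(Xcol = Xcol, dims = c(n, L, C), k = k, p = p,
                               Wmat = Wmat))
}

nnConvBwd <- function(cache, dout) {
  n <- cache$dims[1]; L <- cache$dims[2]; C <- cache$dims[3]
  k <- cache$k; p <- cache$p
  Fn <- dim(dout)[3]
  dM <- .flat(dout)
  dW <- crossprod(cache$Xcol, dM)
  dim(dW) <- c(C, k, Fn)
  db <- colSums(dM)
  dXcol <- tcrossprod(dM, cache$Wmat)
  dxp <- array(0, c(n, L + 2L * p, C))
  for (m in seq_len(k)) {
    blk <- dXcol[, ((m - 1L) * C + 1L):(m * C), drop = FALSE]
    dim(blk) <- c(n, L, C)
    dxp[, m:(m + L - 1L), ] <- dxp[, m:(m + L - 1L), , drop = FALSE] + blk
  }
  list(dx = dxp[, (p + 1L):(p + L), , drop = FALSE], dW = dW, db = db)
}

# --- batch normalization per channel -----------------------------------
nnBnFwd <- function(x, gamma, beta, run, training, momentum = 0.9,
                    eps = 1e-5) {
  d <- dim(x); N <- d[1] * d[2]
  xm <- .flat(x)
  if (training) {
    mu <- colMeans(xm)
    v <- colMeans(xm * xm) - mu * mu
    run$mean <- momentum * run$mean + (1 - momentum) * mu
    run$var <- momentum * run$var + (1 - momentum) * v
  } else {
    mu <- run$mean; v <- run$var
  }
  ivar <- 1 / sqrt(v + eps)
  xhat <- sweep(sweep(xm, 2L, mu, "-"), 2L, ivar, "*")
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  dim(out) <- d
  list(out = out, run = run,
       cache = list(xhat = xhat, ivar = ivar, gamma = gamma, d = d, N = N))
}

nnBnBwd <- function(cache, dout) {
  d <- cache$d; N <- cache$N
  dM <- .flat(dout)
  dgamma <- colSums(dM * cache$xhat)
  dbeta <- colSums(dM)
  dxhat <- sweep(dM, 2L, cache$gamma, "*")
  t1 <- sweep(dxhat, 2L, colMeans(dxhat), "-")
  t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), "*")
  dx <- sweep(t1 - t2, 2L, cache$ivar, "*")
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# --- ReLU ---------------------------------------------------------------
nnReluFwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
nnReluBwd <- function(cache, dout) dout * cache

# --- max pooling, kernel = stride = f (floor division of length) -------
nnPoolFwd <- function(x, f = 4L) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  Lo <- L %/% f
  if (Lo < 1L) stopValidation("input too short to pool by %d", f)
  y <- x[, seq(1L, by = f, length.out = Lo), , drop = FALSE]
  arg <- array(1L, dim(y))
  for (j in 2:f) {
    s <- x[, seq(j, by = f, length.out = Lo), , drop = FALSE]
    m <- s > y
    y[m] <- s[m]
    arg[m] <- j
  }
  list(out = y, cache = list(arg = arg, dims = d, f = f, Lo = Lo))
}

nnPoolBwd <- function(cache, dout) {
  d <- cache$dims; f <- cache$f; Lo <- cache$Lo
  dx <- array(0, d)
  for (j in seq_len(f)) {
    m <- cache$arg == j
    blk <- array(0, dim(dout))
    blk[m] <- dout[m]
    dx[, seq(j, by = f, length.out = Lo), ] <- blk
  }
  dx
}

# --- transposed convolution, kernel = stride = f (exact x f upsample) --
# W has dim (Cin, f, F)
nnTconvFwd <- function(x, W, b) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  f <- dim(W)[2]; Fn <- dim(W)[3]
  Xmat <- .flat(x)
  tmp <- Xmat %*% matrix(W, C, f * Fn)    # columns: j within o
  dim(tmp) <- c(n, L, f, Fn)
  out <- aperm(tmp, c(1, 3, 2, 4))
  dim(out) <- c(n, f * L, Fn)
  out <- out + rep(b, each = n * f * L)
  list(out = out, cache = list(Xmat = Xmat, dims = d, f = f, Fn = Fn, W = W))
}

nnTconvBwd <- function(cache, dout) {
  d <- cache$dims; n <- d[1]; L <- d[2]; C <- d[3]
  f <- cache$f; Fn <- cache$Fn
  db <- colSums(matrix(dout, n * f * L, Fn))
  dim(dout) <- c(n, f, L, Fn)
  dtmp <- aperm(dout, c(1, 3, 2, 4))
  dim(dtmp) <- c(n * L, f * Fn)
  dW <- crossprod(cache$Xmat, dtmp)
  dim(dW) <- c(C, f, Fn)
  dx <- tcrossprod(dtmp, matrix(cache$W, C, f * Fn))
  dim(dx) <- c(n, L, C)
  list(dx = dx, dW = dW, db = db)
}

# --- pointwise (1x1) convolution ---------------------------------------
nnPwFwd <- function(x, W, b) {
  d <- dim(x)
  out <- .flat(x) %*% W
  out <- out + rep(b, each = d[1] * d[2])
  dim(out) <- c(d[1], d[2], ncol(W))
  list(out = out, cache = list(Xmat = .flat(x), dims = d, W = W))
}

nnPwBwd <- function(cache, dout) {
  d <- cache$dims
  dM <- .flat(dout)
  list(dx = .unflat(tcrossprod(dM, cache$W), d[1], d[2]),
       dW = crossprod(cache$Xmat, dM), db = colSums(dM))
}

# --- depthwise convolution, kernel k, same padding, optional stride ----
# W has dim (C, k): one kernel per channel, no cross-channel mixing.
nnDwFwd <- function(x, W, b, stride = 1L) {
  d <- dim(x); n <- d[1]; L <- d[2]; C <- d[3]
  k <- ncol(W); p <- (k - 1L) %/% 2L
  xp <- array(0, c(n, L + 2L * p, C))
  xp[, (p + 1L):(p + L), ] <- x
  out <- array(0, c(n, L, C))
  for (m in seq_len(k))
    out <- out + xp[, m:(m + L - 1L), , drop = FALSE] *
      rep(W[, m], each = n * L)
  out <- out + rep(b, each = n * L)
  idx <- seq(1L, L, by = stride)
  list(out = out[, idx, , drop = FALSE],
       cache = list(xp = xp, dims = d, k = k, p = p, W = W,
                    stride = stride, idx = idx))
}

nnDwBwd <- function(cache, dout) {
  d <- cache$dims; n <- d[1]; L <- d[2]; C <- d[3]
  k <- cache$k; p <- cache$p
  full <- array(0, c(n, L, C))
  full[, cache$idx, ] <- dout
  dW <- matrix(0, C, k)
  dxp <- array(0, c(n, L + 2L * p, C))
  for (m in seq_len(k)) {
    slice <- cache$xp[, m:(m + L - 1L), , drop = FALSE]
    dW[, m] <- colSums(matrix(full * slice, n * L, C))
    dxp[, m:(m + L - 1L), ] <- dxp[, m:(m + L - 1L), , drop = FALSE] +
      full * rep(cache$W[, m], each = n * L)
  }
  list(dx = dxp[, (p + 1L):(p + L), , drop = FALSE], dW = dW,
       db = colSums(matrix(full, n * L, C)))
}

# --- global average pooling --------------------------------------------
nnGapFwd <- function(x) {
  d <- dim(x)
  a <- aperm(x, c(2, 1, 3))
  out <- matrix(colSums(matrix(a, d[2], d[1] * d[3])) / d[2], d[1], d[3])
  list(out = out, cache = d)
}

nnGapBwd <- function(cache, dout) {
  d <- cache
  tmp <- array(0, c(d[2], d[1], d[3]))
  tmp[] <- rep(as.vector(dout / d[2]), each = d[2])
  aperm(tmp, c(2, 1, 3))
}

# --- dense --------------------------------------------------------------
nnDenseFwd <- function(x, W, b) {
  list(out = sweep(x %*% W, 2L, b, "+"), cache = list(x = x, W = W))
}

nnDenseBwd <- function(cache, dout) {
  list(dx = tcrossprod(dout, cache$W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# --- squeeze-and-excitation gate ---------------------------------------
nnSeFwd <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  g <- nnGapFwd(x)
  h <- nnDenseFwd(g$out, W1, b1)
  r <- nnReluFwd(h$out)
  z <- nnDenseFwd(r$out, W2, b2)
  s <- 1 / (1 + exp(-z$out))                      # (n, C)
  big <- array(0, c(d[2], d[1], d[3]))
  big[] <- rep(as.vector(s), each = d[2])
  big <- aperm(big, c(2, 1, 3))
  list(out = x * big,
       cache = list(x = x, big = big, s = s, g = g, h = h, r = r, z = z,
                    d = d))
}

nnSeBwd <- function(cache, dout) {
  d <- cache$d
  dx1 <- dout * cache$big
  a <- aperm(dout * cache$x, c(2, 1, 3))
  ds <- matrix(colSums(matrix(a, d[2], d[1] * d[3])), d[1], d[3])
  dz <- ds * cache$s * (1 - cache$s)
  b2g <- nnDenseBwd(cache$z$cache, dz)
  dr <- nnReluBwd(cache$r$cache, b2g$dx)
  b1g <- nnDenseBwd(cache$h$cache, dr)
  dx2 <- nnGapBwd(cache$g$cache, b1g$dx)
  list(dx = dx1 + dx2, dW1 = b1g$dW, db1 = b1g$db, dW2 = b2g$dW,
       db2 = b2g$db)
}

# --- center crop + channel concatenation (UNet skip connections) -------
nnCropConcatFwd <- function(dec, enc) {
  dd <- dim(dec); de <- dim(enc)
  start <- (de[2] - dd[2]) %/% 2L + 1L
  cropped <- enc[, start:(start + dd[2] - 1L), , drop = FALSE]
  out <- array(0, c(dd[1], dd[2], dd[3] + de[3]))
  out[, , seq_len(dd[3])] <- dec
  out[, , dd[3] + seq_len(de[3])] <- cropped
  list(out = out, cache = list(dd = dd, de = de, start = start))
}

nnCropConcatBwd <- function(cache, dout) {
  dd <- cache$dd; de <- cache$de
  ddec <- dout[, , seq_len(dd[3]), drop = FALSE]
  denc <- array(0, de)
  denc[, cache$start:(cache$start + dd[2] - 1L), ] <-
    dout[, , dd[3] + seq_len(de[3]), drop = FALSE]
  list(ddec = ddec, denc = denc)
}

# --- softmax cross-entropy ---------------------------------------------
# logits (n, K), y integer class in 1..K; returns loss, probs and dlogits
nnSoftmaxCE <- function(logits, y = NULL) {
  z <- logits - apply(logits, 1L, max)
  e <- exp(z)
  p <- e / rowSums(e)
  out <- list(prob = p)
  if (!is.null(y)) {
    n <- nrow(p)
    out$loss <- -mean(log(pmax(p[cbind(seq_len(n), y)], 1e-12)))
    hot <- matrix(0, n, ncol(p))
    hot[cbind(seq_len(n), y)] <- 1
    out$dlogits <- (p - hot) / n
  }
  out
}

# --- parameter initialization ------------------------------------------
heConv <- function(Cin, k, Fout) {
  array(stats::rnorm(Cin * k * Fout, sd = sqrt(2 / (Cin * k))),
        c(Cin, k, Fout))
}
heMat <- function(Cin, Cout) {
  matrix(stats::rnorm(Cin * Cout, sd = sqrt(2 / Cin)), Cin, Cout)
}
bnInit <- function(C) list(gamma = rep(1, C), beta = rep(0, C))
bnState <- function(C) list(mean = rep(0, C), var = rep(1, C))
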