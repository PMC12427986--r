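#' Valid-mode 1-D convolution (cross-correlation form)
#'
#' Computes F_i = sum_{m=0}^{k-1} I_{i+m} K_m, the sliding dot product as
#' used inside the convolutional layers: the kernel is not flipped, and the
#' output has length n - k + 1 (valid mode).
#'
#' @param input numeric vector (the signal I).
#' @param kernel numeric vector of length k <= length(input).
#' @return numeric vector of length \code{length(input) - length(kernel) + 1}.
#' @examples
#' conv1d(c(1, 2, 3, 4), c(1, 1))  # 3 5 7
#' @export
conv1d <- function(input, kernel) {
  n <- length(input); k <- length(kernel)
  if (n < 1L || k < 1L) stopValidation("input and kernel must be non-empty")
  if (k > n) stopValidation("kernel longer than input")
  out <- numeric(n - k + 1L)
  for (m in seq_len(k))
    out <- out + input[m:(m + n - k)] * kernel[m]
  out
}

.checkTwoPool <- function(L, f) {
  if ((L %/% f) %/% f < 1L)
    stopValidation("input length %d too short for two pooling stages by %d",
                   L, f)
}

#' Build the 1-D UNet classifier specification
#'
#' Encoder: two conv(k=3, same) + maxpool(/4) stages with 16 then 32
#' filters, then a 64-filter bottleneck conv. Decoder: transposed-conv (x4)
#' with 64 filters plus a skip connection from the second encoder map, then
#' transposed-conv (x4) with 32 filters plus a skip from the first encoder
#' map, then a 16-filter conv. Skip maps are center-cropped to the decoder
#' length before channel concatenation. Head: global average pooling, a
#' dense layer and a 2-way softmax. For a 299 x 8 input the length ladder is
#' 299 -> 74 -> 18 on the encoder and 18 -> 72 -> 288 on the decoder.
#'
#' @param inputLength number of feature rows L'.
#' @param inputChannels number of feature channels C.
#' @return a \linkS4class{ModelSpec}.
#' @examples
#' lengthLadder(buildUnet(299, 8))
#' @export
buildUnet <- function(inputLength, inputChannels) {
  L <- as.integer(inputLength); C <- as.integer(inputChannels)
  f <- 4L
  .checkTwoPool(L, f)
  L1 <- L %/% f; L2 <- L1 %/% f
  new("ModelSpec", architecture = "unet1d", inputLength = L,
      inputChannels = C, encoderFilters = c(16L, 32L, 64L),
      decoderFilters = c(64L, 32L, 16L), poolFactor = f, kernelSize = 3L,
      classOrder = .CLASS_ORDER,
      ladder = list(encoder = c(L, L1, L2),
                    decoder = c(L2, f * L2, f * f * L2)),
      extra = list())
}

#' Build the plain 1-D CNN baseline specification
#'
#' Three conv(k=3, same) blocks with 16, 32 and 64 filters, each followed by
#' maxpool(/4) where the remaining length permits, then global average
#' pooling and a 2-way softmax head.
#'
#' @inheritParams buildUnet
#' @return a \linkS4class{ModelSpec}.
#' @export
buildCnn <- function(inputLength, inputChannels) {
  L <- as.integer(inputLength); C <- as.integer(inputChannels)
  f <- 4L
  .checkTwoPool(L, f)
  L1 <- L %/% f; L2 <- L1 %/% f
  pool3 <- L2 >= f
  enc <- c(L, L1, L2, if (pool3) L2 %/% f)
  new("ModelSpec", architecture = "cnn1d", inputLength = L,
      inputChannels = C, encoderFilters = c(16L, 32L, 64L),
      decoderFilters = integer(0), poolFactor = f, kernelSize = 3L,
      classOrder = .CLASS_ORDER,
      ladder = list(encoder = enc, decoder = integer(0)),
      extra = list(pool3 = pool3))
}

#' Build the MobileNet-style 1-D baseline specification
#'
#' A 16-filter stem convolution followed by three inverted-residual blocks
#' (pointwise expansion x4, depthwise k=3 convolution, squeeze-and-excitation
#' gate with reduction 4, linear pointwise bottleneck projection); the first
#' two blocks use stride 2, and the identity residual is present exactly
#' where stride is 1 and input/output channels match. Head: global average
#' pooling and a 2-way softmax.
#'
#' @inheritParams buildUnet
#' @return a \linkS4class{ModelSpec}.
#' @export
buildMobileNet1d <- function(inputLength, inputChannels) {
  L <- as.integer(inputLength); C <- as.integer(inputChannels)
  .checkTwoPool(L, 4L)
  blocks <- list(
    list(cin = 16L, exp = 64L, stride = 2L, cout = 16L),
    list(cin = 16L, exp = 64L, stride = 2L, cout = 24L),
    list(cin = 24L, exp = 96L, stride = 1L, cout = 24L))
  lens <- L
  for (b in blocks) lens <- c(lens, ceiling(lens[length(lens)] / b$stride))
  for (i in seq_along(blocks))
    blocks[[i]]$residual <- blocks[[i]]$stride == 1L &&
      blocks[[i]]$cin == blocks[[i]]$cout
  new("ModelSpec", architecture = "mobilenet1d", inputLength = L,
      inputChannels = C, encoderFilters = c(16L, 24L, 24L),
      decoderFilters = integer(0), poolFactor = 4L, kernelSize = 3L,
      classOrder = .CLASS_ORDER,
      ladder = list(encoder = as.integer(lens), decoder = integer(0)),
      extra = list(blocks = blocks, seReduction = 4L))
}

# ---------------------------------------------------------------------
# parameter initialization (He for conv/dense, unit-gamma BN)

.initParams <- function(spec) {
  C <- spec@inputChannels; k <- spec@kernelSize; f <- spec@poolFactor
  p <- list()
  s <- list()
  if (spec@architecture == "unet1d") {
    p$c1.W <- heConv(C, k, 16L);  p$c1.b <- rep(0, 16)
    p$c2.W <- heConv(16L, k, 32L); p$c2.b <- rep(0, 32)
    p$c3.W <- heConv(32L, k, 64L); p$c3.b <- rep(0, 64)
    p$u1.W <- heConv(64L, f, 64L); p$u1.b <- rep(0, 64)
    p$u2.W <- heConv(96L, f, 32L); p$u2.b <- rep(0, 32)
    p$c4.W <- heConv(48L, k, 16L); p$c4.b <- rep(0, 16)
    p$fc.W <- heMat(16L, 2L);     p$fc.b <- rep(0, 2)
    for (nm in c("bn1", "bn2", "bn3", "bnu1", "bnu2", "bn4")) {
      Cn <- c(bn1 = 16, bn2 = 32, bn3 = 64, bnu1 = 64, bnu2 = 32,
              bn4 = 16)[[nm]]
      ini <- bnInit(Cn)
      p[[paste0(nm, ".gamma")]] <- ini$gamma
      p[[paste0(nm, ".beta")]] <- ini$beta
      s[[nm]] <- bnState(Cn)
    }
  } else if (spec@architecture == "cnn1d") {
    p$c1.W <- heConv(C, k, 16L);  p$c1.b <- rep(0, 16)
    p$c2.W <- heConv(16L, k, 32L); p$c2.b <- rep(0, 32)
    p$c3.W <- heConv(32L, k, 64L); p$c3.b <- rep(0, 64)
    p$fc.W <- heMat(64L, 2L);     p$fc.b <- rep(0, 2)
    for (nm in c("bn1", "bn2", "bn3")) {
      Cn <- c(bn1 = 16, bn2 = 32, bn3 = 64)[[nm]]
      ini <- bnInit(Cn)
      p[[paste0(nm, ".gamma")]] <- ini$gamma
      p[[paste0(nm, ".beta")]] <- ini$beta
      s[[nm]] <- bnState(Cn)
    }
  } else {
    p$cs.W <- heConv(C, k, 16L); p$cs.b <- rep(0, 16)
    ini <- bnInit(16L); p$bns.gamma <- ini$gamma; p$bns.beta <- ini$beta
    s$bns <- bnState(16L)
    red <- spec@extra$seReduction
    for (i in seq_along(spec@extra$blocks)) {
      b <- spec@extra$blocks[[i]]
      pre <- sprintf("b%d.", i)
      p[[paste0(pre, "pw1.W")]] <- heMat(b$cin, b$exp)
      p[[paste0(pre, "pw1.b")]] <- rep(0, b$exp)
      p[[paste0(pre, "dw.W")]] <- matrix(
        stats::rnorm(b$exp * k, sd = sqrt(2 / k)), b$exp, k)
      p[[paste0(pre, "dw.b")]] <- rep(0, b$exp)
      p[[paste0(pre, "se.W1")]] <- heMat(b$exp, b$exp %/% red)
      p[[paste0(pre, "se.b1")]] <- rep(0, b$exp %/% red)
      p[[paste0(pre, "se.W2")]] <- heMat(b$exp %/% red, b$exp)
      p[[paste0(pre, "se.b2")]] <- rep(0, b$exp)
      p[[paste0(pre, "pw2.W")]] <- heMat(b$exp, b$cout)
      p[[paste0(pre, "pw2.b")]] <- rep(0, b$cout)
      for (bn in c("bn1", "bn2", "bn3")) {
        Cn <- if (bn == "bn3") b$cout else b$exp
        ini <- bnInit(Cn)
        p[[paste0(pre, bn, ".gamma")]] <- ini$gamma
        p[[paste0(pre, bn, ".beta")]] <- ini$beta
        s[[paste0(pre, bn)]] <- bnState(Cn)
      }
    }
    p$fc.W <- heMat(24L, 2L); p$fc.b <- rep(0, 2)
  }
  list(params = p, state = s)
}

# ---------------------------------------------------------------------
# forward / backward per architecture

.convBnRelu <- function(x, p, s, cw, bn, training) {
  cv <- nnConvFwd(x, p[[paste0(cw, ".W")]], p[[paste0(cw, ".b")]])
  b <- nnBnFwd(cv$out, p[[paste0(bn, ".gamma")]], p[[paste0(bn, ".beta")]],
               s[[bn]], training)
  r <- nnReluFwd(b$out)
  list(out = r$out, conv = cv, bn = b, relu = r)
}

.convBnReluBwd <- function(blk, dout, cw, bn, g) {
  dr <- nnReluBwd(blk$relu$cache, dout)
  db <- nnBnBwd(blk$bn$cache, dr)
  g[[paste0(bn, ".gamma")]] <- db$dgamma
  g[[paste0(bn, ".beta")]] <- db$dbeta
  dc <- nnConvBwd(blk$conv$cache, db$dx)
  g[[paste0(cw, ".W")]] <- dc$dW
  g[[paste0(cw, ".b")]] <- dc$db
  list(dx = dc$dx, g = g)
}

.unetFwd <- function(p, s, x, training) {
  f <- 4L
  e1 <- .convBnRelu(x, p, s, "c1", "bn1", training)
  if (training) s$bn1 <- e1$bn$run
  p1 <- nnPoolFwd(e1$out, f)
  e2 <- .convBnRelu(p1$out, p, s, "c2", "bn2", training)
  if (training) s$bn2 <- e2$bn$run
  p2 <- nnPoolFwd(e2$out, f)
  bt <- .convBnRelu(p2$out, p, s, "c3", "bn3", training)
  if (training) s$bn3 <- bt$bn$run
  t1 <- nnTconvFwd(bt$out, p$u1.W, p$u1.b)
  bu1 <- nnBnFwd(t1$out, p$bnu1.gamma, p$bnu1.beta, s$bnu1, training)
  if (training) s$bnu1 <- bu1$run
  ru1 <- nnReluFwd(bu1$out)
  cc1 <- nnCropConcatFwd(ru1$out, e2$out)
  t2 <- nnTconvFwd(cc1$out, p$u2.W, p$u2.b)
  bu2 <- nnBnFwd(t2$out, p$bnu2.gamma, p$bnu2.beta, s$bnu2, training)
  if (training) s$bnu2 <- bu2$run
  ru2 <- nnReluFwd(bu2$out)
  cc2 <- nnCropConcatFwd(ru2$out, e1$out)
  d3 <- .convBnRelu(cc2$out, p, s, "c4", "bn4", training)
  if (training) s$bn4 <- d3$bn$run
  g <- nnGapFwd(d3$out)
  fc <- nnDenseFwd(g$out, p$fc.W, p$fc.b)
  shapes <- list(encoder = c(dim(x)[2], dim(p1$out)[2], dim(p2$out)[2]),
                 decoder = c(dim(bt$out)[2], dim(t1$out)[2], dim(t2$out)[2]),
                 filters = c(dim(e1$out)[3], dim(e2$out)[3], dim(bt$out)[3],
                             dim(t1$out)[3], dim(t2$out)[3], dim(d3$out)[3]))
  list(logits = fc$out, state = s, shapes = shapes,
       cache = list(e1 = e1, p1 = p1, e2 = e2, p2 = p2, bt = bt, t1 = t1,
                    bu1 = bu1, ru1 = ru1, cc1 = cc1, t2 = t2, bu2 = bu2,
                    ru2 = ru2, cc2 = cc2, d3 = d3, g = g, fc = fc))
}

.unetBwd <- function(p, cache, dlogits) {
  g <- list()
  dfc <- nnDenseBwd(cache$fc$cache, dlogits)
  g$fc.W <- dfc$dW; g$fc.b <- dfc$db
  dd3 <- nnGapBwd(cache$g$cache, dfc$dx)
  r <- .convBnReluBwd(cache$d3, dd3, "c4", "bn4", g); g <- r$g
  sp2 <- nnCropConcatBwd(cache$cc2$cache, r$dx)
  dru2 <- nnReluBwd(cache$ru2$cache, sp2$ddec)
  dbu2 <- nnBnBwd(cache$bu2$cache, dru2)
  g$bnu2.gamma <- dbu2$dgamma; g$bnu2.beta <- dbu2$dbeta
  dt2 <- nnTconvBwd(cache$t2$cache, dbu2$dx)
  g$u2.W <- dt2$dW; g$u2.b <- dt2$db
  sp1 <- nnCropConcatBwd(cache$cc1$cache, dt2$dx)
  dru1 <- nnReluBwd(cache$ru1$cache, sp1$ddec)
  dbu1 <- nnBnBwd(cache$bu1$cache, dru1)
  g$bnu1.gamma <- dbu1$dgamma; g$bnu1.beta <- dbu1$dbeta
  dt1 <- nnTconvBwd(cache$t1$cache, dbu1$dx)
  g$u1.W <- dt1$dW; g$u1.b <- dt1$db
  r <- .convBnReluBwd(cache$bt, dt1$dx, "c3", "bn3", g); g <- r$g
  dp2 <- nnPoolBwd(cache$p2$cache, r$dx)
  r <- .convBnReluBwd(cache$e2, dp2 + sp1$denc, "c2", "bn2", g); g <- r$g
  dp1 <- nnPoolBwd(cache$p1$cache, r$dx)
  r <- .convBnReluBwd(cache$e1, dp1 + sp2$denc, "c1", "bn1", g); g <- r$g
  g
}

.cnnFwd <- function(p, s, x, training, pool3) {
  f <- 4L
  b1 <- .convBnRelu(x, p, s, "c1", "bn1", training)
  if (training) s$bn1 <- b1$bn$run
  p1 <- nnPoolFwd(b1$out, f)
  b2 <- .convBnRelu(p1$out, p, s, "c2", "bn2", training)
  if (training) s$bn2 <- b2$bn$run
  p2 <- nnPoolFwd(b2$out, f)
  b3 <- .convBnRelu(p2$out, p, s, "c3", "bn3", training)
  if (training) s$bn3 <- b3$bn$run
  last <- b3$out
  p3 <- NULL
  if (pool3) {
    p3 <- nnPoolFwd(last, f)
    last <- p3$out
  }
  g <- nnGapFwd(last)
  fc <- nnDenseFwd(g$out, p$fc.W, p$fc.b)
  enc <- c(dim(x)[2], dim(p1$out)[2], dim(p2$out)[2],
           if (pool3) dim(p3$out)[2])
  list(logits = fc$out, state = s,
       shapes = list(encoder = enc, decoder = integer(0),
                     filters = c(16L, 32L, 64L)),
       cache = list(b1 = b1, p1 = p1, b2 = b2, p2 = p2, b3 = b3, p3 = p3,
                    g = g, fc = fc))
}

.cnnBwd <- function(p, cache, dlogits) {
  g <- list()
  dfc <- nnDenseBwd(cache$fc$cache, dlogits)
  g$fc.W <- dfc$dW; g$fc.b <- dfc$db
  dlast <- nnGapBwd(cache$g$cache, dfc$dx)
  if (!is.null(cache$p3)) dlast <- nnPoolBwd(cache$p3$cache, dlast)
  r <- .convBnReluBwd(cache$b3, dlast, "c3", "bn3", g); g <- r$g
  dp2 <- nnPoolBwd(cache$p2$cache, r$dx)
  r <- .convBnReluBwd(cache$b2, dp2, "c2", "bn2", g); g <- r$g
  dp1 <- nnPoolBwd(cache$p1$cache, r$dx)
  r <- .convBnReluBwd(cache$b1, dp1, "c1", "bn1", g); g <- r$g
  g
}

.mobFwd <- function(p, s, x, training, blocks) {
  st <- nnConvFwd(x, p$cs.W, p$cs.b)
  bs <- nnBnFwd(st$out, p$bns.gamma, p$bns.beta, s$bns, training)
  if (training) s$bns <- bs$run
  rs <- nnReluFwd(bs$out)
  cur <- rs$out
  bc <- list()
  lens <- dim(cur)[2]
  for (i in seq_along(blocks)) {
    b <- blocks[[i]]
    pre <- sprintf("b%d.", i)
    inx <- cur
    pw1 <- nnPwFwd(cur, p[[paste0(pre, "pw1.W")]], p[[paste0(pre, "pw1.b")]])
    bn1 <- nnBnFwd(pw1$out, p[[paste0(pre, "bn1.gamma")]],
                   p[[paste0(pre, "bn1.beta")]], s[[paste0(pre, "bn1")]],
                   training)
    if (training) s[[paste0(pre, "bn1")]] <- bn1$run
    r1 <- nnReluFwd(bn1$out)
    dw <- nnDwFwd(r1$out, p[[paste0(pre, "dw.W")]], p[[paste0(pre, "dw.b")]],
                  b$stride)
    bn2 <- nnBnFwd(dw$out, p[[paste0(pre, "bn2.gamma")]],
                   p[[paste0(pre, "bn2.beta")]], s[[paste0(pre, "bn2")]],
                   training)
    if (training) s[[paste0(pre, "bn2")]] <- bn2$run
    r2 <- nnReluFwd(bn2$out)
    se <- nnSeFwd(r2$out, p[[paste0(pre, "se.W1")]], p[[paste0(pre, "se.b1")]],
                  p[[paste0(pre, "se.W2")]], p[[paste0(pre, "se.b2")]])
    pw2 <- nnPwFwd(se$out, p[[paste0(pre, "pw2.W")]],
                   p[[paste0(pre, "pw2.b")]])
    bn3 <- nnBnFwd(pw2$out, p[[paste0(pre, "bn3.gamma")]],
                   p[[paste0(pre, "bn3.beta")]], s[[paste0(pre, "bn3")]],
                   training)
    if (training) s[[paste0(pre, "bn3")]] <- bn3$run
    out <- bn3$out
    if (b$residual) out <- out + inx
    bc[[i]] <- list(pw1 = pw1, bn1 = bn1, r1 = r1, dw = dw, bn2 = bn2,
                    r2 = r2, se = se, pw2 = pw2, bn3 = bn3,
                    residual = b$residual)
    cur <- out
    lens <- c(lens, dim(cur)[2])
  }
  g <- nnGapFwd(cur)
  fc <- nnDenseFwd(g$out, p$fc.W, p$fc.b)
  list(logits = fc$out, state = s,
       shapes = list(encoder = as.integer(lens),
                     decoder = integer(0), filters = c(16L, 24L, 24L)),
       cache = list(st = st, bs = bs, rs = rs, blocks = bc, g = g, fc = fc))
}

.mobBwd <- function(p, cache, dlogits) {
  g <- list()
  dfc <- nnDenseBwd(cache$fc$cache, dlogits)
  g$fc.W <- dfc$dW; g$fc.b <- dfc$db
  dcur <- nnGapBwd(cache$g$cache, dfc$dx)
  for (i in rev(seq_along(cache$blocks))) {
    bc <- cache$blocks[[i]]
    pre <- sprintf("b%d.", i)
    dres <- if (bc$residual) dcur else 0
    dbn3 <- nnBnBwd(bc$bn3$cache, dcur)
    g[[paste0(pre, "bn3.gamma")]] <- dbn3$dgamma
    g[[paste0(pre, "bn3.beta")]] <- dbn3$dbeta
    dpw2 <- nnPwBwd(bc$pw2$cache, dbn3$dx)
    g[[paste0(pre, "pw2.W")]] <- dpw2$dW
    g[[paste0(pre, "pw2.b")]] <- dpw2$db
    dse <- nnSeBwd(bc$se$cache, dpw2$dx)
    g[[paste0(pre, "se.W1")]] <- dse$dW1; g[[paste0(pre, "se.b1")]] <- dse$db1
    g[[paste0(pre, "se.W2")]] <- dse$dW2; g[[paste0(pre, "se.b2")]] <- dse$db2
    dr2 <- nnReluBwd(bc$r2$cache, dse$dx)
    dbn2 <- nnBnBwd(bc$bn2$cache, dr2)
    g[[paste0(pre, "bn2.gamma")]] <- dbn2$dgamma
    g[[paste0(pre, "bn2.beta")]] <- dbn2$dbeta
    ddw <- nnDwBwd(bc$dw$cache, dbn2$dx)
    g[[paste0(pre, "dw.W")]] <- ddw$dW
    g[[paste0(pre, "dw.b")]] <- ddw$db
    dr1 <- nnReluBwd(bc$r1$cache, ddw$dx)
    dbn1 <- nnBnBwd(bc$bn1$cache, dr1)
    g[[paste0(pre, "bn1.gamma")]] <- dbn1$dgamma
    g[[paste0(pre, "bn1.beta")]] <- dbn1$dbeta
    dpw1 <- nnPwBwd(bc$pw1$cache, dbn1$dx)
    g[[paste0(pre, "pw1.W")]] <- dpw1$dW
    g[[paste0(pre, "pw1.b")]] <- dpw1$db
    dcur <- dpw1$dx
    if (bc$residual) dcur <- dcur + dres
  }
  drs <- nnReluBwd(cache$rs$cache, dcur)
  dbs <- nnBnBwd(cache$bs$cache, drs)
  g$bns.gamma <- dbs$dgamma; g$bns.beta <- dbs$dbeta
  dst <- nnConvBwd(cache$st$cache, dbs$dx)
  g$cs.W <- dst$dW; g$cs.b <- dst$db
  g
}

.forward <- function(spec, p, s, x, training) {
  switch(spec@architecture,
         unet1d = .unetFwd(p, s, x, training),
         cnn1d = .cnnFwd(p, s, x, training, spec@extra$pool3),
         mobilenet1d = .mobFwd(p, s, x, training, spec@extra$blocks))
}

.backward <- function(spec, p, cache, dlogits) {
  switch(spec@architecture,
         unet1d = .unetBwd(p, cache, dlogits),
         cnn1d = .cnnBwd(p, cache, dlogits),
         mobilenet1d = .mobBwd(p, cache, dlogits))
}

#' Instantiate a network and report its layer length ladder
#'
#' Runs one forward pass of a freshly initialized network on a dummy batch
#' and reads the sequence lengths (and filter counts) directly off the
#' layer outputs — the observed ladder, not the one the spec promises.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @return list with \code{encoder} and \code{decoder} length vectors and
#'   \code{filters}.
#' @examples
#' instantiateShapes(buildUnet(299, 8))
#' @export
instantiateShapes <- function(spec) {
  ini <- withSeed(1L, .initParams(spec))
  x <- array(0, c(2L, spec@inputLength, spec@inputChannels))
  fw <- .forward(spec, ini$params, ini$state, x, training = FALSE)
  fw$shapes
}

#' @rdname accessors
#' @export
setMethod("nParameters", "ModelSpec", function(x) {
  ini <- withSeed(1L, .initParams(x))
  sum(vapply(ini$params, length, integer(1)))
})

#' @rdname accessors
#' @export
setMethod("nParameters", "TrainedModel", function(x) {
  sum(vapply(x@parameters, length, integer(1)))
})

# ---------------------------------------------------------------------

#' Train a classifier
#'
#' Minibatch training with the Adam optimizer and softmax cross-entropy
#' loss for exactly \code{config@epochs} epochs (no early stopping). The
#' seed fixes weight initialization and batch order, so two runs with the
#' same seed, data and platform produce identical histories. Per-epoch
#' training accuracy/loss are averaged over minibatches; the validation set
#' is scored after each epoch with batch-normalization in inference mode.
#'
#' @param spec a \linkS4class{ModelSpec}.
#' @param trainSet,valSet \linkS4class{EncodedDataset}s whose shapes match
#'   the spec; the training set must contain both classes.
#' @param config a \linkS4class{TrainingConfig}.
#' @param verbose print per-epoch progress.
#' @return a \linkS4class{TrainedModel}.
#' @export
trainModel <- function(spec, trainSet, valSet, config = trainingConfig(),
                       verbose = FALSE) {
  dTr <- dim(features(trainSet))
  if (dTr[2] != spec@inputLength || dTr[3] != spec@inputChannels)
    stopValidation("training data %d x %d does not match spec %d x %d",
                   dTr[2], dTr[3], spec@inputLength, spec@inputChannels)
  if (length(unique(siteLabels(trainSet))) < 2L)
    stopValidation("training set must contain both classes")
  xTr <- features(trainSet)
  yTr <- as.integer(siteLabels(trainSet))
  xVa <- features(valSet)
  yVa <- as.integer(siteLabels(valSet))
  n <- dTr[1]
  bs <- config@batchSize
  lr <- config@learningRate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8

  res <- withSeed(config@seed, {
    ini <- .initParams(spec)
    p <- ini$params; s <- ini$state
    mAd <- lapply(p, function(w) w * 0)
    vAd <- lapply(p, function(w) w * 0)
    tAd <- 0L
    hist <- data.frame(epoch = integer(0), train_acc = numeric(0),
                       val_acc = numeric(0), train_loss = numeric(0),
                       val_loss = numeric(0))
    for (ep in seq_len(config@epochs)) {
      perm <- sample.int(n)
      lossSum <- 0; accSum <- 0
      for (start in seq(1L, n, by = bs)) {
        idx <- perm[start:min(start + bs - 1L, n)]
        xb <- xTr[idx, , , drop = FALSE]
        yb <- yTr[idx]
        fw <- .forward(spec, p, s, xb, training = TRUE)
        s <- fw$state
        sm <- nnSoftmaxCE(fw$logits, yb)
        g <- .backward(spec, p, fw$cache, sm$dlogits)
        tAd <- tAd + 1L
        corr <- sqrt(1 - b2^tAd) / (1 - b1^tAd)
        for (nm in names(p)) {
          mAd[[nm]] <- b1 * mAd[[nm]] + (1 - b1) * g[[nm]]
          vAd[[nm]] <- b2 * vAd[[nm]] + (1 - b2) * g[[nm]]^2
          p[[nm]] <- p[[nm]] - lr * corr * mAd[[nm]] /
            (sqrt(vAd[[nm]]) + eps)
        }
        lossSum <- lossSum + sm$loss * length(idx)
        pred <- max.col(sm$prob, ties.method = "first")
        accSum <- accSum + sum(pred == yb)
      }
      va <- .scoreSet(spec, p, s, xVa, yVa)
      hist <- rbind(hist, data.frame(
        epoch = ep, train_acc = accSum / n, val_acc = va$acc,
        train_loss = lossSum / n, val_loss = va$loss))
      if (verbose)
        message(sprintf(
          "epoch %3d  train acc %.3f loss %.3f | val acc %.3f loss %.3f",
          ep, accSum / n, lossSum / n, va$acc, va$loss))
    }
    list(p = p, s = s, hist = hist)
  })
  new("TrainedModel", spec = spec, parameters = res$p, state = res$s,
      history = res$hist, config = config)
}

.scoreSet <- function(spec, p, s, x, y, chunk = 512L) {
  n <- dim(x)[1]
  loss <- 0; acc <- 0
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- .forward(spec, p, s, x[idx, , , drop = FALSE], training = FALSE)
    sm <- nnSoftmaxCE(fw$logits, y[idx])
    loss <- loss + sm$loss * length(idx)
    pred <- max.col(sm$prob, ties.method = "first")
    acc <- acc + sum(pred == y[idx])
  }
  list(loss = loss / n, acc = acc / n)
}

#' Predict methylation status
#'
#' Produces the two softmax class probabilities per site (summing to 1
#' within 1e-6) and the hard label by argmax; an exact tie goes to class 1
#' (unmethylated).
#'
#' @param object a \linkS4class{TrainedModel}.
#' @param data an \linkS4class{EncodedDataset} matching the model's input
#'   shape.
#' @param ... unused.
#' @return list with \code{prob} (n x 2 matrix, columns unmethylated /
#'   methylated) and \code{label} (factor).
#' @export
setMethod("predict", "TrainedModel", function(object, data, ...) {
  x <- features(data)
  d <- dim(x)
  spec <- object@spec
  if (d[2] != spec@inputLength || d[3] != spec@inputChannels)
    stopValidation("data %d x %d does not match model input %d x %d",
                   d[2], d[3], spec@inputLength, spec@inputChannels)
  prob <- matrix(NA_real_, d[1], 2L,
                 dimnames = list(NULL, spec@classOrder))
  for (start in seq(1L, d[1], by = 512L)) {
    idx <- start:min(start + 511L, d[1])
    fw <- .forward(spec, object@parameters, object@state,
                   x[idx, , , drop = FALSE], training = FALSE)
    prob[idx, ] <- nnSoftmaxCE(fw$logits)$prob
  }
  label <- factor(ifelse(prob[, 2L] > prob[, 1L], "methylated",
                         "unmethylated"), levels = spec@classOrder)
  list(prob = prob, label = label)
})

#' Save / load a model checkpoint
#'
#' The weights go into an opaque RDS file accompanied by a JSON manifest
#' (architecture, input shape, class order, seed, training settings) so a
#' checkpoint is self-describing.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param dir checkpoint directory (created if needed).
#' @return the directory (invisibly) / the reloaded model.
#' @export
writeCheckpoint <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model, file.path(dir, "weights.rds"))
  spec <- model@spec
  manifest <- list(architecture = spec@architecture,
                   input_length = spec@inputLength,
                   input_channels = spec@inputChannels,
                   class_order = spec@classOrder,
                   epochs = model@config@epochs,
                   batch_size = model@config@batchSize,
                   learning_rate = model@config@learningRate,
                   seed = model@config@seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  utils::write.table(model@history, file.path(dir, "history.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname writeCheckpoint
#' @export
readCheckpoint <- function(dir) {
  readRDS(file.path(dir, "weights.rds"))
}
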