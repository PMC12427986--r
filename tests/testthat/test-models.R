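test_that("conv1d computes the sliding dot product in valid mode", {
  expect_equal(conv1d(c(1, 2, 3), 1), c(1, 2, 3))
  expect_equal(conv1d(c(1, 2, 3, 4), c(1, 1)), c(3, 5, 7))
  expect_error(conv1d(c(1, 2), c(1, 1, 1)), "longer than input")
  set.seed(31)
  for (rep in 1:200) {
    n <- sample(5:30, 1)
    k <- sample(1:min(5, n), 1)
    I <- rnorm(n); K <- rnorm(k)
    expect_equal(conv1d(I, K), oracleConv(I, K), tolerance = 1e-10)
  }
})

test_that("the UNet length ladder matches the instantiated layer shapes", {
  cases <- list(list(L = 299L, C = 8L, enc = c(299, 74, 18),
                     dec = c(18, 72, 288)),
                list(L = 300L, C = 4L, enc = c(300, 75, 18),
                     dec = c(18, 72, 288)),
                list(L = 99L, C = 8L, enc = c(99, 24, 6),
                     dec = c(6, 24, 96)))
  for (cs in cases) {
    spec <- buildUnet(cs$L, cs$C)
    expect_equal(lengthLadder(spec)$encoder, cs$enc)
    expect_equal(lengthLadder(spec)$decoder, cs$dec)
    sh <- instantiateShapes(spec)       # read off the actual layer outputs
    expect_equal(sh$encoder, cs$enc)
    expect_equal(sh$decoder, cs$dec)
    expect_equal(sh$filters, c(16L, 32L, 64L, 64L, 32L, 16L))
  }
  expect_error(buildUnet(10, 8), "too short")
})

test_that("the CNN spec pools where length permits and stays smaller than the UNet", {
  spec <- buildCnn(299, 8)
  expect_equal(lengthLadder(spec)$encoder, c(299L, 74L, 18L, 4L))
  expect_equal(instantiateShapes(spec)$encoder, c(299L, 74L, 18L, 4L))
  expect_lt(nParameters(buildCnn(299, 8)), nParameters(buildUnet(299, 8)))
  # short input: third pool dropped
  expect_equal(lengthLadder(buildCnn(50, 4))$encoder, c(50L, 12L, 3L))
})

test_that("MobileNet blocks are depthwise with residuals only where shapes match", {
  spec <- buildMobileNet1d(299, 8)
  blocks <- spec@extra$blocks
  expect_equal(vapply(blocks, `[[`, logical(1), "residual"),
               c(FALSE, FALSE, TRUE))
  ini <- methylUNet:::withSeed(1L, methylUNet:::.initParams(spec))
  # one kernel per channel: depthwise weight is (channels x kernel), no
  # cross-channel mixing
  for (i in 1:3)
    expect_equal(dim(ini$params[[sprintf("b%d.dw.W", i)]]),
                 c(blocks[[i]]$exp, 3L))
  # squeeze-and-excitation bottleneck uses reduction 4
  expect_equal(dim(ini$params$b1.se.W1), c(64L, 16L))
  expect_equal(instantiateShapes(spec)$encoder, c(299L, 150L, 75L, 75L))
})

test_that("training runs the configured epochs and is seed-reproducible", {
  ds <- randomDataset(48, 20, 4, seed = 1)
  spec <- buildUnet(20, 4)
  cfg <- trainingConfig(epochs = 3, batchSize = 16, seed = 5)
  m1 <- trainModel(spec, ds, ds[1:16], cfg)
  expect_equal(nrow(trainHistory(m1)), 3L)
  expect_equal(names(trainHistory(m1)),
               c("epoch", "train_acc", "val_acc", "train_loss", "val_loss"))
  m2 <- trainModel(spec, ds, ds[1:16], cfg)
  expect_identical(trainHistory(m1), trainHistory(m2))
  m3 <- trainModel(spec, ds, ds[1:16],
                   trainingConfig(epochs = 3, batchSize = 16, seed = 6))
  expect_false(identical(trainHistory(m1)$train_loss,
                         trainHistory(m3)$train_loss))
})

test_that("all three architectures train and predict on the same data", {
  ds <- randomDataset(40, 32, 8, seed = 2)
  for (build in list(buildUnet, buildCnn, buildMobileNet1d)) {
    spec <- build(32, 8)
    m <- trainModel(spec, ds, ds[1:8],
                    trainingConfig(epochs = 2, batchSize = 20, seed = 1))
    pr <- predict(m, ds)
    expect_equal(dim(pr$prob), c(40L, 2L))
    expect_true(all(abs(rowSums(pr$prob) - 1) < 1e-6))
    expect_true(all(pr$label %in% c("methylated", "unmethylated")))
  }
})

test_that("prediction ties resolve to the unmethylated class", {
  ds <- randomDataset(12, 20, 4, seed = 3)
  m <- trainModel(buildUnet(20, 4), ds, ds[1:6],
                  trainingConfig(epochs = 1, batchSize = 12, seed = 1))
  # zero the head: logits are exactly (0, 0) -> probabilities (0.5, 0.5)
  m@parameters$fc.W[] <- 0
  m@parameters$fc.b[] <- 0
  pr <- predict(m, ds)
  expect_true(all(pr$prob == 0.5))
  expect_true(all(pr$label == "unmethylated"))
})

test_that("shape and class-composition preconditions are enforced", {
  ds <- randomDataset(20, 20, 4, seed = 4)
  expect_error(trainModel(buildUnet(24, 4), ds, ds[1:4]),
               "does not match")
  oneClass <- ds
  oneClass@labels <- factor(rep("methylated", 20),
                            levels = c("unmethylated", "methylated"))
  expect_error(trainModel(buildUnet(20, 4), oneClass, ds[1:4]),
               "both classes")
  m <- trainModel(buildUnet(20, 4), ds, ds[1:4],
                  trainingConfig(epochs = 1, seed = 1))
  expect_error(predict(m, randomDataset(5, 24, 4)), "does not match")
})

test_that("analytic gradients agree with finite differences", {
  ns <- asNamespace("methylUNet")
  for (build in list(buildUnet, buildCnn, buildMobileNet1d)) {
    spec <- build(20, 3)
    set.seed(11)
    ini <- ns$.initParams(spec)
    x <- array(runif(4 * 20 * 3), c(4, 20, 3))
    y <- c(1L, 2L, 1L, 2L)
    fw <- ns$.forward(spec, ini$params, ini$state, x, training = TRUE)
    sm <- ns$nnSoftmaxCE(fw$logits, y)
    g <- ns$.backward(spec, ini$params, fw$cache, sm$dlogits)
    lossAt <- function(p) {
      f <- ns$.forward(spec, p, ini$state, x, training = TRUE)
      ns$nnSoftmaxCE(f$logits, y)$loss
    }
    for (nm in sample(names(ini$params), 6)) {
      i <- sample(length(ini$params[[nm]]), 1)
      eps <- 1e-5
      up <- ini$params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- ini$params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (lossAt(up) - lossAt(dn)) / (2 * eps)
      expect_equal(g[[nm]][i], num, tolerance = 1e-4,
                   label = sprintf("%s grad %s[%d]", spec@architecture,
                                   nm, i))
    }
  }
})

test_that("checkpoints round-trip with a self-describing manifest", {
  ds <- randomDataset(16, 20, 4, seed = 6)
  m <- trainModel(buildCnn(20, 4), ds, ds[1:4],
                  trainingConfig(epochs = 2, seed = 9))
  dir <- withr::local_tempdir()
  writeCheckpoint(m, dir)
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_equal(mf$architecture, "cnn1d")
  expect_equal(mf$seed, 9L)
  expect_equal(mf$class_order[[1]], "unmethylated")
  hist <- read.delim(file.path(dir, "history.tsv"))
  expect_equal(nrow(hist), 2L)
  back <- readCheckpoint(dir)
  expect_equal(predict(back, ds)$prob, predict(m, ds)$prob)
})
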