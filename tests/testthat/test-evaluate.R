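test_that("confusion counts follow the positive = methylated convention", {
  truth <- rep(c("methylated", "unmethylated"), each = 10)
  cm <- confusionMatrix(truth, truth)
  expect_equal(confusionCounts(cm),
               c(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  cm2 <- confusionMatrix(truth, rep("methylated", 20))
  expect_equal(confusionCounts(cm2),
               c(tp = 10L, fp = 10L, tn = 0L, fn = 0L))
  # hand case tallied element by element
  tr <- c("methylated", "methylated", "unmethylated", "unmethylated",
          "methylated", "unmethylated")
  pr <- c("methylated", "unmethylated", "unmethylated", "methylated",
          "methylated", "unmethylated")
  cm3 <- confusionMatrix(tr, pr)
  expect_equal(confusionCounts(cm3), c(tp = 2L, fp = 1L, tn = 2L, fn = 1L))
  expect_error(confusionMatrix(tr, pr[1:3]), "lengths differ")
  expect_error(confusionMatrix("methylated", "maybe"), "labels must be")
})

test_that("scalar metrics reproduce the flagship published tuple exactly", {
  cm <- new("ConfusionMatrix", tp = 441L, fn = 15L, fp = 69L, tn = 475L)
  m <- methylUNet:::roundHalfUp(100 * scalarMetrics(cm))
  expect_equal(m[["sn"]], 96.71)
  expect_equal(m[["sp"]], 87.32)
  expect_equal(m[["acc"]], 91.60)
  expect_equal(m[["mcc"]], 83.72)
  expect_equal(m[["precision"]], 86.47)
  expect_equal(m[["f1"]], 91.30)
})

test_that("degenerate classifiers give extreme or undefined metrics, not errors", {
  perfect <- new("ConfusionMatrix", tp = 50L, tn = 50L, fp = 0L, fn = 0L)
  mp <- scalarMetrics(perfect)
  expect_equal(unname(mp[c("sn", "sp", "acc", "precision", "f1")]),
               rep(1, 5))
  expect_equal(mp[["mcc"]], 1)

  allPos <- new("ConfusionMatrix", tp = 10L, fp = 10L, tn = 0L, fn = 0L)
  ma <- scalarMetrics(allPos)
  expect_equal(ma[["sn"]], 1)
  expect_equal(ma[["sp"]], 0)
  expect_equal(ma[["acc"]], 0.5)
  expect_equal(ma[["precision"]], 0.5)
  expect_true(is.na(ma[["mcc"]]))   # a zero product in the denominator

  allNeg <- new("ConfusionMatrix", tp = 0L, fp = 0L, tn = 10L, fn = 10L)
  expect_true(is.na(scalarMetrics(allNeg)[["precision"]]))
})

test_that("accuracy and MCC are invariant under class swap, SN and SP exchange", {
  set.seed(21)
  for (rep in 1:20) {
    cts <- as.integer(rmultinom(1, 200, c(0.3, 0.2, 0.3, 0.2)))
    cm <- new("ConfusionMatrix", tp = cts[1], fp = cts[2], tn = cts[3],
              fn = cts[4])
    sw <- new("ConfusionMatrix", tp = cts[3], fp = cts[4], tn = cts[1],
              fn = cts[2])
    m1 <- scalarMetrics(cm); m2 <- scalarMetrics(sw)
    expect_equal(m1[["acc"]], m2[["acc"]])
    expect_equal(m1[["mcc"]], m2[["mcc"]])
    expect_equal(m1[["sn"]], m2[["sp"]])
    expect_equal(m1[["sp"]], m2[["sn"]])
  }
})

test_that("ROC handles perfect, inverted and tied scores", {
  truth <- rep(c("methylated", "unmethylated"), each = 5)
  sep <- c(seq(0.9, 0.5, length.out = 5), seq(0.4, 0.1, length.out = 5))
  expect_equal(rocCurve(truth, sep)$auroc, 1)
  expect_equal(rocCurve(truth, 1 - sep)$auroc, 0)
  expect_equal(rocCurve(truth, rep(0.5, 10))$auroc, 0.5)
  r <- rocCurve(truth, sep)
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_true(is.na(rocCurve(rep("methylated", 4), runif(4))$auroc))
})

test_that("AUROC equals the Mann-Whitney U normalization on random cases", {
  set.seed(22)
  for (rep in 1:40) {
    n <- sample(6:50, 1)
    truth <- sample(c("methylated", "unmethylated"), n, replace = TRUE)
    if (length(unique(truth)) < 2) next
    # coarse scores force heavy tie structure
    scores <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    expect_equal(rocCurve(truth, scores)$auroc, oracleAUROC(truth, scores))
  }
})

test_that("AUROC agrees with an independent reference implementation", {
  set.seed(23)
  truth <- sample(c("methylated", "unmethylated"), 80, replace = TRUE)
  scores <- runif(80)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = truth, predictor = scores, levels = c("unmethylated",
                                                     "methylated"),
    direction = "<", quiet = TRUE)))
  expect_equal(rocCurve(truth, scores)$auroc, ref)
})

test_that("PR curve endpoints and areas follow the stated conventions", {
  truth <- rep(c("methylated", "unmethylated"), each = 5)
  sep <- c(seq(0.9, 0.5, length.out = 5), seq(0.4, 0.1, length.out = 5))
  expect_equal(prCurve(truth, sep)$auprc, 1)
  # constant scores: a single point at recall 1 with precision = prevalence
  mixed <- c(rep("methylated", 3), rep("unmethylated", 7))
  expect_equal(prCurve(mixed, rep(0.4, 10))$auprc, 0.3)
  expect_true(is.na(prCurve(rep("unmethylated", 5), runif(5))$auprc))
  set.seed(24)
  for (rep in 1:25) {
    n <- sample(6:40, 1)
    truth <- sample(c("methylated", "unmethylated"), n, replace = TRUE)
    if (!any(truth == "methylated")) next
    scores <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)
    expect_equal(prCurve(truth, scores)$auprc, oraclePR(truth, scores))
  }
})

test_that("printed metric tuples back-solve to the published error counts", {
  s1 <- solveConfusionMatrix(1000, 91.60, 96.71, 87.32)
  expect_equal(nrow(s1), 1L)
  expect_true(attr(s1, "unique"))
  expect_equal(as.integer(s1[1, ]), c(441L, 15L, 69L, 475L))

  s2 <- solveConfusionMatrix(2000, 87.15, 83.84, 88.53)
  expect_true(any(s2$fn == 95 & s2$fp == 162))

  s3 <- solveConfusionMatrix(1000, 74.00, 55.95, 82.15)
  expect_true(any(s3$fn == 137))

  # an impossible tuple comes back empty rather than erroring
  none <- solveConfusionMatrix(10, 99.99, 1.01, 1.02)
  expect_equal(nrow(none), 0L)
  expect_false(attr(none, "unique"))
})

test_that("every back-solved matrix reproduces its tuple after 2-dp rounding", {
  r2 <- methylUNet:::roundHalfUp
  set.seed(25)
  for (rep in 1:15) {
    n <- sample(c(200, 500, 1000), 1)
    P <- sample(seq(50, n - 50), 1)
    tp <- sample(0:P, 1); tn <- sample(0:(n - P), 1)
    tuple <- c(acc = r2(100 * (tp + tn) / n), sn = r2(100 * tp / P),
               sp = r2(100 * tn / (n - P)))
    sols <- solveConfusionMatrix(n, tuple["acc"], tuple["sn"], tuple["sp"])
    expect_gte(nrow(sols), 1L)   # the generating matrix must be recovered
    for (j in seq_len(nrow(sols))) {
      m <- scalarMetrics(new("ConfusionMatrix", tp = sols$tp[j],
                             fn = sols$fn[j], fp = sols$fp[j],
                             tn = sols$tn[j]))
      expect_equal(r2(100 * m[["acc"]]), unname(tuple["acc"]))
      expect_equal(r2(100 * m[["sn"]]), unname(tuple["sn"]))
      expect_equal(r2(100 * m[["sp"]]), unname(tuple["sp"]))
    }
  }
})

test_that("evaluation reports serialize with the conventional column order", {
  truth <- factor(rep(c("methylated", "unmethylated"), each = 10),
                  levels = c("unmethylated", "methylated"))
  cm <- confusionMatrix(truth, truth)
  roc <- rocCurve(truth, c(runif(10, 0.6, 1), runif(10, 0, 0.4)))
  pr <- prCurve(truth, c(runif(10, 0.6, 1), runif(10, 0, 0.4)))
  rep_ <- new("EvalReport", cm = cm, metrics = scalarMetrics(cm),
              auroc = roc$auroc, auprc = pr$auprc, roc = roc$points,
              pr = pr$points)
  row <- reportRow(rep_)
  expect_equal(names(row)[1:6],
               c("ACC", "SN", "SP", "MCC", "Precision", "F1"))
  expect_equal(row$AUROC100, 100 * row$AUROC)
  dir <- withr::local_tempdir()
  writeEvalReport(rep_, dir)
  expect_true(all(file.exists(file.path(dir, c(
    "metrics.json", "metrics.tsv", "roc_points.tsv", "pr_points.tsv")))))
  js <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(js$ACC, 100)
})
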