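#' Build a 2x2 confusion matrix
#'
#' Counts are taken with methylated as the positive class.
#'
#' @param truth,predicted factors (or characters) over
#'   \{unmethylated, methylated\}, equal length.
#' @return a \linkS4class{ConfusionMatrix}.
#' @examples
#' confusionMatrix(c("methylated", "unmethylated"),
#'                 c("methylated", "methylated"))
#' @export
confusionMatrix <- function(truth, predicted) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stopValidation("truth and predicted lengths differ")
  if (length(truth) < 1L) stopValidation("empty label vectors")
  known <- c("methylated", "unmethylated")
  if (!all(truth %in% known) || !all(predicted %in% known))
    stopValidation("labels must be 'methylated' or 'unmethylated'")
  tPos <- truth == "methylated"; pPos <- predicted == "methylated"
  new("ConfusionMatrix",
      tp = sum(tPos & pPos), fp = sum(!tPos & pPos),
      tn = sum(!tPos & !pPos), fn = sum(tPos & !pPos))
}

#' Scalar metrics from a confusion matrix
#'
#' SN = TP/(TP+FN), SP = TN/(TN+FP), ACC = (TP+TN)/total, MCC =
#' (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)), precision =
#' TP/(TP+FP) and F-1 = 2*precision*SN/(precision+SN), all on the 0-1
#' scale. A zero denominator yields \code{NA} (an explicit undefined
#' marker), never an exception, so degenerate classifiers stay visible.
#'
#' @param cm a \linkS4class{ConfusionMatrix}.
#' @return named numeric vector: \code{sn}, \code{sp}, \code{acc},
#'   \code{mcc}, \code{precision}, \code{f1}.
#' @examples
#' cm <- new("ConfusionMatrix", tp = 441L, fn = 15L, fp = 69L, tn = 475L)
#' round(100 * scalarMetrics(cm), 2)
#' @export
scalarMetrics <- function(cm) {
  tp <- as.numeric(cm@tp); fp <- as.numeric(cm@fp)
  tn <- as.numeric(cm@tn); fn <- as.numeric(cm@fn)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  sn <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  acc <- div(tp + tn, tp + tn + fp + fn)
  den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (den == 0) NA_real_ else (tp * tn - fp * fn) / sqrt(den)
  prec <- div(tp, tp + fp)
  f1 <- if (is.na(prec) || is.na(sn) || prec + sn == 0) NA_real_ else
    2 * prec * sn / (prec + sn)
  c(sn = sn, sp = sp, acc = acc, mcc = mcc, precision = prec, f1 = f1)
}

.scoreInput <- function(truth, scores) {
  truth <- as.character(truth)
  if (length(truth) != length(scores))
    stopValidation("truth and scores lengths differ")
  if (any(!is.finite(scores))) stopValidation("scores must be finite")
  truth == "methylated"
}

#' ROC curve and AUROC
#'
#' Sweeps every distinct score as a threshold (ties grouped, one point per
#' distinct score), reporting (FPR, TPR) points anchored at (0,0) and
#' (1,1); the area is by the trapezoidal rule. A single-class truth vector
#' gives an \code{NA} area.
#'
#' @param truth labels over \{unmethylated, methylated\}.
#' @param scores positive-class (methylated) probabilities or scores.
#' @return list with \code{points} (data.frame threshold/fpr/tpr) and
#'   \code{auroc}.
#' @export
rocCurve <- function(truth, scores) {
  pos <- .scoreInput(truth, scores)
  P <- sum(pos); N <- sum(!pos)
  if (P == 0 || N == 0)
    return(list(points = data.frame(threshold = numeric(0),
                                    fpr = numeric(0), tpr = numeric(0)),
                auroc = NA_real_))
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(pos & scores == t), numeric(1)))
  fp <- cumsum(vapply(thr, function(t) sum(!pos & scores == t), numeric(1)))
  pts <- data.frame(threshold = c(Inf, thr), fpr = c(0, fp / N),
                    tpr = c(0, tp / P))
  auroc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                                  utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auroc = auroc)
}

#' Precision-recall curve and AUPRC
#'
#' Precision/recall at every distinct-score threshold (ties grouped); the
#' recall = 0 endpoint extends the first precision value, and the area is
#' the trapezoid over recall. With no positive examples the area is
#' \code{NA}.
#'
#' @inheritParams rocCurve
#' @return list with \code{points} (data.frame threshold/recall/precision)
#'   and \code{auprc}.
#' @export
prCurve <- function(truth, scores) {
  pos <- .scoreInput(truth, scores)
  P <- sum(pos)
  if (P == 0)
    return(list(points = data.frame(threshold = numeric(0),
                                    recall = numeric(0),
                                    precision = numeric(0)),
                auprc = NA_real_))
  thr <- sort(unique(scores), decreasing = TRUE)
  tp <- cumsum(vapply(thr, function(t) sum(pos & scores == t), numeric(1)))
  np <- cumsum(vapply(thr, function(t) sum(scores == t), numeric(1)))
  rec <- tp / P
  prec <- tp / np
  pts <- data.frame(threshold = c(Inf, thr), recall = c(0, rec),
                    precision = c(prec[1], prec))
  auprc <- sum(diff(pts$recall) * (utils::head(pts$precision, -1) +
                                     utils::tail(pts$precision, -1)) / 2)
  list(points = pts, auprc = auprc)
}

#' Back-solve integer confusion matrices from printed metric tuples
#'
#' Given a total count and ACC/SN/SP printed to two decimals (percent),
#' searches every positive-count P in 1..n-1, forms TP = round(SN*P/100)
#' and TN = round(SP*(n-P)/100) (half-up rounding), and keeps every
#' (tp, fp, tn, fn) whose recomputed ACC, SN and SP all round (half-up,
#' 2 dp) back to the inputs. An empty result signals an inconsistent
#' tuple; attribute \code{"unique"} reports whether exactly one solution
#' exists.
#'
#' @param n total number of evaluated sites (n >= 2).
#' @param acc,sn,sp printed percentages in [0, 100].
#' @return data.frame with columns tp, fn, fp, tn (one row per solution).
#' @examples
#' solveConfusionMatrix(1000, 91.60, 96.71, 87.32)
#' @export
solveConfusionMatrix <- function(n, acc, sn, sp) {
  n <- as.integer(n)
  if (n < 2L) stopValidation("need n >= 2")
  if (any(c(acc, sn, sp) < 0 | c(acc, sn, sp) > 100))
    stopValidation("metrics must be percentages in [0, 100]")
  sols <- list()
  for (P in seq_len(n - 1L)) {
    Nn <- n - P
    tp <- floor(sn * P / 100 + 0.5)
    tn <- floor(sp * Nn / 100 + 0.5)
    if (tp > P || tn > Nn) next
    fn <- P - tp; fp <- Nn - tn
    okAcc <- roundHalfUp(100 * (tp + tn) / n) == roundHalfUp(acc)
    okSn <- roundHalfUp(100 * tp / P) == roundHalfUp(sn)
    okSp <- roundHalfUp(100 * tn / Nn) == roundHalfUp(sp)
    if (okAcc && okSn && okSp)
      sols[[length(sols) + 1L]] <- c(tp = as.integer(tp),
                                     fn = as.integer(fn),
                                     fp = as.integer(fp),
                                     tn = as.integer(tn))
  }
  out <- if (length(sols)) as.data.frame(do.call(rbind, sols)) else
    data.frame(tp = integer(0), fn = integer(0), fp = integer(0),
               tn = integer(0))
  attr(out, "unique") <- nrow(out) == 1L
  out
}

#' Evaluate a trained model on a dataset
#'
#' Runs \code{\link[=predict,TrainedModel-method]{predict}}, tallies the
#' confusion matrix against the dataset labels, and computes all scalar
#' metrics plus ROC/AUROC and PR/AUPRC curves from the methylated-class
#' probability.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param data an \linkS4class{EncodedDataset} with labels.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateModel <- function(model, data) {
  pr <- predict(model, data)
  truth <- siteLabels(data)
  cm <- confusionMatrix(truth, pr$label)
  roc <- rocCurve(truth, pr$prob[, "methylated"])
  prc <- prCurve(truth, pr$prob[, "methylated"])
  new("EvalReport", cm = cm, metrics = scalarMetrics(cm),
      auroc = roc$auroc, auprc = prc$auprc, roc = roc$points,
      pr = prc$points)
}

#' Flatten an EvalReport to a one-row percent-scale table
#'
#' Columns follow the conventional reporting order (ACC, SN, SP, MCC,
#' precision, F-1, all in percent) with AUROC/AUPRC appended on the 0-1
#' scale plus 0-100 convenience columns.
#'
#' @param report an \linkS4class{EvalReport}.
#' @return a one-row data.frame.
#' @export
reportRow <- function(report) {
  m <- report@metrics
  data.frame(ACC = roundHalfUp(100 * m[["acc"]]),
             SN = roundHalfUp(100 * m[["sn"]]),
             SP = roundHalfUp(100 * m[["sp"]]),
             MCC = roundHalfUp(100 * m[["mcc"]]),
             Precision = roundHalfUp(100 * m[["precision"]]),
             F1 = roundHalfUp(100 * m[["f1"]]),
             AUROC = report@auroc, AUPRC = report@auprc,
             AUROC100 = 100 * report@auroc, AUPRC100 = 100 * report@auprc)
}

#' Serialize an EvalReport
#'
#' Writes the scalar metrics as JSON and the curves as TSV files for
#' external plotting.
#'
#' @param report an \linkS4class{EvalReport}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeEvalReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  row <- reportRow(report)
  jsonlite::write_json(
    c(as.list(row), as.list(confusionCounts(report@cm))),
    file.path(dir, "metrics.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(row, file.path(dir, "metrics.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report@roc, file.path(dir, "roc_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report@pr, file.path(dir, "pr_points.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Basic diagnostic plots
#'
#' Learning curves (training/validation accuracy and loss per epoch) and
#' ROC / precision-recall curves, drawn with base graphics.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param report an \linkS4class{EvalReport}.
#' @return \code{NULL}, invisibly.
#' @export
plotHistory <- function(model) {
  h <- trainHistory(model)
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(h$epoch, h$train_acc, type = "l", ylim = c(0, 1), xlab = "epoch",
       ylab = "accuracy", main = "Accuracy")
  graphics::lines(h$epoch, h$val_acc, lty = 2)
  graphics::legend("bottomright", c("train", "validation"), lty = 1:2,
                   bty = "n")
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       main = "Loss",
       ylim = range(c(h$train_loss, h$val_loss), finite = TRUE))
  graphics::lines(h$epoch, h$val_loss, lty = 2)
  invisible(NULL)
}

#' @rdname plotHistory
#' @export
plotCurves <- function(report) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  plot(report@roc$fpr, report@roc$tpr, type = "l", xlab = "FPR",
       ylab = "TPR", main = sprintf("ROC (AUROC %.3f)", report@auroc))
  graphics::abline(0, 1, lty = 3)
  plot(report@pr$recall, report@pr$precision, type = "l", ylim = c(0, 1),
       xlab = "recall", ylab = "precision",
       main = sprintf("PR (AUPRC %.3f)", report@auprc))
  invisible(NULL)
}
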