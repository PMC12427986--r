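#' @include AllClasses.R
NULL

#' Accessors
#'
#' Small accessor generics for the package's S4 containers, in place of
#' direct slot access.
#'
#' @param x an object of the documented class.
#' @return the corresponding component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("windowWidth", function(x) standardGeneric("windowWidth"))
#' @rdname accessors
#' @export
setGeneric("windowSeqs", function(x) standardGeneric("windowSeqs"))
#' @rdname accessors
#' @export
setGeneric("siteRanges", function(x) standardGeneric("siteRanges"))
#' @rdname accessors
#' @export
setGeneric("features", function(x) standardGeneric("features"))
#' @rdname accessors
#' @export
setGeneric("siteLabels", function(x) standardGeneric("siteLabels"))
#' @rdname accessors
#' @export
setGeneric("siteIds", function(x) standardGeneric("siteIds"))
#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname accessors
#' @export
setGeneric("schemeName", function(x) standardGeneric("schemeName"))
#' @rdname accessors
#' @export
setGeneric("lengthLadder", function(x) standardGeneric("lengthLadder"))
#' @rdname accessors
#' @export
setGeneric("modelSpec", function(x) standardGeneric("modelSpec"))
#' @rdname accessors
#' @export
setGeneric("trainHistory", function(x) standardGeneric("trainHistory"))
#' @rdname accessors
#' @export
setGeneric("nParameters", function(x) standardGeneric("nParameters"))
#' @rdname accessors
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))
#' @rdname accessors
#' @export
setGeneric("bayesAccuracy", function(x) standardGeneric("bayesAccuracy"))

#' Row count of an encoding scheme for a window of length L
#'
#' Monomer encoding keeps one row per base (L rows); the dimer schemes use
#' overlapping dinucleotides (L - 1 rows).
#'
#' @param x an \linkS4class{EncodingScheme}.
#' @param L window length in bases.
#' @return integer number of feature rows.
#' @examples
#' rowCount(encodingScheme("dimer"), 300L)  # 299
#' @export
setGeneric("rowCount", function(x, L) standardGeneric("rowCount"))

#' @rdname rowCount
#' @export
setMethod("rowCount", "EncodingScheme", function(x, L) {
  L <- as.integer(L)
  if (x@name == "monomer") L else L - 1L
})

#' @rdname accessors
#' @export
setMethod("windowWidth", "MethylWindows", function(x) x@width)
#' @rdname accessors
#' @export
setMethod("windowSeqs", "MethylWindows", function(x) x@seqs)
#' @rdname accessors
#' @export
setMethod("siteRanges", "MethylWindows", function(x) x@sites)
#' @rdname accessors
#' @export
setMethod("siteLabels", "MethylWindows", function(x) x@sites$label)

#' @rdname accessors
#' @export
setMethod("features", "EncodedDataset", function(x) x@features)
#' @rdname accessors
#' @export
setMethod("siteLabels", "EncodedDataset", function(x) x@labels)
#' @rdname accessors
#' @export
setMethod("siteIds", "EncodedDataset", function(x) x@siteIds)
#' @rdname accessors
#' @export
setMethod("scheme", "EncodedDataset", function(x) x@scheme)
#' @rdname accessors
#' @export
setMethod("schemeName", "EncodedDataset", function(x) x@scheme@name)

#' Subset an EncodedDataset by site index
#'
#' @param x an \linkS4class{EncodedDataset}.
#' @param i integer or logical index over sites.
#' @param j,... unused.
#' @param drop unused.
#' @return the subsetted \linkS4class{EncodedDataset}.
#' @export
setMethod("[", "EncodedDataset", function(x, i, j, ..., drop = FALSE) {
  new("EncodedDataset", features = x@features[i, , , drop = FALSE],
      labels = x@labels[i], scheme = x@scheme, siteIds = x@siteIds[i])
})

#' @rdname accessors
#' @export
setMethod("lengthLadder", "ModelSpec", function(x) x@ladder)
#' @rdname accessors
#' @export
setMethod("lengthLadder", "TrainedModel", function(x) x@spec@ladder)
#' @rdname accessors
#' @export
setMethod("modelSpec", "TrainedModel", function(x) x@spec)
#' @rdname accessors
#' @export
setMethod("trainHistory", "TrainedModel", function(x) x@history)

#' @rdname accessors
#' @export
setMethod("confusionCounts", "ConfusionMatrix", function(x) {
  c(tp = x@tp, fp = x@fp, tn = x@tn, fn = x@fn)
})

#' @rdname accessors
#' @export
setMethod("bayesAccuracy", "SyntheticMethylome", function(x) x@bayesAccuracy)

setMethod("show", "EncodingScheme", function(object) {
  cat(sprintf("EncodingScheme '%s' (%d channels)\n", object@name,
              object@channels))
})

setMethod("show", "MethylWindows", function(object) {
  cat(sprintf("MethylWindows: %d windows of width %d bp (CpG C at offset %d)\n",
              length(object@seqs), object@width, object@width %/% 2L + 1L))
  if (length(object@sites) > 0) {
    tab <- table(object@sites$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "EncodedDataset", function(object) {
  d <- dim(object@features)
  cat(sprintf("EncodedDataset: %d x %d x %d (%s encoding)\n",
              d[1], d[2], d[3], object@scheme@name))
  tab <- table(object@labels)
  cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %s for input %d x %d\n", object@architecture,
              object@inputLength, object@inputChannels))
  cat("  encoder lengths:", paste(object@ladder$encoder, collapse = " -> "),
      "\n")
  if (length(object@ladder$decoder))
    cat("  decoder lengths:", paste(object@ladder$decoder, collapse = " -> "),
        "\n")
})

setMethod("show", "TrainedModel", function(object) {
  h <- object@history
  cat(sprintf("TrainedModel: %s, %d epochs\n", object@spec@architecture,
              nrow(h)))
  cat(sprintf("  final train acc %.3f / val acc %.3f\n",
              h$train_acc[nrow(h)], h$val_acc[nrow(h)]))
})

setMethod("show", "ConfusionMatrix", function(object) {
  m <- matrix(c(object@tp, object@fn, object@fp, object@tn), 2, 2,
              dimnames = list(truth = c("methylated", "unmethylated"),
                              predicted = c("methylated", "unmethylated")))
  cat("ConfusionMatrix (positive = methylated)\n")
  print(m)
})

setMethod("show", "EvalReport", function(object) {
  cat("EvalReport\n")
  pc <- function(v) ifelse(is.na(v), "NA", sprintf("%.2f%%", 100 * v))
  m <- object@metrics
  cat(sprintf("  ACC %s  SN %s  SP %s  MCC %s  precision %s  F-1 %s\n",
              pc(m["acc"]), pc(m["sn"]), pc(m["sp"]),
              ifelse(is.na(m["mcc"]), "NA", sprintf("%.4f", m["mcc"])),
              pc(m["precision"]), pc(m["f1"])))
  cat(sprintf("  AUROC %s  AUPRC %s\n",
              ifelse(is.na(object@auroc), "NA", sprintf("%.4f", object@auroc)),
              ifelse(is.na(object@auprc), "NA", sprintf("%.4f", object@auprc))))
})

setMethod("show", "SyntheticRule", function(object) {
  cat(sprintf(
    "SyntheticRule: motif %s within +/-%d bp -> beta ~ %g%%, else %g%% (spread %g)\n",
    object@motif, object@motifWindow, object@betaHighMean,
    object@betaLowMean, object@betaSpread))
})

setMethod("show", "SyntheticMethylome", function(object) {
  cat(sprintf(
    "SyntheticMethylome: %d sites on %s (%d bp), Bayes accuracy %.3f\n",
    length(object@sites), names(object@genome)[1],
    Biostrings::width(object@genome)[1], object@bayesAccuracy))
})
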