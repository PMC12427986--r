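#' @import methods
#' @importFrom S4Vectors mcols mcols<-
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom Biostrings DNAStringSet
NULL

.CLASS_ORDER <- c("unmethylated", "methylated")

#' EncodingScheme: how a window sequence becomes a one-hot matrix
#'
#' A scheme names the featureization of a nucleotide window: \code{monomer}
#' (one row per base, 4 channels in A,C,G,T order), \code{dimer} (one row per
#' overlapping dinucleotide, 8 channels = first-base one-hot followed by
#' second-base one-hot), or \code{dimer16} (one row per overlapping
#' dinucleotide, 16-way one-hot over the 16 dinucleotides).
#'
#' @slot name scheme name, one of \code{"monomer"}, \code{"dimer"},
#'   \code{"dimer16"}.
#' @slot channels number of feature channels per row.
#' @export
setClass("EncodingScheme",
  representation(name = "character", channels = "integer"),
  validity = function(object) {
    chan <- c(monomer = 4L, dimer = 8L, dimer16 = 16L)
    if (!object@name %in% names(chan))
      return(sprintf("unknown scheme '%s'", object@name))
    if (object@channels != chan[[object@name]])
      return(sprintf("scheme '%s' must have %d channels", object@name,
                     chan[[object@name]]))
    TRUE
  })

#' Constructor for EncodingScheme
#'
#' @param name one of \code{"monomer"}, \code{"dimer"}, \code{"dimer16"}.
#' @return an \linkS4class{EncodingScheme}.
#' @examples
#' encodingScheme("dimer")
#' @export
encodingScheme <- function(name = c("monomer", "dimer", "dimer16")) {
  name <- match.arg(name)
  chan <- c(monomer = 4L, dimer = 8L, dimer16 = 16L)
  new("EncodingScheme", name = name, channels = chan[[name]])
}

#' MethylWindows: fixed-width sequence windows centered on CpG sites
#'
#' Each window is a \code{width}-bp stretch of genome sequence whose center
#' carries the C of a CpG dinucleotide: with 1-based in-window coordinates
#' the C sits at index \code{width/2 + 1} and the G at \code{width/2 + 2}.
#'
#' @slot seqs a \linkS4class{DNAStringSet} of equal-width window sequences.
#' @slot sites a \linkS4class{GRanges} of the originating CpG sites (1-based
#'   position of the C), with metadata columns \code{beta} and \code{label}.
#' @slot width the (even) window width in bp.
#' @export
setClass("MethylWindows",
  representation(seqs = "DNAStringSet", sites = "GRanges", width = "integer"),
  validity = function(object) {
    if (length(object@seqs) != length(object@sites))
      return("seqs and sites lengths differ")
    if (object@width %% 2L != 0L || object@width <= 0L)
      return("width must be a positive even integer")
    if (length(object@seqs) > 0 &&
        !all(Biostrings::width(object@seqs) == object@width))
      return("all window sequences must have length equal to width")
    TRUE
  })

#' EncodedDataset: a batch of one-hot encoded windows with labels
#'
#' @slot features numeric array of dimension n x L' x C, entries in {0,1};
#'   L' is \code{width} for monomer and \code{width - 1} for dimer schemes.
#' @slot labels factor of length n with levels
#'   \code{c("unmethylated", "methylated")}.
#' @slot scheme the \linkS4class{EncodingScheme} used.
#' @slot siteIds character vector of length n (provenance, "chrom:pos").
#' @export
setClass("EncodedDataset",
  representation(features = "array", labels = "factor",
                 scheme = "EncodingScheme", siteIds = "character"),
  validity = function(object) {
    d <- dim(object@features)
    if (length(d) != 3L) return("features must be a 3-d array (n x L' x C)")
    if (d[1] != length(object@labels)) return("n != length(labels)")
    if (d[1] != length(object@siteIds)) return("n != length(siteIds)")
    if (d[3] != object@scheme@channels)
      return("channel dimension does not match scheme")
    if (!identical(levels(object@labels), .CLASS_ORDER))
      return("labels must have levels c('unmethylated','methylated')")
    if (length(object@features) &&
        !all(object@features %in% c(0, 1)))
      return("features must be 0/1")
    TRUE
  })

#' ModelSpec: architecture hyper-parameters for a 1-D classifier
#'
#' Describes one of the three supported architectures together with the
#' length ladder its pooling/upsampling stages produce for the given input.
#'
#' @slot architecture one of \code{"unet1d"}, \code{"cnn1d"},
#'   \code{"mobilenet1d"}.
#' @slot inputLength number of feature rows L'.
#' @slot inputChannels number of feature channels C.
#' @slot encoderFilters filter counts along the encoder (16, 32, 64).
#' @slot decoderFilters filter counts along the decoder (64, 32, 16).
#' @slot poolFactor down/up-sampling factor (4).
#' @slot kernelSize convolution kernel width (3).
#' @slot classOrder output class order; class 1 is \code{"unmethylated"}.
#' @slot ladder list with \code{encoder} and \code{decoder} length sequences.
#' @slot extra architecture-specific settings (MobileNet block plan).
#' @export
setClass("ModelSpec",
  representation(architecture = "character", inputLength = "integer",
                 inputChannels = "integer", encoderFilters = "integer",
                 decoderFilters = "integer", poolFactor = "integer",
                 kernelSize = "integer", classOrder = "character",
                 ladder = "list", extra = "list"),
  validity = function(object) {
    if (!object@architecture %in% c("unet1d", "cnn1d", "mobilenet1d"))
      return("unknown architecture")
    if (!identical(object@classOrder, .CLASS_ORDER))
      return("classOrder must be c('unmethylated','methylated')")
    TRUE
  })

#' TrainingConfig: optimization settings
#'
#' @slot epochs number of full passes over the training set (no early
#'   stopping); default 50.
#' @slot batchSize minibatch size; default 32.
#' @slot learningRate Adam step size; default 1e-3.
#' @slot seed integer seed fixing initialization and batch order.
#' @export
setClass("TrainingConfig",
  representation(epochs = "integer", batchSize = "integer",
                 learningRate = "numeric", seed = "integer"),
  validity = function(object) {
    if (object@epochs < 1L) return("epochs must be >= 1")
    if (object@batchSize < 1L) return("batchSize must be >= 1")
    if (object@learningRate <= 0) return("learningRate must be positive")
    TRUE
  })

#' Constructor for TrainingConfig
#'
#' @param epochs,batchSize,learningRate,seed see \linkS4class{TrainingConfig}.
#' @return a \linkS4class{TrainingConfig}.
#' @examples
#' trainingConfig(epochs = 5, seed = 1)
#' @export
trainingConfig <- function(epochs = 50L, batchSize = 32L,
                           learningRate = 1e-3, seed = 1L) {
  new("TrainingConfig", epochs = as.integer(epochs),
      batchSize = as.integer(batchSize),
      learningRate = as.numeric(learningRate), seed = as.integer(seed))
}

#' TrainedModel: a fitted classifier with its training history
#'
#' @slot spec the \linkS4class{ModelSpec} trained.
#' @slot parameters fitted weights (named list of arrays).
#' @slot state batch-normalization running statistics.
#' @slot history data.frame with one row per epoch: \code{epoch},
#'   \code{train_acc}, \code{val_acc}, \code{train_loss}, \code{val_loss}.
#' @slot config the \linkS4class{TrainingConfig} used.
#' @export
setClass("TrainedModel",
  representation(spec = "ModelSpec", parameters = "list", state = "list",
                 history = "data.frame", config = "TrainingConfig"),
  validity = function(object) {
    if (nrow(object@history) != object@config@epochs)
      return("history must have one row per epoch")
    TRUE
  })

#' ConfusionMatrix: 2x2 counts with methylated as the positive class
#'
#' @slot tp,fp,tn,fn nonnegative integer counts.
#' @export
setClass("ConfusionMatrix",
  representation(tp = "integer", fp = "integer", tn = "integer",
                 fn = "integer"),
  validity = function(object) {
    v <- c(object@tp, object@fp, object@tn, object@fn)
    if (any(is.na(v)) || any(v < 0L)) return("counts must be nonnegative")
    TRUE
  })

#' EvalReport: scalar metrics plus ROC and precision-recall curves
#'
#' Scalar metrics are on the 0-1 scale; \code{NA} marks a metric whose
#' denominator is zero (degenerate classifier) rather than silently
#' reporting 0.
#'
#' @slot cm the \linkS4class{ConfusionMatrix}.
#' @slot metrics named numeric: \code{sn}, \code{sp}, \code{acc}, \code{mcc},
#'   \code{precision}, \code{f1}.
#' @slot auroc,auprc areas in [0,1] (\code{NA} when undefined).
#' @slot roc data.frame of ROC points (\code{threshold}, \code{fpr},
#'   \code{tpr}).
#' @slot pr data.frame of PR points (\code{threshold}, \code{recall},
#'   \code{precision}).
#' @export
setClass("EvalReport",
  representation(cm = "ConfusionMatrix", metrics = "numeric",
                 auroc = "numeric", auprc = "numeric",
                 roc = "data.frame", pr = "data.frame"))

#' SyntheticRule: the planted sequence-to-methylation rule
#'
#' Sites whose window contains the motif draw their methylation percentage
#' from a high-mean Beta distribution, all others from a low-mean one; with
#' the 50\% labeling threshold the motif becomes the learnable signal.
#'
#' @slot motif short nucleotide string (default a TATA-box-like 6-mer).
#' @slot betaHighMean,betaLowMean mean methylation percentages of the two
#'   site populations (defaults 80 and 20).
#' @slot betaSpread concentration of the Beta noise around each mean; larger
#'   is less noisy. The default 6 puts the Bayes accuracy of the planted
#'   rule at about 0.95.
#' @slot motifWindow radius in bp around the site within which the motif
#'   counts (default 50, i.e. a 100-bp window).
#' @slot injectFraction fraction of sites that get the motif injected
#'   (default 0.5, balancing the classes).
#' @slot clusterSize number of motif occurrences injected per motif-positive
#'   site (default 3). Methylation-associated sequence features are regional
#'   (CpG islands, AT-rich promoter elements) rather than single hexamer
#'   hits, so the planted element is a small cluster; the labeled rule is
#'   still plain motif presence.
#' @export
setClass("SyntheticRule",
  representation(motif = "character", betaHighMean = "numeric",
                 betaLowMean = "numeric", betaSpread = "numeric",
                 motifWindow = "integer", injectFraction = "numeric",
                 clusterSize = "integer"),
  validity = function(object) {
    if (!(object@betaHighMean > 50 && object@betaLowMean < 50) &&
        object@betaHighMean != object@betaLowMean)
      return("need betaHighMean > 50 > betaLowMean (or equal means)")
    if (nchar(object@motif) >= object@motifWindow)
      return("motif must be shorter than motifWindow")
    if (object@injectFraction < 0 || object@injectFraction > 1)
      return("injectFraction must be in [0,1]")
    if (object@betaSpread <= 0) return("betaSpread must be positive")
    if (object@clusterSize < 1L) return("clusterSize must be >= 1")
    TRUE
  })

#' Constructor for SyntheticRule
#'
#' @param motif,betaHighMean,betaLowMean,betaSpread,motifWindow,injectFraction,clusterSize
#'   see \linkS4class{SyntheticRule}.
#' @return a \linkS4class{SyntheticRule}.
#' @examples
#' syntheticRule()
#' @export
syntheticRule <- function(motif = "TATATA", betaHighMean = 80,
                          betaLowMean = 20, betaSpread = 6,
                          motifWindow = 50L, injectFraction = 0.5,
                          clusterSize = 3L) {
  new("SyntheticRule", motif = toupper(motif),
      betaHighMean = as.numeric(betaHighMean),
      betaLowMean = as.numeric(betaLowMean),
      betaSpread = as.numeric(betaSpread),
      motifWindow = as.integer(motifWindow),
      injectFraction = as.numeric(injectFraction),
      clusterSize = as.integer(clusterSize))
}

#' SyntheticMethylome: a generated genome plus planted methylation table
#'
#' @slot genome single-chromosome \linkS4class{DNAStringSet}.
#' @slot sites \linkS4class{GRanges} of CpG sites with \code{beta},
#'   \code{label} and \code{motif} (motif-in-window indicator) columns.
#' @slot rule the \linkS4class{SyntheticRule} used.
#' @slot seed generator seed.
#' @slot bayesAccuracy best achievable label accuracy under the rule.
#' @export
setClass("SyntheticMethylome",
  representation(genome = "DNAStringSet", sites = "GRanges",
                 rule = "SyntheticRule", seed = "integer",
                 bayesAccuracy = "numeric"),
  validity = function(object) {
    if (object@bayesAccuracy < 0.5 || object@bayesAccuracy > 1)
      return("bayesAccuracy must lie in (0.5, 1]")
    TRUE
  })
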