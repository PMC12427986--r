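#' Default pipeline configuration
#'
#' One configuration list drives every stage (single source of truth);
#' command-line flags override individual keys. Values mirror the study
#' defaults: 300-bp windows with dimer encoding, 5000 sites, a 70:20:10
#' split and 50 training epochs.
#'
#' @param outdir output directory.
#' @return a named list of settings.
#' @export
defaultConfig <- function(outdir = "methylUNet-run") {
  list(
    outdir = outdir,
    genome = NULL,            # FASTA path; NULL means use the simulate stage
    table = NULL,             # methylation TSV path
    coords = "tsv1",          # table dialect: bed0 or tsv1
    window = 300L,            # window size W: 100, 200 or 300
    scheme = "dimer",         # monomer, dimer or dimer16
    sampleSize = 5000L,       # sites to subsample (NULL = keep all)
    fractions = c(0.70, 0.20, 0.10),
    model = "unet1d",         # unet1d, cnn1d or mobilenet1d
    epochs = 50L,
    batchSize = 32L,
    learningRate = 1e-3,
    seed = 1L,
    # simulate-stage settings
    genomeLength = 2e6, gcContent = 0.5, nSites = 5000L,
    motif = "TATATA", betaHighMean = 80, betaLowMean = 20, betaSpread = 6,
    injectFraction = 0.5, clusterSize = 3L)
}

.cfgMerge <- function(cfg, overrides) {
  for (nm in names(overrides))
    if (!is.null(overrides[[nm]])) cfg[[nm]] <- overrides[[nm]]
  cfg
}

#' Run pipeline stages
#'
#' Ties the stages together: \code{simulate} writes a synthetic genome +
#' methylation table fixture; \code{encode} reads genome and table,
#' subsamples, extracts windows, encodes and splits; \code{train} fits the
#' configured model; \code{evaluate} scores the test split and writes the
#' metric report and curve files. Every stage logs its resolved settings
#' and writes its outputs under \code{config$outdir}, so a run can be
#' reproduced from the logged configuration alone.
#'
#' @param config list as from \code{\link{defaultConfig}}.
#' @param stages character vector of stages to run, in order.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the objects produced by the stages run.
#' @export
runPipeline <- function(config = defaultConfig(),
                        stages = c("simulate", "encode", "train",
                                   "evaluate"),
                        quiet = FALSE) {
  cfg <- .cfgMerge(defaultConfig(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  jsonlite::write_json(cfg[!vapply(cfg, is.null, logical(1))],
                       file.path(cfg$outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  out <- list(config = cfg)

  if ("simulate" %in% stages) {
    rule <- syntheticRule(motif = cfg$motif, betaHighMean = cfg$betaHighMean,
                          betaLowMean = cfg$betaLowMean,
                          betaSpread = cfg$betaSpread,
                          motifWindow = cfg$window %/% 2L,
                          injectFraction = cfg$injectFraction,
                          clusterSize = cfg$clusterSize)
    genome <- generateGenome(cfg$genomeLength, cfg$gcContent,
                             seed = cfg$seed)
    sm <- plantMethylome(genome, cfg$nSites, rule, seed = cfg$seed)
    paths <- writeFixture(sm, cfg$outdir)
    say("simulate: %d sites, Bayes accuracy %.3f, seed %d",
        length(sm@sites), bayesAccuracy(sm), cfg$seed)
    cfg$genome <- paths[["fasta"]]
    cfg$table <- paths[["sites"]]
    cfg$coords <- "tsv1"
    out$methylome <- sm
  }

  if ("encode" %in% stages) {
    if (is.null(cfg$genome) || is.null(cfg$table))
      stopValidation("encode stage needs 'genome' and 'table' paths")
    genome <- readGenome(cfg$genome)
    sites <- readMethylationTable(cfg$table, coords = cfg$coords)
    if (!is.null(cfg$sampleSize) && cfg$sampleSize < length(sites))
      sites <- subsampleSites(sites, cfg$sampleSize, seed = cfg$seed)
    windows <- extractWindows(genome, sites, width = cfg$window)
    ed <- encodeWindows(windows, cfg$scheme)
    split <- splitDataset(length(siteLabels(ed)), cfg$fractions,
                          seed = cfg$seed)
    d <- dim(features(ed))
    say("encode: tensor %d x %d x %d (%s), splits %d/%d/%d",
        d[1], d[2], d[3], cfg$scheme, length(split$train),
        length(split$test), length(split$validation))
    writeEncodedDataset(ed[split$train], file.path(cfg$outdir, "train"))
    writeEncodedDataset(ed[split$test], file.path(cfg$outdir, "test"))
    writeEncodedDataset(ed[split$validation],
                        file.path(cfg$outdir, "validation"))
    writeSplitManifest(siteIds(ed), split,
                       file.path(cfg$outdir, "split_manifest.tsv"))
    out$encoded <- ed
    out$split <- split
  }

  if ("train" %in% stages) {
    trainDir <- file.path(cfg$outdir, "train")
    if (!dir.exists(trainDir))
      stopValidation("train stage needs the encode stage's output in %s",
                     cfg$outdir)
    trainSet <- readEncodedDataset(trainDir)
    valSet <- readEncodedDataset(file.path(cfg$outdir, "validation"))
    d <- dim(features(trainSet))
    spec <- switch(cfg$model,
                   unet1d = buildUnet(d[2], d[3]),
                   cnn1d = buildCnn(d[2], d[3]),
                   mobilenet1d = buildMobileNet1d(d[2], d[3]),
                   stopValidation("unknown model '%s'", cfg$model))
    model <- trainModel(spec, trainSet, valSet,
                        trainingConfig(epochs = cfg$epochs,
                                       batchSize = cfg$batchSize,
                                       learningRate = cfg$learningRate,
                                       seed = cfg$seed),
                        verbose = !quiet)
    writeCheckpoint(model, file.path(cfg$outdir, "checkpoint"))
    say("train: %s, %d epochs, final val acc %.3f", cfg$model, cfg$epochs,
        utils::tail(trainHistory(model)$val_acc, 1))
    out$model <- model
  }

  if ("evaluate" %in% stages) {
    ckpt <- file.path(cfg$outdir, "checkpoint")
    if (!dir.exists(ckpt))
      stopValidation("evaluate stage needs a trained checkpoint in %s",
                     cfg$outdir)
    model <- out$model
    if (is.null(model)) model <- readCheckpoint(ckpt)
    testSet <- readEncodedDataset(file.path(cfg$outdir, "test"))
    report <- evaluateModel(model, testSet)
    writeEvalReport(report, file.path(cfg$outdir, "report"))
    if (!quiet) show(report)
    out$report <- report
  }
  invisible(out)
}

#' Score a model on an externally supplied site list (promoter mode)
#'
#' Evaluates an already-trained model on CG sites drawn from user-supplied
#' regions (e.g. gene promoters): reads the site table, extracts and
#' encodes windows with the model's own width and scheme, and returns the
#' standard report schema.
#'
#' @param model a \linkS4class{TrainedModel}.
#' @param genome a \linkS4class{DNAStringSet}.
#' @param sites a \linkS4class{GRanges} with \code{beta} (or \code{label})
#'   metadata, as from \code{\link{readMethylationTable}}.
#' @param width window width used when the model was trained.
#' @param scheme encoding scheme used when the model was trained.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluateSites <- function(model, genome, sites, width, scheme) {
  windows <- extractWindows(genome, sites, width = width)
  ed <- encodeWindows(windows, scheme)
  evaluateModel(model, ed)
}
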