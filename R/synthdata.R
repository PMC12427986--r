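#' Generate a random genome sequence
#'
#' I.i.d. residues with the requested GC content (split evenly between G
#' and C, and the remainder between A and T); deterministic for a fixed
#' seed.
#'
#' @param length genome length in bp (>= 1000).
#' @param gcContent target GC fraction in (0, 1).
#' @param seed integer seed.
#' @param name chromosome name for the FASTA record.
#' @return a single-record named \linkS4class{DNAStringSet}.
#' @examples
#' generateGenome(2000, 0.5, seed = 7)
#' @export
generateGenome <- function(length, gcContent = 0.5, seed = 1L,
                           name = "chrS") {
  length <- as.integer(length)
  if (length < 1000L) stopValidation("genome length must be >= 1000")
  if (gcContent <= 0 || gcContent >= 1)
    stopValidation("gcContent must lie strictly between 0 and 1")
  probs <- c(A = (1 - gcContent) / 2, C = gcContent / 2,
             G = gcContent / 2, T = (1 - gcContent) / 2)
  res <- withSeed(seed, sample(names(probs), length, replace = TRUE,
                               prob = probs))
  out <- Biostrings::DNAStringSet(paste(res, collapse = ""))
  names(out) <- name
  out
}

.betaShapes <- function(meanPct, spread) {
  mu <- meanPct / 100
  c(shape1 = spread * mu, shape2 = spread * (1 - mu))
}

# P(beta >= 50) under the Beta(mean, concentration) noise model; the
# infinite-spread limit collapses to a point mass at the mean
.pMethylated <- function(meanPct, spread) {
  if (is.infinite(spread)) return(as.numeric(meanPct >= 50))
  sh <- .betaShapes(meanPct, spread)
  stats::pbeta(0.5, sh[1], sh[2], lower.tail = FALSE)
}

# Bayes accuracy of the planted rule: the optimal classifier sees motif
# presence and predicts the majority label of that stratum
.bayesAccuracy <- function(fPresent, rule) {
  pH <- .pMethylated(rule@betaHighMean, rule@betaSpread)
  pL <- .pMethylated(rule@betaLowMean, rule@betaSpread)
  fPresent * max(pH, 1 - pH) + (1 - fPresent) * max(pL, 1 - pL)
}

#' Plant a learnable methylation rule into a genome
#'
#' Selects \code{nSites} CG positions (spaced so their windows do not
#' interact), injects a small cluster of the rule's motif
#' (\code{clusterSize} occurrences) into the window of a fraction of them,
#' and draws each site's methylation percentage from a high-mean Beta
#' distribution when the motif occurs within \code{motifWindow} bp of the
#' site (whether injected or by chance) and from a low-mean one otherwise. Labels then follow the 50\% threshold, so
#' motif presence is the learnable signal; the returned object reports the
#' Bayes accuracy this rule and noise level imply.
#'
#' @param genome a single-record \linkS4class{DNAStringSet} (e.g. from
#'   \code{\link{generateGenome}}).
#' @param nSites number of CpG sites to select.
#' @param rule a \linkS4class{SyntheticRule}.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticMethylome}; its genome carries the
#'   injected motifs.
#' @export
plantMethylome <- function(genome, nSites, rule = syntheticRule(),
                           seed = 1L) {
  nSites <- as.integer(nSites)
  chrName <- names(genome)[1]
  chr <- as.character(genome[[1]])
  glen <- nchar(chr)
  half <- rule@motifWindow
  mlen <- nchar(rule@motif)
  W <- 2L * half

  cg <- Biostrings::start(Biostrings::matchPattern("CG", genome[[1]]))
  cg <- cg[cg - half >= 1L & cg + half - 1L <= glen]
  if (length(cg) < nSites)
    stopValidation("genome has only %d usable CG sites, need %d",
                   length(cg), nSites)

  res <- withSeed(seed, {
    # greedy selection with spacing >= W + motif length: windows cannot
    # overlap, so injections never leak into a neighbouring site's window
    minGap <- W + mlen
    cand <- sample(cg)
    kept <- integer(0)
    for (p in cand) {
      if (length(kept) == 0L) { kept <- p; next }
      i <- findInterval(p, kept)
      nearLeft <- if (i >= 1L) p - kept[i] else Inf
      nearRight <- if (i < length(kept)) kept[i + 1L] - p else Inf
      if (min(nearLeft, nearRight) >= minGap) {
        kept <- append(kept, p, after = i)
        if (length(kept) == nSites) break
      }
    }
    if (length(kept) < nSites)
      stopValidation(
        "could only place %d of %d sites with non-overlapping windows",
        length(kept), nSites)
    pos <- kept

    inject <- sample(seq_along(pos), round(rule@injectFraction * nSites))
    chars <- strsplit(chr, "", fixed = TRUE)[[1]]
    motifChars <- strsplit(rule@motif, "", fixed = TRUE)[[1]]
    for (j in inject) {
      p <- pos[j]
      # candidate motif starts: inside the window, clear of the center CG
      lo <- p - half
      hi <- p + half - mlen
      starts <- setdiff(lo:hi, (p - mlen + 1L):(p + 1L))
      ss <- sample(starts, min(rule@clusterSize, length(starts)))
      for (s in ss) chars[s:(s + mlen - 1L)] <- motifChars
    }
    newChr <- paste(chars, collapse = "")
    genome2 <- Biostrings::DNAStringSet(newChr)
    names(genome2) <- chrName

    hits <- Biostrings::start(Biostrings::matchPattern(rule@motif,
                                                       genome2[[1]]))
    present <- vapply(pos, function(p) {
      any(hits >= p - half & hits <= p + half - mlen)
    }, logical(1))

    shH <- .betaShapes(rule@betaHighMean, rule@betaSpread)
    shL <- .betaShapes(rule@betaLowMean, rule@betaSpread)
    beta <- numeric(nSites)
    beta[present] <- 100 * stats::rbeta(sum(present), shH[1], shH[2])
    beta[!present] <- 100 * stats::rbeta(sum(!present), shL[1], shL[2])
    list(pos = pos, present = present, beta = beta, genome2 = genome2)
  })

  sites <- GenomicRanges::GRanges(
    seqnames = chrName,
    ranges = IRanges::IRanges(start = res$pos, width = 1L))
  mcols(sites)$beta <- res$beta
  mcols(sites)$label <- labelBeta(res$beta)
  mcols(sites)$motif <- res$present

  new("SyntheticMethylome", genome = res$genome2, sites = sites,
      rule = rule, seed = as.integer(seed),
      bayesAccuracy = .bayesAccuracy(mean(res$present), rule))
}

#' Write a synthetic methylome to fixture files
#'
#' Emits exactly the dialects the readers consume: a FASTA genome, a
#' methylation TSV (\code{tsv1} coordinates), and a JSON manifest recording
#' the rule, seed and Bayes accuracy. Re-running the generator with the
#' manifest's seed reproduces byte-identical files.
#'
#' @param sm a \linkS4class{SyntheticMethylome}.
#' @param dir output directory (created if needed).
#' @return named character vector of the file paths, invisibly.
#' @export
writeFixture <- function(sm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "genome.fa")
  tsv <- file.path(dir, "sites.tsv")
  mf <- file.path(dir, "manifest.json")
  Biostrings::writeXStringSet(sm@genome, fa)
  writeMethylationTable(sm@sites, tsv, coords = "tsv1")
  rule <- sm@rule
  jsonlite::write_json(list(
    motif = rule@motif, beta_high_mean = rule@betaHighMean,
    beta_low_mean = rule@betaLowMean, beta_spread = rule@betaSpread,
    motif_window = rule@motifWindow,
    inject_fraction = rule@injectFraction,
    cluster_size = rule@clusterSize, seed = sm@seed,
    bayes_accuracy = sm@bayesAccuracy,
    genome_name = names(sm@genome)[1],
    genome_length = Biostrings::width(sm@genome)[1],
    n_sites = length(sm@sites), coords = "tsv1"),
    mf, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fa, sites = tsv, manifest = mf))
}
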