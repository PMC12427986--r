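#' Read a reference genome from FASTA
#'
#' Reads a (multi-record) FASTA file into a \linkS4class{DNAStringSet}.
#' Residues are uppercased and any character outside \{A,C,G,T,N\} (IUPAC
#' ambiguity codes and the like) is mapped to N; the number of such
#' replacements is reported in a message and attached as the
#' \code{"nReplaced"} attribute.
#'
#' @param path path to a FASTA file.
#' @return a named \linkS4class{DNAStringSet}, one entry per record.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chrT", "acgt"), fa)
#' readGenome(fa)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stopIO("FASTA file not found: %s", path)
  if (file.size(path) == 0) stopIO("FASTA file is empty: %s", path)
  head_lines <- readLines(path, n = 50L, warn = FALSE)
  first <- which(nzchar(trimws(head_lines)))[1]
  if (is.na(first) || !startsWith(trimws(head_lines[first]), ">"))
    stopValidation("malformed FASTA header at line %d of %s",
                   ifelse(is.na(first), 1L, first), path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0) stopIO("FASTA file has no records: %s", path)
  chars <- toupper(as.character(raw))
  cleaned <- gsub("[^ACGTN]", "N", chars)
  nrep <- sum(nchar(gsub("[^ACGTN]", "", chars))) # chars kept by the scrub
  nrep <- sum(nchar(chars)) - nrep
  if (nrep > 0)
    message(sprintf("readGenome: %d non-ACGTN residue(s) replaced by N", nrep))
  out <- Biostrings::DNAStringSet(cleaned)
  names(out) <- sub("\\s.*$", "", names(raw))
  attr(out, "nReplaced") <- nrep
  out
}

#' Label methylation percentages by the 50\% threshold
#'
#' A site is called methylated when its methylation percentage (beta) is
#' 50\% or higher, unmethylated below.
#'
#' @param beta numeric vector of methylation percentages in [0, 100].
#' @return factor with levels \code{c("unmethylated", "methylated")}.
#' @examples
#' labelBeta(c(50, 49.99, 0, 100))
#' @export
labelBeta <- function(beta) {
  if (any(is.na(beta)) || any(beta < 0 | beta > 100))
    stopValidation("beta values must lie in [0, 100]")
  factor(ifelse(beta >= 50, "methylated", "unmethylated"),
         levels = .CLASS_ORDER)
}

#' Read a CpG methylation table
#'
#' Reads a TSV with header columns \code{chrom}, \code{pos},
#' \code{beta_percent}. Two coordinate dialects are supported: \code{bed0}
#' (0-based positions, the ENCODE RRBS/BED convention) and \code{tsv1}
#' (1-based). Positions are stored 1-based in the returned
#' \linkS4class{GRanges} (width-1 ranges at the C of each CpG). Rows whose
#' beta falls outside [0, 100] are rejected with a message; the count is
#' attached as attribute \code{"nRejected"}.
#'
#' @param path path to the TSV file.
#' @param coords coordinate dialect, \code{"bed0"} or \code{"tsv1"}.
#' @return a \linkS4class{GRanges} with metadata columns \code{beta} and
#'   \code{label}.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("chrom\tpos\tbeta_percent", "chr4\t1001\t75"), tsv)
#' readMethylationTable(tsv, coords = "tsv1")
#' @export
readMethylationTable <- function(path, coords = c("bed0", "tsv1")) {
  coords <- match.arg(coords)
  if (!file.exists(path)) stopIO("methylation table not found: %s", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "beta_percent")
  if (!all(need %in% names(df)))
    stopValidation("methylation table needs columns: %s",
                   paste(need, collapse = ", "))
  if (!is.numeric(df$pos)) stopValidation("non-numeric position column")
  if (!is.numeric(df$beta_percent)) stopValidation("non-numeric beta column")
  if (any(df$pos < ifelse(coords == "bed0", 0, 1)))
    stopValidation("negative or zero position under dialect '%s'", coords)
  bad <- is.na(df$beta_percent) | df$beta_percent < 0 | df$beta_percent > 100
  if (any(bad)) {
    message(sprintf(
      "readMethylationTable: rejected %d row(s) with beta outside [0, 100]",
      sum(bad)))
    df <- df[!bad, , drop = FALSE]
  }
  start1 <- if (coords == "bed0") df$pos + 1L else df$pos
  gr <- GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = as.integer(start1), width = 1L))
  mcols(gr)$beta <- df$beta_percent
  mcols(gr)$label <- labelBeta(df$beta_percent)
  attr(gr, "nRejected") <- sum(bad)
  gr
}

#' Write a CpG methylation table
#'
#' Inverse of \code{\link{readMethylationTable}}; the same dialect
#' round-trips sites exactly.
#'
#' @param sites \linkS4class{GRanges} with a \code{beta} metadata column.
#' @param path output TSV path.
#' @param coords coordinate dialect for the written positions.
#' @return \code{path}, invisibly.
#' @export
writeMethylationTable <- function(sites, path, coords = c("bed0", "tsv1")) {
  coords <- match.arg(coords)
  pos <- GenomicRanges::start(sites)
  if (coords == "bed0") pos <- pos - 1L
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(sites)),
                   pos = pos, beta_percent = mcols(sites)$beta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract fixed-width windows centered on CpG sites
#'
#' For a site whose C sits at 1-based genome position p, the window covers
#' positions [p - W/2, p + W/2 - 1], so the C lands at in-window index
#' W/2 + 1 (0-based offset W/2) and the CpG dinucleotide is fully contained
#' for every supported width. Sites whose window overruns a chromosome end, whose center fails
#' CG validation, or whose window exceeds \code{maxNFraction} ambiguous
#' bases are skipped (not fatal); per-reason counts are attached as the
#' \code{"skipped"} attribute and reported in a message.
#'
#' @param genome \linkS4class{DNAStringSet} as from \code{\link{readGenome}}.
#' @param sites \linkS4class{GRanges} of CpG sites (C positions, 1-based).
#' @param width even window width; 100, 200 and 300 are the supported sizes.
#' @param validateCG check that the genome carries CG at each site.
#' @param maxNFraction skip windows with more than this fraction of Ns.
#' @param reverseComplementMinus reverse-complement windows of sites on the
#'   minus strand (sites are otherwise taken as forward-strand Cs).
#' @return a \linkS4class{MethylWindows} object.
#' @export
extractWindows <- function(genome, sites, width = 300L, validateCG = TRUE,
                           maxNFraction = 0.1,
                           reverseComplementMinus = FALSE) {
  width <- as.integer(width)
  if (width %% 2L != 0L || width <= 0L)
    stopValidation("width must be a positive even integer")
  half <- width %/% 2L
  chrlen <- stats::setNames(Biostrings::width(genome), names(genome))
  chrom <- as.character(GenomicRanges::seqnames(sites))
  pos <- GenomicRanges::start(sites)

  known <- chrom %in% names(genome)
  len <- rep(NA_integer_, length(sites))
  len[known] <- chrlen[chrom[known]]
  inb <- known & (pos - half >= 1L) & (pos + half - 1L <= len)

  keep <- inb
  notCG <- rep(FALSE, length(sites))
  if (validateCG && any(keep)) {
    idx <- which(keep)
    center <- rep("NN", length(idx))
    for (chr in unique(chrom[idx])) {
      sel <- idx[chrom[idx] == chr]
      center[chrom[idx] == chr] <- as.character(Biostrings::extractAt(
        genome[[chr]], IRanges::IRanges(start = pos[sel], width = 2L)))
    }
    ok <- center == "CG"
    notCG[idx[!ok]] <- TRUE
    keep[idx[!ok]] <- FALSE
  }

  seqs <- Biostrings::DNAStringSet()
  if (any(keep)) {
    idx <- which(keep)
    parts <- character(length(idx))
    for (chr in unique(chrom[idx])) {
      sel <- chrom[idx] == chr
      parts[sel] <- as.character(Biostrings::extractAt(
        genome[[chr]],
        IRanges::IRanges(start = pos[idx][sel] - half, width = width)))
    }
    seqs <- Biostrings::DNAStringSet(parts)
  }

  tooN <- rep(FALSE, length(sites))
  if (length(seqs) > 0) {
    nfrac <- Biostrings::letterFrequency(seqs, "N") / width
    drop <- as.vector(nfrac > maxNFraction)
    tooN[which(keep)[drop]] <- TRUE
    seqs <- seqs[!drop]
    keep[which(keep)[drop]] <- FALSE
  }

  kept <- sites[keep]
  if (reverseComplementMinus && length(kept) > 0) {
    minus <- as.character(GenomicRanges::strand(kept)) == "-"
    if (any(minus)) seqs[minus] <- Biostrings::reverseComplement(seqs[minus])
  }

  skipped <- c(out_of_bounds = sum(!inb), not_cg = sum(notCG),
               excess_n = sum(tooN))
  if (sum(skipped) > 0)
    message(sprintf(
      "extractWindows: skipped %d site(s) (out_of_bounds=%d, not_cg=%d, excess_n=%d)",
      sum(skipped), skipped[1], skipped[2], skipped[3]))
  mw <- new("MethylWindows", seqs = seqs, sites = kept, width = width)
  attr(mw, "skipped") <- skipped
  mw
}

#' Stratified random subsample of CpG sites
#'
#' Draws \code{n} sites preserving the methylated:unmethylated ratio of the
#' input to within one site; deterministic for a fixed seed.
#'
#' @param sites \linkS4class{GRanges} with a \code{label} metadata column.
#' @param n number of sites to keep.
#' @param seed integer seed.
#' @return the subsampled \linkS4class{GRanges} (original order preserved).
#' @export
subsampleSites <- function(sites, n, seed = 1L) {
  n <- as.integer(n)
  if (n > length(sites))
    stopValidation("cannot subsample %d from %d sites", n, length(sites))
  lab <- mcols(sites)$label
  if (is.null(lab)) lab <- labelBeta(mcols(sites)$beta)
  isM <- lab == "methylated"
  nM <- round(n * sum(isM) / length(sites))
  nM <- min(max(nM, n - sum(!isM)), sum(isM), n)
  nU <- n - nM
  keep <- withSeed(seed, {
    sort(c(sample(which(isM), nM), sample(which(!isM), nU)))
  })
  sites[keep]
}

#' Seeded 70:20:10 train/test/validation split
#'
#' Indices 1..n are shuffled with the given seed and sliced contiguously
#' into train, test and validation sets of sizes floor(f1 n), floor(f2 n)
#' and the remainder. With the default fractions and n = 5000 this yields
#' exactly 3500 / 1000 / 500.
#'
#' @param n number of items (or an object with a length).
#' @param fractions three nonnegative fractions summing to 1.
#' @param seed integer seed for the shuffle.
#' @return list with integer index vectors \code{train}, \code{test},
#'   \code{validation}; together a partition of 1..n.
#' @examples
#' lengths(splitDataset(5000, seed = 7))
#' @export
splitDataset <- function(n, fractions = c(0.70, 0.20, 0.10), seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L) n <- length(n)
  n <- as.integer(n)
  if (length(fractions) != 3L || any(fractions < 0))
    stopValidation("fractions must be three nonnegative numbers")
  if (abs(sum(fractions) - 1) > 1e-9)
    stopValidation("fractions must sum to 1")
  if (all(fractions > 0) && n < 3L)
    stopValidation("need n >= 3 when all fractions are positive")
  nTrain <- floor(fractions[1] * n)
  nTest <- floor(fractions[2] * n)
  nVal <- n - nTrain - nTest
  perm <- withSeed(seed, sample.int(n))
  list(train = perm[seq_len(nTrain)],
       test = perm[nTrain + seq_len(nTest)],
       validation = perm[nTrain + nTest + seq_len(nVal)])
}

#' Write a split manifest
#'
#' Records which site went into which split as a two-column TSV
#' (\code{site_id}, \code{split}) for reproducibility.
#'
#' @param siteIds character vector of site identifiers.
#' @param split list as returned by \code{\link{splitDataset}}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeSplitManifest <- function(siteIds, split, path) {
  assign <- character(length(siteIds))
  for (nm in names(split)) assign[split[[nm]]] <- nm
  utils::write.table(data.frame(site_id = siteIds, split = assign),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
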