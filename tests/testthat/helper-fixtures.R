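# Shared fixtures and independent oracles, all built in code.

# -- pinned regression fixture: the published dimer encoding of the 30-bp
#    sequence "CACACAAATAGTATACATCAAAAATGATTT", one row per dinucleotide --
DIMER30_SEQ <- "CACACAAATAGTATACATCAAAAATGATTT"
DIMER30_ROWS <- c(
  "CA 01001000", "AC 10000100", "CA 01001000", "AC 10000100",
  "CA 01001000", "AA 10001000", "AA 10001000", "AT 10000001",
  "TA 00011000", "AG 10000010", "GT 00100001", "TA 00011000",
  "AT 10000001", "TA 00011000", "AC 10000100", "CA 01001000",
  "AT 10000001", "TC 00010100", "CA 01001000", "AA 10001000",
  "AA 10001000", "AA 10001000", "AA 10001000", "AT 10000001",
  "TG 00010010", "GA 00101000", "AT 10000001", "TT 00010001",
  "TT 00010001")

dimer30Matrix <- function() {
  bits <- sub("^.. ", "", DIMER30_ROWS)
  m <- t(vapply(strsplit(bits, ""), as.numeric, numeric(8)))
  dimnames(m) <- list(NULL, rep(c("A", "C", "G", "T"), 2))
  m
}

dimer30Dinucs <- function() sub(" .*$", "", DIMER30_ROWS)

# -- independent oracles -------------------------------------------------

# brute-force sliding dot product, index by index
oracleConv <- function(input, kernel) {
  n <- length(input); k <- length(kernel)
  out <- numeric(n - k + 1)
  for (i in seq_along(out)) {
    acc <- 0
    for (m in 0:(k - 1)) acc <- acc + input[i + m] * kernel[m + 1]
    out[i] <- acc
  }
  out
}

# AUROC as the normalized Mann-Whitney U statistic over all pos/neg pairs,
# ties counting one half
oracleAUROC <- function(truth, scores) {
  pos <- scores[truth == "methylated"]
  neg <- scores[truth != "methylated"]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# precision/recall at each distinct threshold by explicit confusion
# tallying, then the trapezoid with the recall-0 extension
oraclePR <- function(truth, scores) {
  pos <- truth == "methylated"
  thr <- sort(unique(scores), decreasing = TRUE)
  rec <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    call <- scores >= thr[i]
    rec[i] <- sum(call & pos) / sum(pos)
    prec[i] <- sum(call & pos) / sum(call)
  }
  rec <- c(0, rec); prec <- c(prec[1], prec)
  sum(diff(rec) * (head(prec, -1) + tail(prec, -1)) / 2)
}

# -- small data builders -------------------------------------------------

# a deterministic genome with CG planted at known 1-based C positions
handGenome <- function(len = 4000, cgAt = c(500, 2000, 3500),
                       name = "chrT") {
  set.seed(99)
  chars <- sample(c("A", "T"), len, replace = TRUE)  # no accidental CG
  for (p in cgAt) chars[p:(p + 1)] <- c("C", "G")
  g <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(g) <- name
  g
}

handSites <- function(pos, beta, chrom = "chrT") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start = pos, width = 1L))
  gr$beta <- beta
  gr$label <- labelBeta(beta)
  gr
}

# random 0/1 dataset for exercising the training plumbing (not learnable)
randomDataset <- function(n, L, C, seed = 1) {
  set.seed(seed)
  arr <- array(rbinom(n * L * C, 1, 0.25), c(n, L, C))
  lab <- factor(rep(c("unmethylated", "methylated"), length.out = n),
                levels = c("unmethylated", "methylated"))
  new("EncodedDataset", features = arr, labels = lab,
      scheme = if (C == 4) encodingScheme("monomer") else
        if (C == 8) encodingScheme("dimer") else encodingScheme("dimer16"),
      siteIds = sprintf("chrT:%d", seq_len(n)))
}

# full synthetic pipeline fixture shared by the heavier tests
syntheticEncoded <- function(nSites = 2000, width = 100, seed = 1,
                             scheme = "dimer", rule = syntheticRule(),
                             genomeLength = 8e5) {
  g <- generateGenome(genomeLength, 0.5, seed = seed)
  sm <- plantMethylome(g, nSites, rule, seed = seed)
  w <- suppressMessages(extractWindows(sm@genome, sm@sites, width = width))
  list(sm = sm, windows = w, encoded = encodeWindows(w, scheme))
}
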