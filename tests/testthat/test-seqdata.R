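test_that("readGenome parses records, folds case and normalizes ambiguity", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chrT", "ACGT"), fa)
  g <- readGenome(fa)
  expect_equal(names(g), "chrT")
  expect_equal(as.character(g[[1]]), "ACGT")
  expect_equal(Biostrings::width(g), 4L)

  writeLines(c(">a", "acg", "t", ">b", "NNNN"), fa)
  g <- readGenome(fa)
  expect_equal(unname(Biostrings::width(g)), c(4L, 4L))
  expect_equal(as.character(g[[1]]), "ACGT")

  writeLines(c(">r", "ACRT"), fa)
  expect_message(g <- readGenome(fa), "1 non-ACGTN")
  expect_equal(as.character(g[[1]]), "ACNT")
  expect_equal(attr(g, "nReplaced"), 1L)
})

test_that("readGenome rejects missing, empty and malformed input", {
  expect_error(readGenome(tempfile()), "not found")
  fa <- withr::local_tempfile(fileext = ".fa")
  file.create(fa)
  expect_error(readGenome(fa), "empty")
  writeLines(c("ACGT", ">late"), fa)
  expect_error(readGenome(fa), "malformed FASTA header at line 1")
})

test_that("methylation tables honor both coordinate dialects", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tbeta_percent", "chr4\t1001\t75"), tsv)
  gr <- readMethylationTable(tsv, coords = "tsv1")
  expect_equal(GenomicRanges::start(gr), 1001L)  # 0-based pos 1000
  expect_equal(gr$beta, 75)

  writeLines(c("chrom\tpos\tbeta_percent", "chr4\t1000\t75"), tsv)
  gr0 <- readMethylationTable(tsv, coords = "bed0")
  expect_equal(GenomicRanges::start(gr0), 1001L)  # same site as above
})

test_that("out-of-range beta rows are rejected with a count, bad columns error", {
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("chrom\tpos\tbeta_percent", "chr1\t10\t120", "chr1\t20\t50"),
             tsv)
  expect_message(gr <- readMethylationTable(tsv, coords = "tsv1"),
                 "rejected 1 row")
  expect_equal(length(gr), 1L)
  expect_equal(attr(gr, "nRejected"), 1L)

  writeLines(c("chrom\tpos\tbeta_percent", "chr1\tx\t50"), tsv)
  expect_error(readMethylationTable(tsv, coords = "tsv1"), "non-numeric")
  writeLines(c("chrom\tposition\tscore", "chr1\t1\t50"), tsv)
  expect_error(readMethylationTable(tsv, coords = "tsv1"), "columns")
})

test_that("a written table re-read under the same dialect round-trips exactly", {
  sites <- handSites(c(500, 2000, 3500), c(80.5, 12.25, 50))
  for (dialect in c("bed0", "tsv1")) {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeMethylationTable(sites, tsv, coords = dialect)
    back <- readMethylationTable(tsv, coords = dialect)
    expect_equal(GenomicRanges::start(back), GenomicRanges::start(sites))
    expect_equal(back$beta, sites$beta)
    expect_equal(back$label, sites$label)
  }
})

test_that("the beta threshold is inclusive at 50 and labels obey the law", {
  expect_equal(as.character(labelBeta(50)), "methylated")
  expect_equal(as.character(labelBeta(49.99)), "unmethylated")
  expect_equal(as.character(labelBeta(c(0, 100))),
               c("unmethylated", "methylated"))
  expect_error(labelBeta(101), "0, 100")
  beta <- runif(200, 0, 100)
  expect_equal(labelBeta(beta) == "methylated", beta >= 50)
})

test_that("windows are centered with the C at offset W/2 (0-based)", {
  g <- handGenome()
  sites <- handSites(2000, 80)
  w <- extractWindows(g, sites, width = 300)
  expect_equal(windowWidth(w), 300L)
  seq <- as.character(windowSeqs(w)[[1]])
  expect_equal(nchar(seq), 300L)
  # 0-based offset 150 == 1-based in-window index 151
  expect_equal(substr(seq, 151, 152), "CG")
  expect_equal(seq,
               as.character(Biostrings::subseq(g[[1]], 1850, 2149)))
})

test_that("boundary overruns and non-CG centers are skipped with reasons", {
  g <- handGenome(len = 10000, cgAt = c(100, 5000))
  sites <- handSites(c(100, 5000, 9990), c(80, 20, 50))
  expect_message(w <- extractWindows(g, sites, width = 300), "skipped 2")
  expect_equal(length(windowSeqs(w)), 1L)
  sk <- attr(w, "skipped")
  expect_equal(unname(sk[["out_of_bounds"]]), 2L)

  # center not a CG -> skipped, not fatal
  sites2 <- handSites(c(5000, 5007), c(80, 20))
  expect_message(w2 <- extractWindows(g, sites2, width = 300), "not_cg=1")
  expect_equal(length(windowSeqs(w2)), 1L)
})

test_that("every emitted window carries CG at its center", {
  fx <- syntheticEncoded(nSites = 200, width = 100, seed = 3,
                         genomeLength = 1e5)
  seqs <- as.character(windowSeqs(fx$windows))
  expect_true(all(substr(seqs, 51, 52) == "CG"))
})

test_that("subsampling is stratified, deterministic and size-checked", {
  sites <- handSites(seq(1, 3000) * 10 + 100,
                     c(rep(80, 1800), rep(20, 1200)), chrom = "chrX")
  sub <- subsampleSites(sites, 500, seed = 7)
  expect_equal(length(sub), 500L)
  # input ratio 60:40 preserved within one site
  expect_equal(sum(sub$label == "methylated"), 300L, tolerance = 0)
  sub2 <- subsampleSites(sites, 500, seed = 7)
  expect_identical(GenomicRanges::start(sub), GenomicRanges::start(sub2))
  sub3 <- subsampleSites(sites, 500, seed = 8)
  expect_false(identical(GenomicRanges::start(sub),
                         GenomicRanges::start(sub3)))
  all3000 <- subsampleSites(sites, 3000, seed = 1)
  expect_equal(length(all3000), 3000L)
  expect_error(subsampleSites(sites, 3001), "cannot subsample")
})

test_that("the 70:20:10 split has floor sizes and partitions the indices", {
  sp <- splitDataset(5000, seed = 1)
  expect_equal(lengths(sp), c(train = 3500L, test = 1000L,
                              validation = 500L))
  sp10 <- splitDataset(10, seed = 1)
  expect_equal(unname(lengths(sp10)), c(7L, 2L, 1L))
  for (n in c(3, 17, 101, 1234)) {
    for (seed in 1:3) {
      s <- splitDataset(n, seed = seed)
      all <- c(s$train, s$test, s$validation)
      expect_equal(sort(all), seq_len(n))
      expect_equal(length(all), length(unique(all)))
    }
  }
  expect_identical(splitDataset(100, seed = 5), splitDataset(100, seed = 5))
  expect_error(splitDataset(100, fractions = c(0.5, 0.3, 0.1)), "sum to 1")
  expect_error(splitDataset(2), "n >= 3")
})

test_that("the split manifest records every site's assignment", {
  sp <- splitDataset(10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSplitManifest(sprintf("chr1:%d", 1:10), sp, path)
  mf <- read.delim(path)
  expect_equal(nrow(mf), 10L)
  expect_equal(sum(mf$split == "train"), 7L)
  expect_equal(sum(mf$split == "validation"), 1L)
})
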