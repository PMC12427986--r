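.BASE_ORDER <- c("A", "C", "G", "T")

# base index matrix for a set of equal-width sequences: n x W integers in
# 1..4, NA for N
.baseIndexMatrix <- function(seqs) {
  chars <- strsplit(as.character(seqs), "", fixed = TRUE)
  W <- unique(lengths(chars))
  if (length(W) != 1L)
    stopValidation("all sequences must share one width")
  m <- matrix(unlist(chars), nrow = length(chars), ncol = W, byrow = TRUE)
  bad <- !(m %in% c(.BASE_ORDER, "N"))
  if (any(bad))
    stopValidation("sequence contains characters outside {A,C,G,T,N}: %s",
                   paste(unique(m[bad]), collapse = ","))
  matrix(match(m, .BASE_ORDER), nrow = nrow(m), ncol = W)
}

#' Monomer (per-nucleotide) one-hot encoding
#'
#' Maps a window sequence to an L x 4 binary matrix with columns in the
#' fixed base order A, C, G, T: 'A' becomes (1,0,0,0), 'C' (0,1,0,0),
#' 'G' (0,0,1,0), 'T' (0,0,0,1). Ambiguous bases (N) give all-zero rows so
#' matrix shapes stay determined by the window alone.
#'
#' @param seq a character string or \code{DNAString} over \{A,C,G,T,N\}.
#' @return an L x 4 numeric matrix with column names A, C, G, T.
#' @examples
#' encodeMonomer("ACGT")  # the 4 x 4 identity
#' @export
encodeMonomer <- function(seq) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L < 1L) stopValidation("empty sequence")
  idx <- .baseIndexMatrix(seq)[1, ]
  M <- matrix(0, nrow = L, ncol = 4L, dimnames = list(NULL, .BASE_ORDER))
  ok <- !is.na(idx)
  M[cbind(which(ok), idx[ok])] <- 1
  M
}

#' Dimer (overlapping dinucleotide) one-hot encoding
#'
#' Row i of the result encodes the dinucleotide seq[i]seq[i+1] as the
#' concatenation of the two constituent monomer one-hot vectors, giving
#' (L - 1) rows of 8 channels (A,C,G,T of the first base followed by
#' A,C,G,T of the second); every unambiguous row sums to 2. A dinucleotide
#' containing N yields an all-zero row.
#'
#' @param seq a character string or \code{DNAString} over \{A,C,G,T,N\},
#'   length at least 2.
#' @return an (L - 1) x 8 numeric matrix.
#' @examples
#' encodeDimer("CA")  # one row: 0 1 0 0 1 0 0 0
#' @export
encodeDimer <- function(seq) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L < 2L) stopValidation("dimer encoding needs length >= 2")
  m <- encodeMonomer(seq)
  D <- cbind(m[-L, , drop = FALSE], m[-1, , drop = FALSE])
  D[rowSums(D) < 2, ] <- 0
  dimnames(D) <- list(NULL, rep(.BASE_ORDER, 2))
  D
}

#' 16-channel dinucleotide one-hot encoding
#'
#' Alternative dimer reading: each overlapping dinucleotide is one of 16
#' categories and gets a 16-way one-hot row (columns ordered AA, AC, AG,
#' AT, CA, ... TT). Kept as an option; the 8-channel \code{\link{encodeDimer}}
#' is the canonical scheme (it is the one that reproduces both the published
#' worked example and the 299 x 8 tensor shape).
#'
#' @inheritParams encodeDimer
#' @return an (L - 1) x 16 numeric matrix.
#' @export
encodeDimer16 <- function(seq) {
  seq <- toupper(as.character(seq))
  L <- nchar(seq)
  if (L < 2L) stopValidation("dimer encoding needs length >= 2")
  idx <- .baseIndexMatrix(seq)[1, ]
  i1 <- idx[-L]; i2 <- idx[-1]
  cols <- as.vector(t(outer(.BASE_ORDER, .BASE_ORDER, paste0)))
  D <- matrix(0, nrow = L - 1L, ncol = 16L, dimnames = list(NULL, cols))
  ok <- !is.na(i1) & !is.na(i2)
  D[cbind(which(ok), (i1[ok] - 1L) * 4L + i2[ok])] <- 1
  D
}

#' Decode a monomer matrix back to sequence
#'
#' Inverse of \code{\link{encodeMonomer}} on unambiguous input; all-zero
#' rows decode to N.
#'
#' @param mat an L x 4 one-hot matrix.
#' @return the nucleotide string.
#' @export
decodeMonomer <- function(mat) {
  stopifnot(ncol(mat) == 4L)
  hit <- max.col(mat, ties.method = "first")
  hit[rowSums(mat) == 0] <- NA
  paste(ifelse(is.na(hit), "N", .BASE_ORDER[hit]), collapse = "")
}

#' Encode a batch of windows into a feature tensor
#'
#' Stacks the per-window one-hot matrices into an n x L' x C array in input
#' order, carrying the site labels and ids along; L' is the scheme's row
#' count for the shared window width (e.g. 5000 windows of 300 bp give
#' 5000 x 300 x 4 under monomer and 5000 x 299 x 8 under dimer encoding).
#'
#' @param windows a \linkS4class{MethylWindows} object (all one width).
#' @param scheme an \linkS4class{EncodingScheme} or scheme name.
#' @return an \linkS4class{EncodedDataset}.
#' @export
encodeWindows <- function(windows, scheme = "dimer") {
  if (is.character(scheme)) scheme <- encodingScheme(scheme)
  n <- length(windowSeqs(windows))
  if (n == 0L) stopValidation("no windows to encode")
  W <- windowWidth(windows)
  Lp <- rowCount(scheme, W)
  C <- scheme@channels
  idx <- .baseIndexMatrix(windowSeqs(windows))

  arr <- array(0, dim = c(n, Lp, C))
  if (scheme@name == "monomer") {
    cells <- which(!is.na(idx), arr.ind = TRUE)
    arr[cbind(cells[, 1], cells[, 2], idx[cells])] <- 1
  } else {
    i1 <- idx[, -W, drop = FALSE]
    i2 <- idx[, -1, drop = FALSE]
    ok <- which(!is.na(i1) & !is.na(i2), arr.ind = TRUE)
    if (scheme@name == "dimer") {
      arr[cbind(ok[, 1], ok[, 2], i1[ok])] <- 1
      arr[cbind(ok[, 1], ok[, 2], i2[ok] + 4L)] <- 1
    } else {
      arr[cbind(ok[, 1], ok[, 2], (i1[ok] - 1L) * 4L + i2[ok])] <- 1
    }
  }
  sites <- siteRanges(windows)
  ids <- sprintf("%s:%d", as.character(GenomicRanges::seqnames(sites)),
                 GenomicRanges::start(sites))
  new("EncodedDataset", features = arr, labels = sites$label,
      scheme = scheme, siteIds = ids)
}

#' Write / read an encoded dataset
#'
#' Portable on-disk form: the feature tensor is serialized with
#' \code{saveRDS} next to a JSON manifest recording the scheme, shape and
#' site ids, so a stored tensor is self-describing.
#'
#' @param ed an \linkS4class{EncodedDataset}.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeEncodedDataset <- function(ed, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(ed@features, file.path(dir, "features.rds"))
  manifest <- list(scheme = ed@scheme@name, shape = dim(ed@features),
                   labels = as.character(ed@labels), site_ids = ed@siteIds)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname writeEncodedDataset
#' @export
readEncodedDataset <- function(dir) {
  mf <- jsonlite::read_json(file.path(dir, "manifest.json"),
                            simplifyVector = TRUE)
  new("EncodedDataset", features = readRDS(file.path(dir, "features.rds")),
      labels = factor(mf$labels, levels = .CLASS_ORDER),
      scheme = encodingScheme(mf$scheme), siteIds = mf$site_ids)
}
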