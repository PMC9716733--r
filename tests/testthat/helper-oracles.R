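# Independent brute-force oracles used across the suite. These deliberately
# take different algorithmic routes from the package implementation.

# Doubletail exact p by explicit enumeration with sort/cumsum thresholding.
# Returns the p for every observed split a = 0..s of the total s at once.
oracleDoubletailAll <- function(s, nA, nB, phi) {
  if (s == 0) return(1)
  m0 <- s / (nA + nB)
  a <- 0:s
  probs <- if (phi < 1e-12) {
    dpois(a, nA * m0) * dpois(s - a, nB * m0)
  } else {
    dnbinom(a, size = nA / phi, mu = nA * m0) *
      dnbinom(s - a, size = nB / phi, mu = nB * m0)
  }
  tot <- sum(probs)
  ord <- order(probs)
  cs <- cumsum(probs[ord])
  sorted <- probs[ord]
  # p(a) = mass of all outcomes with prob <= prob(a), ties within 1e-12 rel
  idx <- findInterval(probs * (1 + 1e-12), sorted)
  pmin(1, cs[idx] / tot)
}

# Per-region feature classifier by direct looping over genes.
oracleAnnotateOne <- function(chrom, mid, geneDf, exonDf, utrDf,
                              proximalBp = 1000, distalBp = 10000) {
  gsub <- geneDf[geneDf$chrom == chrom, , drop = FALSE]
  inProx <- FALSE; inDist <- FALSE; inUtr <- FALSE
  inExon <- FALSE; inGene <- FALSE
  for (i in seq_len(nrow(gsub))) {
    tss <- if (gsub$strand[i] == "-") gsub$end[i] else gsub$start[i]
    d <- if (gsub$strand[i] == "-") mid - tss else tss - mid
    if (d >= 0 && d < proximalBp) inProx <- TRUE
    if (d >= proximalBp && d < distalBp) inDist <- TRUE
    if (mid >= gsub$start[i] && mid <= gsub$end[i]) inGene <- TRUE
  }
  esub <- exonDf[exonDf$chrom == chrom, , drop = FALSE]
  if (nrow(esub) && any(mid >= esub$start & mid <= esub$end)) inExon <- TRUE
  usub <- utrDf[utrDf$chrom == chrom, , drop = FALSE]
  if (nrow(usub) && any(mid >= usub$start & mid <= usub$end)) inUtr <- TRUE
  if (inProx) "proximal_promoter"
  else if (inDist) "distal_promoter"
  else if (inUtr) "utr"
  else if (inExon) "exon"
  else if (inGene) "intron"
  else "intergenic"
}

grToDf <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)))
}

# Naive interval-membership window counting (0-based half-open windows).
oracleCountTags <- function(tagChrom, tagPos1, windows) {
  wdf <- grToDf(windows)
  out <- integer(nrow(wdf))
  for (k in seq_along(tagPos1)) {
    hit <- which(wdf$chrom == tagChrom[k] & tagPos1[k] >= wdf$start &
                   tagPos1[k] <= wdf$end)
    out[hit] <- out[hit] + 1L
  }
  out
}

# small WindowCounts fixture built directly from matrices
makeWindowCounts <- function(y, conditions, tracks, replicates = NULL) {
  n <- ncol(y)
  if (is.null(replicates)) replicates <- seq_len(n)
  gr <- GenomicRanges::GRanges("chr1",
    IRanges::IRanges(seq(1, by = 3000, length.out = nrow(y)), width = 3000))
  WindowCounts(y, gr, data.frame(condition = conditions, track = tracks,
                                 replicate = replicates))
}
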