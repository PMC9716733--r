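# fixture: two genes on opposite strands with exons/UTRs, plain coordinates
mkModels <- function() {
  si <- GenomeInfoDb::Seqinfo("chr1", 100000)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(20001, 60001), c(26000, 66000)),
    strand = c("+", "-"), gene_id = c("geneA", "geneB"), seqinfo = si)
  exons <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(20001, 24001, 60001, 64001),
                             c(21000, 26000, 61000, 66000)),
    strand = rep(c("+", "-"), each = 2),
    gene_id = rep(c("geneA", "geneB"), each = 2), seqinfo = si)
  utrs <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(20001, 65851), c(20150, 66000)),
    strand = c("+", "-"), gene_id = c("geneA", "geneB"), seqinfo = si)
  geneModels(genes, exons, utrs)
}

regionAt <- function(mid, w = 1) {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(mid, width = w))
}

test_that("midpoint classification follows the precedence rules", {
  m <- mkModels()
  lbl <- function(mid) as.character(
    annotateRegions(regionAt(mid), m)$feature)
  expect_equal(lbl(19500), "proximal_promoter")   # 500 bp upstream of + TSS
  expect_equal(lbl(15001), "distal_promoter")     # 5 kb upstream
  expect_equal(lbl(20100), "utr")                 # 5' UTR of geneA
  expect_equal(lbl(20500), "exon")
  expect_equal(lbl(22000), "intron")
  expect_equal(lbl(50000), "intergenic")
  # minus-strand gene: upstream lies right of the TSS at 66000
  expect_equal(lbl(66500), "proximal_promoter")
  expect_equal(lbl(70000), "distal_promoter")
  expect_equal(lbl(59000), "intergenic")          # downstream of geneB
  # precedence: promoter beats gene-body features of another arrangement
  expect_equal(lbl(66000), "proximal_promoter")   # TSS base itself
  # nearest gene is reported
  ann <- annotateRegions(regionAt(19500), m)
  expect_equal(ann$gene_id, "geneA")
  expect_error(annotateRegions(
    GenomicRanges::GRanges("chrX", IRanges::IRanges(1, 10)), m), "unknown")
})

test_that("summaries normalize and agree with the brute-force oracle", {
  st <- simulateGenome(simConfig(nChroms = 2, chromLength = 300000L,
                                 seed = 61))
  m <- st$models
  set.seed(62)
  mids <- sample(3000:297000, 1000, replace = TRUE)
  chroms <- sample(c("chr1", "chr2"), 1000, replace = TRUE)
  regions <- GenomicRanges::GRanges(chroms,
                                    IRanges::IRanges(mids - 1500,
                                                     mids + 1499))
  ann <- annotateRegions(regions, m)
  gdf <- cbind(grToDf(genes(m)),
               gene_id = S4Vectors::mcols(genes(m))$gene_id)
  edf <- grToDf(m@exons); udf <- grToDf(m@utrs)
  midUsed <- (GenomicRanges::start(regions) +
                GenomicRanges::end(regions)) %/% 2L
  oracle <- vapply(seq_along(regions), function(i) {
    oracleAnnotateOne(chroms[i], midUsed[i], gdf, edf, udf)
  }, character(1))
  expect_equal(as.character(ann$feature), oracle)
  s <- summarizeAnnotation(regions, m)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(s$count), length(regions))
  expect_error(summarizeAnnotation(GenomicRanges::GRanges(), m),
               "no regions")
})

test_that("mirroring every gene strand mirrors promoter calls", {
  m <- mkModels()
  flipped <- m
  GenomicRanges::strand(flipped@genes) <-
    ifelse(as.character(GenomicRanges::strand(m@genes)) == "+", "-", "+")
  # geneA TSS moves from 20001 to 26000: upstream flips sides
  lblF <- function(mid) as.character(
    annotateRegions(regionAt(mid), flipped)$feature)
  expect_equal(lblF(26500), "proximal_promoter")
  expect_equal(lblF(19500), "intergenic")
})

test_that("motif scanning reports IUPAC hits in TSS-relative coordinates", {
  set.seed(91)
  bg <- paste(sample(c("A", "C", "T"), 400, TRUE), collapse = "")
  # plant ACGTG at positions 153..157: spans -147..-143 for a TSS at 300
  s <- paste0(substr(bg, 1, 152), "ACGTG", substr(bg, 158, 400))
  hit <- scanMotif(s, "ACGTG", tssPos = 300, strand = "+")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$relStart, -147)
  expect_equal(hit$relEnd, -143)
  expect_equal(substr(s, hit$start, hit$end), "ACGTG")
  # no match
  expect_equal(nrow(scanMotif(strrep("T", 50), "ACGTG", 25, "+")), 0)
  # IUPAC degeneracy: RCGTG matches ACGTG and GCGTG
  s2 <- paste0("TTTACGTGTTTTGCGTGTTT")
  hits2 <- scanMotif(s2, "RCGTG", tssPos = 20, strand = "+")
  expect_equal(nrow(hits2), 2)
  expect_error(scanMotif(s2, "ACGTQ", 10, "+"), "IUPAC")
  # -1 is immediately upstream, +1 the TSS itself (no zero)
  one <- scanMotif("AAAT", "T", tssPos = 4, strand = "+")
  expect_equal(one$relStart, 1)
  adj <- scanMotif("AATA", "T", tssPos = 4, strand = "+")
  expect_equal(adj$relStart, -1)
})

test_that("minus-strand scanning searches the reverse complement", {
  # gene on '-': upstream is to the right of the TSS in plus coordinates
  s <- paste0(strrep("A", 100), strrep("A", 42), "CACGT", strrep("A", 53))
  # CACGT at plus positions 143..147 is ACGTG on the minus strand;
  # for a minus-strand TSS at 100 - wait, upstream right: tss at 100
  hits <- scanMotif(s, "ACGTG", tssPos = 100, strand = "-")
  expect_equal(nrow(hits), 1)
  expect_equal(hits$relStart, -47)
  expect_equal(hits$relEnd, -43)
})

test_that("planted promoter motifs are recovered from the toy genome", {
  sim <- simulateGenome(simConfig(nChroms = 1, chromLength = 200000L,
                                  seed = 53))
  tss <- tssOf(sim$models)
  str <- as.character(GenomicRanges::strand(genes(sim$models)))
  seqs <- as.character(sim$genome)
  for (k in seq_len(min(4, length(tss)))) {
    s <- seqs[[as.character(GenomicRanges::seqnames(genes(sim$models)))[k]]]
    # upstream lies left of a plus TSS and right of a minus TSS
    if (str[k] == "+") {
      win <- substr(s, tss[k] - 400, tss[k] + 99)
      tp <- 401
    } else {
      win <- substr(s, tss[k] - 99, tss[k] + 400)
      tp <- 100
    }
    h6 <- scanMotif(win, "TCGGAAGT", tssPos = tp, strand = str[k])
    hH <- scanMotif(win, "ACGTG", tssPos = tp, strand = str[k])
    expect_true(any(h6$relStart == -231 & h6$relEnd == -224))
    expect_true(any(hH$relStart == -147 & hH$relEnd == -143))
  }
})

test_that("TSS profiles are flat for uniform tags and mirror under strand flip", {
  sim <- simulateGenome(simConfig(nChroms = 2, chromLength = 300000L,
                                  seed = 71))
  set.seed(72)
  n <- 60000
  tags <- GenomicRanges::GRanges(
    sample(c("chr1", "chr2"), n, TRUE),
    IRanges::IRanges(sample(300000, n, TRUE), width = 1))
  prof <- tssProfile(tags, sim$models, flankBp = 2000, binBp = 500)
  expect_equal(nrow(prof), 8)
  expect_lt(max(prof$density) / max(mean(prof$density), 1e-12), 1.35)
  # planted central tags dominate
  tss <- tssOf(sim$models)
  chr <- as.character(GenomicRanges::seqnames(genes(sim$models)))
  central <- GenomicRanges::GRanges(
    rep(chr, each = 5),
    IRanges::IRanges(rep(tss, each = 5) +
                       rep(c(-100, -50, 0, 50, 100), length(tss)),
                     width = 1))
  profC <- tssProfile(central, sim$models, 2000, 100)
  centralBins <- which(profC$binStart %in% c(-200, -100, 0, 100))
  expect_gt(sum(profC$density[centralBins]),
            0.9 * sum(profC$density))
  # mirroring all strands mirrors the profile; width-1 "genes" keep the
  # TSS at the same base under the flip
  pts <- seq(20000, 280000, by = 20000)
  mkPoint <- function(strand) geneModels(GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(pts, width = 1), strand = strand,
    gene_id = sprintf("p%02d", seq_along(pts))))
  skew <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(rep(pts, each = 2) +
                               rep(c(-350, 650), length(pts)), width = 1))
  p1 <- tssProfile(skew, mkPoint("+"), 1000, 100)
  p2 <- tssProfile(skew, mkPoint("-"), 1000, 100)
  expect_equal(p1$density, rev(p2$density))
  expect_gt(sum(p1$density), 0)
  expect_error(tssProfile(tags, sim$models, 1500, 400), "multiple")
})
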