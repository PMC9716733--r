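mkIntModels <- function() {
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(20001, 60001, 120001), c(26000, 66000, 125000)),
    strand = c("+", "-", "+"),
    gene_id = c("geneA", "geneB", "geneC"))
  geneModels(genes)
}

test_that("regions map to genes by body or promoter overlap", {
  m <- mkIntModels()
  regions <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(22001, 14001, 67001, 1), width = 3000))
  names(regions) <- paste0("r", 1:4)
  res <- assignRegionsToGenes(regions, m)
  a <- res$assignments
  expect_equal(a$gene_id[a$region_id == "r1"], "geneA")
  expect_equal(a$rule[a$region_id == "r1"], "body")
  # r2 sits 3-9 kb upstream of geneA's TSS
  expect_equal(a$gene_id[a$region_id == "r2"], "geneA")
  expect_equal(a$rule[a$region_id == "r2"], "promoter")
  # r3 is upstream of minus-strand geneB (right side)
  expect_equal(a$gene_id[a$region_id == "r3"], "geneB")
  expect_equal(res$unmapped, "r4")
  # brute-force overlap oracle on random fixtures
  set.seed(14)
  gdf <- grToDf(genes(m))
  for (i in 1:5) {
    st <- sample(1:130000, 50)
    rr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(st, width = 2000))
    names(rr) <- paste0("w", seq_along(rr))
    got <- assignRegionsToGenes(rr, m)$assignments
    for (g in seq_len(nrow(gdf))) {
      lo <- if (gdf$strand[g] == "+") gdf$start[g] - 10000 else gdf$start[g]
      hi <- if (gdf$strand[g] == "-") gdf$end[g] + 10000 else gdf$end[g]
      hits <- names(rr)[st + 1999 >= lo & st <= hi]
      gid <- c("geneA", "geneB", "geneC")[g]
      expect_setequal(got$region_id[got$gene_id == gid], hits)
    }
  }
})

test_that("gene-set intersection produces consistent Venn cells", {
  r <- intersectGeneSets(list(a = c("g1", "g2", "g3"),
                              b = c("g2", "g3", "g4")))
  expect_setequal(r$intersection, c("g2", "g3"))
  expect_equal(sum(r$venn), 4)  # |union|
  expect_equal(unname(r$venn[["a&b"]]), 2)
  # idempotence
  rAA <- intersectGeneSets(list(a = c("x", "y"), b = c("x", "y")))
  expect_setequal(rAA$intersection, c("x", "y"))
  # conservation property over random sets
  set.seed(33)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(letters, sample(5:15, 1)))
    names(sets) <- c("s1", "s2", "s3")
    rr <- intersectGeneSets(sets)
    expect_equal(sum(rr$venn), length(unique(unlist(sets))))
    expect_setequal(rr$intersection, Reduce(intersect, sets))
  }
  expect_error(intersectGeneSets(list(a = "g1")), "two")
})

test_that("peak-overlap classification is a true partition", {
  m <- mkIntModels()
  peaks <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(c(19800, 124000),
                                                   width = 400))
  cls <- classifyByPeakOverlap(c("geneA", "geneB", "geneC"), peaks, m)
  expect_setequal(cls$bound, c("geneA", "geneC"))
  expect_setequal(cls$unbound, "geneB")
  # no peaks: everything unbound
  none <- classifyByPeakOverlap(c("geneA", "geneB"),
                                GenomicRanges::GRanges(), m)
  expect_equal(length(none$bound), 0)
  expect_setequal(none$unbound, c("geneA", "geneB"))
  # property: disjoint and exhaustive on random fixtures
  set.seed(44)
  for (i in 1:5) {
    pk <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(sample(1:130000, 8), width = 500))
    ids <- sample(c("geneA", "geneB", "geneC"), 2)
    cc <- classifyByPeakOverlap(ids, pk, m)
    expect_setequal(c(cc$bound, cc$unbound), ids)
    expect_length(intersect(cc$bound, cc$unbound), 0)
  }
})

test_that("co-regulated gene list requires both directions in every line", {
  tab <- function(ids, flags) data.frame(id = ids, flag = flags)
  line1 <- list(
    hypoxia_vs_normoxia = tab(c("g1", "g2", "g3"), c("up", "up", "ns")),
    kd_vs_ctrl = tab(c("g1", "g2", "g3"), c("down", "ns", "down")))
  line2 <- list(
    hypoxia_vs_normoxia = tab(c("g1", "g2", "g3"), c("up", "up", "up")),
    kd_vs_ctrl = tab(c("g1", "g2", "g3"), c("down", "down", "ns")))
  expect_equal(buildCoregulatedGeneList(list(line1)), "g1")
  # cross-line intersection: g2 is co-regulated in line2 only
  expect_equal(buildCoregulatedGeneList(list(line1, line2)), "g1")
  expect_error(buildCoregulatedGeneList(list(line1[1])), "absent")
})

test_that("the composed chain recovers planted gene classes on synthetic data", {
  st <- simulateStudy(simConfig(nChroms = 4, chromLength = 1000000L,
                                gainFraction = 0.06, seed = 83))
  gt <- geneTruth(st$truth)
  skip_if(sum(gt$is_de) < 3)
  sh <- sampleSheet(st$expression)
  deTabs <- lapply(list(hypoxia_vs_normoxia = c("normoxia", "hypoxia"),
                        kd_vs_ctrl = c("hypoxia_ctrlkd", "hypoxia_kd")),
                   function(ct) {
    j <- which(sh$condition %in% ct)
    callDE(counts(st$expression)[, j], sh$condition[j], contrast = ct)
  })
  co <- buildCoregulatedGeneList(list(deTabs))
  # genes linked to planted gain windows are enriched in the output
  linked <- gt$gene_id[gt$is_de]
  unlinked <- gt$gene_id[!gt$is_de]
  rateLinked <- mean(linked %in% co)
  rateUnlinked <- mean(unlinked %in% co)
  expect_gt(rateLinked, 0.5)
  expect_gt(rateLinked, rateUnlinked + 0.3)
  expect_lt(rateUnlinked, 0.05)
  # every planted bound gene that was recovered lands in the bound class
  cls <- classifyByPeakOverlap(intersect(co, linked), st$peaks, st$models)
  expect_true(all(intersect(st$boundGenes, intersect(co, linked)) %in%
                    cls$bound))
  expect_setequal(c(cls$bound, cls$unbound), intersect(co, linked))
})
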