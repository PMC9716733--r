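# Genomic feature classification of regions, TSS-relative motif scanning
# and strand-aware TSS metaprofiles.

.FEATURE_LEVELS <- c("proximal_promoter", "distal_promoter", "utr", "exon",
                     "intron", "intergenic")

# strand-aware upstream extension of gene bodies (promoter inclusion)
.extendUpstream <- function(gr, bp) {
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  st <- GenomicRanges::start(gr)
  en <- GenomicRanges::end(gr)
  st[!minus] <- pmax(1L, st[!minus] - as.integer(bp))
  en[minus] <- en[minus] + as.integer(bp)
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(st, en),
                                strand = GenomicRanges::strand(gr))
  S4Vectors::mcols(out) <- S4Vectors::mcols(gr)
  out
}

# promoter interval (distLo, distHi] upstream of the TSS on the coding
# strand, as genomic ranges; distLo < distHi in bp upstream
.promoterRanges <- function(models, distLo, distHi) {
  g <- models@genes
  tss <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                GenomicRanges::end(g), GenomicRanges::start(g))
  minus <- as.character(GenomicRanges::strand(g)) == "-"
  st <- ifelse(minus, tss + distLo, tss - distHi + 1L)
  en <- ifelse(minus, tss + distHi - 1L, tss - distLo)
  GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                         IRanges::IRanges(pmax(st, 1L), pmax(en, 1L)),
                         gene_id = S4Vectors::mcols(g)$gene_id)
}

#' Classify regions into genomic feature categories
#'
#' Each region is classified by its midpoint with the precedence
#' `proximal_promoter > distal_promoter > utr > exon > intron >
#' intergenic`. Promoter windows are measured upstream of the TSS on the
#' coding strand: proximal covers `(TSS - proximalBp, TSS]` and distal
#' `(TSS - distalBp, TSS - proximalBp]`. `intron` means inside a gene body
#' without touching an exon of that precedence level. The nearest gene
#' (ties broken by lexicographic gene id) is reported alongside.
#'
#' @param regions `GRanges` of regions (e.g. gain-of-6mA windows).
#' @param models a [GeneModels-class].
#' @param proximalBp,distalBp promoter distance cut-offs in bp upstream of
#'   the TSS (defaults 1000 and 10000).
#' @return `data.frame` with `region_id`, `feature` (factor over the six
#'   categories) and `gene_id` of the nearest gene (`NA` when no gene
#'   shares the chromosome).
#' @examples
#' # see summarizeAnnotation() for a complete example
#' @export
annotateRegions <- function(regions, models, proximalBp = 1000,
                            distalBp = 10000) {
  gchroms <- GenomeInfoDb::seqlevels(models@genes)
  known <- as.character(GenomicRanges::seqnames(regions)) %in% gchroms
  if (!all(known))
    stop("regions on chromosomes unknown to the gene models: ",
         paste(unique(as.character(
           GenomicRanges::seqnames(regions))[!known]), collapse = ", "))
  mid <- (GenomicRanges::start(regions) + GenomicRanges::end(regions)) %/% 2L
  midGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(regions),
                                  IRanges::IRanges(mid, width = 1L))
  hitAny <- function(feat) {
    GenomicRanges::countOverlaps(midGr, feat, ignore.strand = TRUE) > 0
  }
  prox <- hitAny(.promoterRanges(models, 0L, as.integer(proximalBp)))
  dist <- hitAny(.promoterRanges(models, as.integer(proximalBp),
                                 as.integer(distalBp)))
  inUtr <- hitAny(models@utrs)
  inExon <- hitAny(models@exons)
  inGene <- hitAny(models@genes)
  feature <- rep("intergenic", length(regions))
  feature[inGene] <- "intron"
  feature[inExon] <- "exon"
  feature[inUtr] <- "utr"
  feature[dist] <- "distal_promoter"
  feature[prox] <- "proximal_promoter"
  # nearest gene, ties by lexicographic gene id
  gid <- S4Vectors::mcols(models@genes)$gene_id
  ord <- order(gid)
  gSorted <- models@genes[ord]
  hits <- GenomicRanges::nearest(midGr, gSorted, ignore.strand = TRUE,
                                 select = "all")
  qh <- S4Vectors::queryHits(hits)
  sh <- S4Vectors::subjectHits(hits)
  o <- order(qh, sh)  # gSorted is in gene-id order, so min subject wins ties
  first <- o[!duplicated(qh[o])]
  geneId <- rep(NA_character_, length(midGr))
  geneId[qh[first]] <- gid[ord][sh[first]]
  ids <- names(regions)
  if (is.null(ids)) ids <- .windowIds(regions)
  data.frame(region_id = ids,
             feature = factor(feature, levels = .FEATURE_LEVELS),
             gene_id = geneId, row.names = NULL)
}

#' Summarize feature fractions of a region set
#'
#' @param regions `GRanges` of regions (non-empty).
#' @param models a [GeneModels-class].
#' @param ... passed to [annotateRegions()].
#' @return `data.frame` with `feature`, `count` and `fraction`; fractions
#'   sum to 1.
#' @examples
#' sim <- simulateGenome(simConfig(seed = 5))
#' w <- tileWindows(sim$layout)[1:50]
#' summarizeAnnotation(w, sim$models)
#' @export
summarizeAnnotation <- function(regions, models, ...) {
  if (!length(regions)) stop("no regions to summarize")
  ann <- annotateRegions(regions, models, ...)
  counts <- table(ann$feature)
  data.frame(feature = factor(names(counts), levels = .FEATURE_LEVELS),
             count = as.integer(counts),
             fraction = as.numeric(counts) / length(regions))
}

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
            S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT", D = "AGT",
            H = "ACT", V = "ACG", N = "ACGT")

# TSS-relative coordinate of a 1-based sequence position, in the gene's
# orientation: -1 is the base immediately upstream of the TSS, +1 the TSS.
.tssRelative <- function(pos, tssPos, strand) {
  if (strand == "+") ifelse(pos < tssPos, pos - tssPos, pos - tssPos + 1L)
  else ifelse(pos > tssPos, tssPos - pos, tssPos - pos + 1L)
}

#' Scan a sequence for an IUPAC consensus motif in TSS-relative coordinates
#'
#' Reports every exact IUPAC match of `motif` read 5' to 3' on the strand
#' of the gene. The input `sequence` is given in genome (plus-strand)
#' orientation; for a minus-strand gene the reverse complement of the motif
#' is located. Matches are reported both in absolute sequence coordinates
#' and TSS-relative coordinates, where -1 is the base immediately upstream
#' of the TSS, upstream is negative, and ranges are inclusive (so the HRE
#' core `ACGTG` planted at -147 spans -147 to -143).
#'
#' @param sequence character or `DNAString` over A/C/G/T/N.
#' @param motif IUPAC consensus string (e.g. `"TCGGAAGT"`, `"RCGTG"`).
#' @param tssPos 1-based position of the TSS base within `sequence`.
#' @param strand `"+"` or `"-"`: the strand of the gene.
#' @return `data.frame` with `motif`, `strand`, `start`, `end` (absolute,
#'   1-based) and `relStart`, `relEnd` (TSS-relative, `relStart <=
#'   relEnd`).
#' @examples
#' s <- paste0(strrep("T", 50), "ACGTG", strrep("T", 145))
#' scanMotif(s, "ACGTG", tssPos = 198, strand = "+")  # hit at -147..-143
#' @export
scanMotif <- function(sequence, motif, tssPos, strand = c("+", "-")) {
  strand <- match.arg(strand)
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(.IUPAC))
  if (length(bad))
    stop("invalid IUPAC code(s) in motif: ", paste(bad, collapse = ", "))
  subj <- Biostrings::DNAString(as.character(sequence))
  pat <- if (strand == "+") Biostrings::DNAString(motif) else
    Biostrings::reverseComplement(Biostrings::DNAString(motif))
  m <- Biostrings::matchPattern(pat, subj, fixed = FALSE)
  st <- BiocGenerics::start(m)
  en <- BiocGenerics::end(m)
  relA <- .tssRelative(st, tssPos, strand)
  relB <- .tssRelative(en, tssPos, strand)
  data.frame(motif = rep(motif, length(st)),
             strand = rep(strand, length(st)),
             start = st, end = en,
             relStart = pmin(relA, relB), relEnd = pmax(relA, relB))
}

#' Average tag density around transcription start sites
#'
#' Bins strand-oriented tag positions relative to every TSS into
#' `binBp`-wide bins covering `[-flankBp, flankBp)` (upstream negative)
#' and averages the per-bp density over genes.
#'
#' @param tags `GRanges` of width-1 tag positions.
#' @param models a [GeneModels-class] with at least one gene.
#' @param flankBp half-width of the profiled window (multiple of `binBp`).
#' @param binBp bin width in bp.
#' @return `data.frame` with `binStart`, `binEnd` (TSS-relative, bp) and
#'   `density` (tags per bp per gene).
#' @export
tssProfile <- function(tags, models, flankBp = 2000, binBp = 100) {
  if (!length(models@genes)) stop("no genes in the models")
  if (flankBp %% binBp != 0)
    stop("flankBp must be a multiple of binBp")
  g <- models@genes
  tss <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                GenomicRanges::end(g), GenomicRanges::start(g))
  minus <- as.character(GenomicRanges::strand(g)) == "-"
  rel <- numeric(0)
  tchr <- as.character(GenomicRanges::seqnames(tags))
  tpos <- GenomicRanges::start(tags)
  gchr <- as.character(GenomicRanges::seqnames(g))
  for (k in seq_along(g)) {
    d <- tpos[tchr == gchr[k]] - tss[k]
    if (minus[k]) d <- -d
    rel <- c(rel, d[d >= -flankBp & d < flankBp])
  }
  edges <- seq(-flankBp, flankBp, by = binBp)
  nbins <- length(edges) - 1L
  idx <- floor((rel + flankBp) / binBp) + 1L
  cnt <- tabulate(idx, nbins = nbins)
  data.frame(binStart = edges[-length(edges)], binEnd = edges[-1],
             density = cnt / binBp / length(g))
}
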