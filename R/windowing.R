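# Genome tiling, tag deduplication and per-window counting.

#' @importFrom GenomicRanges GRanges tileGenome findOverlaps countOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths seqlevels Seqinfo
NULL

#' Describe a genome layout
#'
#' @param chroms chromosome names (unique).
#' @param lengths chromosome lengths in bp (positive).
#' @return `data.frame` with columns `chrom` and `length`.
#' @examples
#' genomeLayout(c("chr1", "chr2"), c(300000, 300000))
#' @export
genomeLayout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(lengths <= 0) || any(!is.finite(lengths)))
    stop("chromosome lengths must be positive")
  data.frame(chrom = chroms, length = lengths)
}

.layoutSeqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = layout$chrom,
                        seqlengths = as.integer(layout$length))
}

#' Tile a genome into fixed-width windows
#'
#' Consecutive non-overlapping windows per chromosome; a trailing partial
#' window is retained whenever at least 1 bp remains, so the tiling is a
#' partition of the genome. Window ids use 0-based half-open coordinates.
#'
#' @param layout a layout from [genomeLayout()] (columns `chrom`,
#'   `length`).
#' @param width window width in bp (> 0; default 3000, the 3-kb windows of
#'   the differential 6mA pipeline).
#' @return `GRanges` of windows, named by window id, with an `is_partial`
#'   column flagging trailing windows shorter than `width`.
#' @examples
#' w <- tileWindows(genomeLayout("chr1", 10000), width = 3000)
#' names(w)   # "chr1:0-3000" ... "chr1:9000-10000"
#' @export
tileWindows <- function(layout, width = 3000) {
  if (!is.numeric(width) || length(width) != 1L || width <= 0)
    stop("width must be a single positive number")
  si <- .layoutSeqinfo(layout)
  gr <- GenomicRanges::tileGenome(si, tilewidth = as.integer(width),
                                  cut.last.tile.in.chrom = TRUE)
  names(gr) <- .windowIds(gr)
  S4Vectors::mcols(gr)$is_partial <- GenomicRanges::width(gr) < width
  gr
}

#' Deduplicate aligned 5'-end tags
#'
#' ChIP-exo tags are collapsed to at most one per (chromosome, 5' position,
#' strand); the first occurrence is kept and input order is preserved, so
#' the operation is idempotent.
#'
#' @param tags `GRanges` of width-1 tag positions (5' ends) with strand.
#' @return The deduplicated `GRanges`.
#' @examples
#' t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(100, 100, 100), width = 1),
#'                             strand = c("+", "+", "-"))
#' length(deduplicateTags(t))  # 2: strand distinguishes
#' @export
deduplicateTags <- function(tags) {
  key <- paste(as.character(GenomicRanges::seqnames(tags)),
               GenomicRanges::start(tags),
               as.character(GenomicRanges::strand(tags)))
  tags[!duplicated(key)]
}

#' Count tags per window
#'
#' Assigns every tag to the unique window containing its 5'-end position
#' (windows are half-open in 0-based terms, so a tag at position `k * width`
#' opens the next window). Tags below the mapping-quality cut-off are
#' excluded; tags on chromosomes absent from the tiling are skipped with a
#' warning and reported in the `dropped` attribute. The column sum equals
#' the number of retained tags.
#'
#' @param tags deduplicated tag `GRanges`; an optional `mapq` metadata
#'   column is compared against `mapqMin`.
#' @param windows tiled windows from [tileWindows()].
#' @param mapqMin minimum mapping quality (default 10); ignored when the
#'   tags carry no `mapq`.
#' @return Integer vector of counts named by window id, with attribute
#'   `dropped` (tags on unknown chromosomes).
#' @examples
#' w <- tileWindows(genomeLayout("chr1", 9000), 3000)
#' t <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(3000, 3001), width = 1))
#' countTags(t, w)   # both tags fall in [3000, 6000)
#' @export
countTags <- function(tags, windows, mapqMin = 10) {
  mq <- S4Vectors::mcols(tags)$mapq
  if (!is.null(mq)) tags <- tags[mq >= mapqMin]
  known <- as.character(GenomicRanges::seqnames(tags)) %in%
    GenomeInfoDb::seqlevels(windows)
  dropped <- sum(!known)
  if (dropped > 0) {
    warning(dropped, " tag(s) on chromosomes absent from the tiling were ",
            "skipped")
    tags <- tags[known]
  }
  # 5'-end positions as width-1 ranges; each hits exactly one tile
  pos <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(tags),
    IRanges::IRanges(GenomicRanges::start(tags), width = 1L))
  GenomeInfoDb::seqlevels(pos) <- GenomeInfoDb::seqlevels(windows)
  counts <- GenomicRanges::countOverlaps(windows, pos)
  names(counts) <- names(windows)
  attr(counts, "dropped") <- dropped
  counts
}

#' Assemble a WindowCounts object from per-sample tag sets
#'
#' Deduplicates and counts each sample's tags over a shared tiling and
#' binds them into a [WindowCounts-class]; library sizes are the retained
#' tag totals per sample.
#'
#' @param tagList named list of tag `GRanges`, one element per sample.
#' @param windows tiled windows from [tileWindows()].
#' @param sampleSheet `data.frame` with `condition`, `track`, `replicate`
#'   in the order of `tagList`.
#' @param mapqMin minimum mapping quality passed to [countTags()].
#' @return A [WindowCounts-class].
#' @export
buildWindowCounts <- function(tagList, windows, sampleSheet, mapqMin = 10) {
  stopifnot(length(tagList) == nrow(sampleSheet))
  mat <- vapply(tagList, function(t) {
    as.integer(countTags(deduplicateTags(t), windows, mapqMin))
  }, integer(length(windows)))
  colnames(mat) <- names(tagList)
  WindowCounts(mat, windows, sampleSheet)
}
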