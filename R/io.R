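# Readers and writers for the standard plain-text formats around the
# pipeline: chrom sizes TSV, BED6 tags and peaks, GFF3 gene models, TSV
# count matrices and the JSON truth table.

#' @importFrom utils read.delim write.table
#' @importFrom rtracklayer import export
NULL

#' Read a two-column chrom-sizes table
#'
#' @param path TSV with chromosome name and length (no header).
#' @return A layout `data.frame` from [genomeLayout()].
#' @export
readChromSizes <- function(path) {
  df <- read.delim(path, header = FALSE)
  genomeLayout(df[[1]], df[[2]])
}

#' Read aligned 5'-end tags from BED6
#'
#' One BED record per tag; the 5' end is the interval start for `+`
#' records and the interval end for `-` records. The BED score column is
#' kept as the mapping quality.
#'
#' @param path BED6 file.
#' @return `GRanges` of width-1 tag positions with `mapq`.
#' @export
readTagsBed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  minus <- as.character(GenomicRanges::strand(gr)) == "-"
  pos <- ifelse(minus, GenomicRanges::end(gr), GenomicRanges::start(gr))
  out <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                IRanges::IRanges(pos, width = 1L),
                                strand = GenomicRanges::strand(gr))
  sc <- S4Vectors::mcols(gr)$score
  S4Vectors::mcols(out)$mapq <- if (is.null(sc)) rep(255L, length(gr))
    else as.integer(sc)
  out
}

#' Write tags as BED6 5'-end records
#'
#' @param tags width-1 tag `GRanges` with optional `mapq`.
#' @param path output BED file.
#' @export
writeTagsBed <- function(tags, path) {
  mq <- S4Vectors::mcols(tags)$mapq
  if (is.null(mq)) mq <- rep(255L, length(tags))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(tags)),
    start = GenomicRanges::start(tags) - 1L,
    end = GenomicRanges::start(tags),
    name = sprintf("tag%d", seq_along(tags)),
    score = mq,
    strand = as.character(GenomicRanges::strand(tags)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Read gene models from GFF3
#'
#' Records of type `gene` become gene bodies (identifier from the `ID` or
#' `gene_id` attribute; duplicates are rejected); `exon` records and any
#' type containing `UTR` are attached by their `Parent`/`gene_id`
#' attribute.
#'
#' @param path GFF3 file.
#' @return A [GeneModels-class].
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(S4Vectors::mcols(gr)$type)
  pickId <- function(x) {
    id <- S4Vectors::mcols(x)$gene_id
    if (is.null(id)) id <- S4Vectors::mcols(x)$ID
    as.character(id)
  }
  parentOf <- function(x) {
    p <- S4Vectors::mcols(x)$Parent
    if (is.null(p)) return(pickId(x))
    as.character(vapply(p, function(v)
      if (length(v)) v[[1]] else NA_character_, character(1)))
  }
  g <- gr[type == "gene"]
  gid <- pickId(g)
  if (anyDuplicated(gid)) stop("duplicate gene identifiers in the GFF3")
  genes <- GenomicRanges::granges(g)
  S4Vectors::mcols(genes)$gene_id <- gid
  ex <- gr[type == "exon"]
  exons <- GenomicRanges::granges(ex)
  S4Vectors::mcols(exons)$gene_id <- sub("^(transcript|mRNA):", "",
                                         parentOf(ex))
  ut <- gr[grepl("UTR", type, ignore.case = TRUE)]
  utrs <- GenomicRanges::granges(ut)
  S4Vectors::mcols(utrs)$gene_id <- sub("^(transcript|mRNA):", "",
                                        parentOf(ut))
  geneModels(genes, exons, utrs)
}

#' Write gene models as GFF3
#'
#' @param models a [GeneModels-class].
#' @param path output GFF3 file.
#' @export
writeGeneModelsGff3 <- function(models, path) {
  tag <- function(gr, type, id, parent = NULL) {
    out <- GenomicRanges::granges(gr)
    S4Vectors::mcols(out)$source <- "gain6mA"
    S4Vectors::mcols(out)$type <- type
    S4Vectors::mcols(out)$ID <- id
    if (!is.null(parent)) S4Vectors::mcols(out)$Parent <- parent
    out
  }
  g <- models@genes
  gid <- S4Vectors::mcols(g)$gene_id
  ex <- models@exons
  exParent <- S4Vectors::mcols(ex)$gene_id
  exId <- paste0(exParent, ".exon", sequence(rle(exParent)$lengths))
  ut <- models@utrs
  utParent <- S4Vectors::mcols(ut)$gene_id
  utId <- paste0(utParent, ".utr", sequence(rle(utParent)$lengths))
  all <- c(tag(g, "gene", gid),
           tag(ex, "exon", exId, exParent),
           tag(ut, "UTR", utId, utParent))
  rtracklayer::export(sort(all, ignore.strand = TRUE), path,
                      format = "GFF3")
}

#' Write a WindowCounts object as TSV count matrix + sample sheet
#'
#' @param wc a [WindowCounts-class].
#' @param countsPath TSV of counts, first column the unit id.
#' @param sheetPath TSV sample sheet (sample, condition, track, replicate,
#'   lib.size).
#' @export
writeCountMatrix <- function(wc, countsPath, sheetPath) {
  y <- counts(wc)
  df <- data.frame(id = rownames(y), y, check.names = FALSE)
  write.table(df, countsPath, sep = "\t", quote = FALSE, row.names = FALSE)
  sh <- sampleSheet(wc)
  sh <- data.frame(sample = colnames(y), sh)
  write.table(sh, sheetPath, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV count matrix + sample sheet into a WindowCounts
#'
#' Unit ids of the form `chrom:start-end` (0-based half-open) are parsed
#' back into genomic ranges; other ids become unit-length placeholder
#' ranges on a synthetic contig.
#'
#' @param countsPath,sheetPath files written by [writeCountMatrix()].
#' @return A [WindowCounts-class].
#' @export
readCountMatrix <- function(countsPath, sheetPath) {
  df <- read.delim(countsPath, check.names = FALSE)
  ids <- df[[1]]
  y <- as.matrix(df[, -1, drop = FALSE])
  sh <- read.delim(sheetPath)
  parse <- regmatches(ids, regexec("^(.+):(\\d+)-(\\d+)$", ids))
  ok <- lengths(parse) == 4L
  if (all(ok)) {
    chrom <- vapply(parse, `[`, character(1), 2)
    st <- as.integer(vapply(parse, `[`, character(1), 3)) + 1L
    en <- as.integer(vapply(parse, `[`, character(1), 4))
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(st, en))
  } else {
    gr <- GenomicRanges::GRanges("unplaced",
                                 IRanges::IRanges(seq_along(ids),
                                                  width = 1L))
  }
  names(gr) <- ids
  WindowCounts(y, gr, sh[, c("condition", "track", "replicate")],
               libSizes = sh$lib.size)
}

#' Write called gain regions as BED6
#'
#' The BED name is the window id and the score is `-10 * log10(p)` of the
#' first comparison, capped at 1000.
#'
#' @param grs a [GainRegionSet-class].
#' @param path output BED file.
#' @export
writeGainRegionsBed <- function(grs, path) {
  r <- gainRegions(grs)
  p <- S4Vectors::mcols(r)$p
  score <- if (is.null(p)) rep(0, length(r)) else
    pmin(1000, round(-10 * log10(pmax(p, 1e-100))))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(r)),
    start = GenomicRanges::start(r) - 1L,
    end = GenomicRanges::end(r),
    name = names(r),
    score = score,
    strand = ".")
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Write a complete synthetic study to a directory
#'
#' Emits the toy genome (FASTA), chrom sizes (TSV), gene models (GFF3),
#' window and expression count matrices with sample sheets (TSV), the peak
#' set (BED6), calibration tables (TSV) and the truth table (JSON).
#' Identical configs produce identical files.
#'
#' @param study output of [simulateStudy()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of written paths.
#' @export
writeSimulation <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    genome = file.path(dir, "genome.fa"),
    chrom_sizes = file.path(dir, "chrom_sizes.tsv"),
    genes = file.path(dir, "genes.gff3"),
    counts = file.path(dir, "window_counts.tsv"),
    counts_sheet = file.path(dir, "window_samples.tsv"),
    expression = file.path(dir, "expression_counts.tsv"),
    expression_sheet = file.path(dir, "expression_samples.tsv"),
    peaks = file.path(dir, "peaks.bed"),
    ms_standards = file.path(dir, "ms_standards.tsv"),
    qpcr_standards = file.path(dir, "qpcr_standards.tsv"),
    truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(study$genome, paths[["genome"]])
  write.table(study$layout, paths[["chrom_sizes"]], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeGeneModelsGff3(study$models, paths[["genes"]])
  writeCountMatrix(study$counts, paths[["counts"]],
                   paths[["counts_sheet"]])
  writeCountMatrix(study$expression, paths[["expression"]],
                   paths[["expression_sheet"]])
  pk <- study$peaks
  write.table(data.frame(as.character(GenomicRanges::seqnames(pk)),
                         GenomicRanges::start(pk) - 1L,
                         GenomicRanges::end(pk), names(pk), 0L, "."),
              paths[["peaks"]], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  write.table(study$calibration$ms$standards, paths[["ms_standards"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(study$calibration$qpcr$standards, paths[["qpcr_standards"]],
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(windows = windowTruth(study$truth),
                genes = geneTruth(study$truth))
  jsonlite::write_json(truth, paths[["truth"]], dataframe = "columns",
                       na = "null", digits = NA)
  invisible(paths)
}
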