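# Gene-set integration: region-to-gene assignment, Venn intersections,
# peak-overlap gene classes and the co-regulated gene list.

#' Assign regions to genes by body or promoter overlap
#'
#' A region is assigned to every gene whose body or upstream promoter
#' window (default 10 kb) it overlaps; multi-assignments are retained and
#' tagged with the rule that matched (`"body"` when the gene body itself
#' overlaps, `"promoter"` otherwise).
#'
#' @param regions `GRanges` of regions, named by id.
#' @param models a [GeneModels-class].
#' @param promoterBp upstream promoter window in bp.
#' @return List with `assignments` (`data.frame` of `region_id`,
#'   `gene_id`, `rule`) and `unmapped` (ids of regions assigned to no
#'   gene).
#' @export
assignRegionsToGenes <- function(regions, models, promoterBp = 10000) {
  ids <- names(regions)
  if (is.null(ids)) ids <- .windowIds(regions)
  g <- models@genes
  gid <- S4Vectors::mcols(g)$gene_id
  ovBody <- GenomicRanges::findOverlaps(regions, g, ignore.strand = TRUE)
  ext <- .extendUpstream(g, promoterBp)
  ovExt <- GenomicRanges::findOverlaps(regions, ext, ignore.strand = TRUE)
  bodyKey <- paste(S4Vectors::queryHits(ovBody),
                   S4Vectors::subjectHits(ovBody))
  extKey <- paste(S4Vectors::queryHits(ovExt), S4Vectors::subjectHits(ovExt))
  assignments <- data.frame(
    region_id = ids[S4Vectors::queryHits(ovExt)],
    gene_id = gid[S4Vectors::subjectHits(ovExt)],
    rule = ifelse(extKey %in% bodyKey, "body", "promoter"))
  assignments <- assignments[order(assignments$region_id,
                                   assignments$gene_id), , drop = FALSE]
  rownames(assignments) <- NULL
  list(assignments = assignments,
       unmapped = setdiff(ids, assignments$region_id))
}

#' Intersect gene sets with Venn cell counts
#'
#' @param sets named list (>= 2) of character vectors of gene ids.
#' @return List with `intersection` (ids present in every set) and `venn`
#'   (named integer vector of exclusive cell counts; names are
#'   `"&"`-joined set names; cells sum to the union size).
#' @examples
#' intersectGeneSets(list(a = c("g1", "g2", "g3"), b = c("g2", "g3", "g4")))
#' @export
intersectGeneSets <- function(sets) {
  if (!is.list(sets) || length(sets) < 2L)
    stop("at least two gene sets are required")
  if (is.null(names(sets)))
    names(sets) <- paste0("set", seq_along(sets))
  sets <- lapply(sets, unique)
  union <- unique(unlist(sets))
  member <- vapply(sets, function(s) union %in% s,
                   logical(length(union)))
  member <- matrix(member, nrow = length(union),
                   dimnames = list(union, names(sets)))
  pattern <- apply(member, 1, function(m)
    paste(names(sets)[m], collapse = "&"))
  venn <- vapply(split(union, pattern), length, integer(1))
  list(intersection = union[rowSums(member) == length(sets)],
       venn = venn)
}

#' Partition genes by peak overlap
#'
#' Splits a gene set into genes with at least one peak overlapping their
#' body or upstream promoter window ("bound") and the rest ("unbound").
#' The two parts are disjoint and jointly exhaustive.
#'
#' @param geneIds character vector of gene ids.
#' @param peaks `GRanges` of peaks.
#' @param models a [GeneModels-class].
#' @param promoterBp upstream promoter window in bp.
#' @return List with `bound` and `unbound` character vectors.
#' @export
classifyByPeakOverlap <- function(geneIds, peaks, models,
                                  promoterBp = 10000) {
  g <- models@genes
  gid <- S4Vectors::mcols(g)$gene_id
  idx <- match(geneIds, gid)
  if (anyNA(idx))
    stop("gene ids missing from the models: ",
         paste(geneIds[is.na(idx)], collapse = ", "))
  ext <- .extendUpstream(g[idx], promoterBp)
  hit <- GenomicRanges::countOverlaps(ext, peaks, ignore.strand = TRUE) > 0
  list(bound = geneIds[hit], unbound = geneIds[!hit])
}

#' Build the co-regulated gene list from differential-expression tables
#'
#' Genes upregulated under hypoxia (hypoxia vs normoxia) AND downregulated
#' under methyltransferase knockdown in hypoxia (knockdown vs control),
#' intersected across every provided cell line.
#'
#' @param deTables list with one element per cell line; each element is a
#'   named list of [callDE()] tables (contrast name -> table).
#' @param upContrast,downContrast names of the contrasts gating `"up"` and
#'   `"down"` flags respectively.
#' @return Character vector of co-regulated gene ids.
#' @export
buildCoregulatedGeneList <- function(deTables,
                                     upContrast = "hypoxia_vs_normoxia",
                                     downContrast = "kd_vs_ctrl") {
  if (!length(deTables)) stop("no DE tables supplied")
  perLine <- lapply(deTables, function(tabs) {
    for (ct in c(upContrast, downContrast))
      if (!ct %in% names(tabs))
        stop(sprintf("contrast '%s' absent from a cell line's tables", ct))
    up <- tabs[[upContrast]]
    dn <- tabs[[downContrast]]
    intersect(up$id[up$flag == "up"], dn$id[dn$flag == "down"])
  })
  Reduce(intersect, perLine)
}
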