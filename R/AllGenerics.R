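# Generics and simple accessors.

#' Library sizes of a count container
#'
#' @param x a [WindowCounts-class] object.
#' @return Numeric vector of per-sample library sizes.
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))

#' @rdname libSizes
#' @export
setMethod("libSizes", "WindowCounts", function(x) {
  SummarizedExperiment::colData(x)$lib.size
})

#' Sample sheet of a count container
#'
#' @param x a [WindowCounts-class] object.
#' @return `data.frame` with condition, track, replicate and lib.size.
#' @export
setGeneric("sampleSheet", function(x) standardGeneric("sampleSheet"))

#' @rdname sampleSheet
#' @export
setMethod("sampleSheet", "WindowCounts", function(x) {
  as.data.frame(SummarizedExperiment::colData(x))
})

#' @importFrom BiocGenerics counts
#' @export
setMethod("counts", "WindowCounts", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

#' Estimated dispersion value
#'
#' @param object a [DispersionEstimate-class].
#' @return The common dispersion phi as a single number.
#' @export
setGeneric("dispersion", function(object) standardGeneric("dispersion"))

#' @rdname dispersion
#' @export
setMethod("dispersion", "DispersionEstimate", function(object) object@phi)

#' Common pseudo-library size
#'
#' @param object a [DispersionEstimate-class].
#' @return The geometric-mean library size N*.
#' @export
setGeneric("pseudoLibSize", function(object) standardGeneric("pseudoLibSize"))

#' @rdname pseudoLibSize
#' @export
setMethod("pseudoLibSize", "DispersionEstimate",
          function(object) object@pseudoLib)

#' Regions of a gain-region set
#'
#' @param object a [GainRegionSet-class].
#' @return `GRanges` of the emitted regions with provenance flags.
#' @export
setGeneric("gainRegions", function(object) standardGeneric("gainRegions"))

#' @rdname gainRegions
#' @export
setMethod("gainRegions", "GainRegionSet", function(object) object@regions)

#' Per-stage passing counts of a gain-region call
#'
#' @param object a [GainRegionSet-class].
#' @return Named integer vector of windows passing each stage.
#' @export
setGeneric("stageCounts", function(object) standardGeneric("stageCounts"))

#' @rdname stageCounts
#' @export
setMethod("stageCounts", "GainRegionSet", function(object) object@stageCounts)

#' Window-level ground truth of a synthetic study
#'
#' @param object a [TruthTable-class].
#' @return `data.frame` of per-window planted effects.
#' @export
setGeneric("windowTruth", function(object) standardGeneric("windowTruth"))

#' @rdname windowTruth
#' @export
setMethod("windowTruth", "TruthTable", function(object) object@windows)

#' Gene-level ground truth of a synthetic study
#'
#' @param object a [TruthTable-class].
#' @return `data.frame` of per-gene planted effects.
#' @export
setGeneric("geneTruth", function(object) standardGeneric("geneTruth"))

#' @rdname geneTruth
#' @export
setMethod("geneTruth", "TruthTable", function(object) object@genes)

#' Gene bodies of a set of gene models
#'
#' @param object a [GeneModels-class].
#' @return `GRanges` of gene bodies with `gene_id`.
#' @export
setGeneric("genes", function(object) standardGeneric("genes"))

#' @rdname genes
#' @export
setMethod("genes", "GeneModels", function(object) object@genes)

#' Transcription start sites of gene models
#'
#' The TSS is the 5' end of the gene body: start on `+`, end on `-`.
#'
#' @param object a [GeneModels-class].
#' @return Integer vector of TSS positions (1-based), named by gene id.
#' @export
setGeneric("tssOf", function(object) standardGeneric("tssOf"))

#' @rdname tssOf
#' @export
setMethod("tssOf", "GeneModels", function(object) {
  g <- object@genes
  tss <- ifelse(as.character(GenomicRanges::strand(g)) == "-",
                GenomicRanges::end(g), GenomicRanges::start(g))
  names(tss) <- S4Vectors::mcols(g)$gene_id
  tss
})
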