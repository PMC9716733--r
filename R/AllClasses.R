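#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end strand width
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importClassesFrom GenomicRanges GRanges
#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
NULL

# ---------------------------------------------------------------------------
# SimConfig

#' Configuration of the synthetic 6mA study generator
#'
#' Holds every knob of the synthetic data generator: the toy genome layout,
#' the negative-binomial count model, the planted hypoxia-induced /
#' knockdown-reverted gain effect, and the planted WGA amplification
#' artifacts. A fixed `seed` makes every downstream simulation
#' byte-reproducible.
#'
#' @slot nChroms number of chromosomes in the toy genome.
#' @slot chromLength length of each chromosome in bp.
#' @slot windowWidth genomic window width in bp (default 3000, the 3-kb
#'   windows used throughout the pipeline).
#' @slot nReplicates replicates per condition and track.
#' @slot meanDepth expected tags per window per sample.
#' @slot dispersion true negative-binomial dispersion phi (>= 0) of the
#'   generated counts.
#' @slot gainFraction fraction of windows planted as gain-of-6mA.
#' @slot gainEffect multiplicative fold (>= 1) applied to signal counts of
#'   hypoxic conditions carrying the effect (hypoxia and hypoxia with
#'   control knockdown); knockdown reverts it.
#' @slot wgaArtifactFraction fraction of windows planted as WGA
#'   amplification artifacts.
#' @slot wgaArtifactEffect extra fold applied to artifact windows in the WGA
#'   track.
#' @slot wgaArtifactSignalEffect bleed-through fold applied to artifact
#'   windows in hypoxic signal tracks.
#' @slot inputBiasSd log-normal sd of the shared per-window propensity
#'   applied to signal, input and WGA alike.
#' @slot geneSpacing mean intergenic spacing in bp for the toy gene models.
#' @slot expressionEffect fold applied to expression of genes linked to
#'   planted gain windows.
#' @slot seed master integer seed; per-stream sub-seeds are derived from it
#'   deterministically.
#'
#' @seealso [simConfig()], [simulateStudy()]
#' @export
setClass("SimConfig", representation(
  nChroms = "integer", chromLength = "integer", windowWidth = "integer",
  nReplicates = "integer", meanDepth = "numeric", dispersion = "numeric",
  gainFraction = "numeric", gainEffect = "numeric",
  wgaArtifactFraction = "numeric", wgaArtifactEffect = "numeric",
  wgaArtifactSignalEffect = "numeric", inputBiasSd = "numeric",
  geneSpacing = "integer", expressionEffect = "numeric", seed = "integer"))

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nChroms < 1L) msg <- c(msg, "nChroms must be >= 1")
  if (object@chromLength < 1L) msg <- c(msg, "chromLength must be positive")
  if (object@windowWidth < 1L) msg <- c(msg, "windowWidth must be positive")
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be positive")
  if (object@dispersion < 0) msg <- c(msg, "dispersion must be >= 0")
  for (f in c("gainFraction", "wgaArtifactFraction")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must be in [0, 1]", f))
  }
  if (object@gainFraction + object@wgaArtifactFraction > 1)
    msg <- c(msg, "gainFraction + wgaArtifactFraction must be <= 1")
  if (object@gainEffect < 1) msg <- c(msg, "gainEffect must be >= 1")
  if (object@wgaArtifactEffect < 1)
    msg <- c(msg, "wgaArtifactEffect must be >= 1")
  if (object@wgaArtifactSignalEffect < 1)
    msg <- c(msg, "wgaArtifactSignalEffect must be >= 1")
  if (object@inputBiasSd < 0) msg <- c(msg, "inputBiasSd must be >= 0")
  if (object@geneSpacing < 1L) msg <- c(msg, "geneSpacing must be positive")
  if (object@expressionEffect < 1)
    msg <- c(msg, "expressionEffect must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Create a synthetic-study configuration
#'
#' Defaults describe the study conditions emulated throughout:
#' three replicates per condition and track (three hypoxia replicates enter
#' each comparison), 3-kb windows, a mean depth of 50 tags per window,
#' a common dispersion of 0.02 (biological coefficient of variation about
#' 0.14, typical of replicate cell-line cultures), a two-fold planted gain
#' effect, and WGA artifacts three-fold inflated in the WGA track with a
#' 1.5-fold bleed-through into hypoxic signal tracks.
#'
#' @param nChroms,chromLength,windowWidth,nReplicates,meanDepth,dispersion
#'   see [SimConfig-class].
#' @param gainFraction,gainEffect,wgaArtifactFraction,wgaArtifactEffect
#'   see [SimConfig-class].
#' @param wgaArtifactSignalEffect,inputBiasSd,geneSpacing,expressionEffect
#'   see [SimConfig-class].
#' @param seed master seed for all random streams.
#' @return A [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nChroms = 2, chromLength = 300000, seed = 11)
#' cfg
#' @export
simConfig <- function(nChroms = 2L, chromLength = 300000L,
                      windowWidth = 3000L, nReplicates = 3L,
                      meanDepth = 50, dispersion = 0.02,
                      gainFraction = 0.02, gainEffect = 2,
                      wgaArtifactFraction = 0.02, wgaArtifactEffect = 3,
                      wgaArtifactSignalEffect = 1.5, inputBiasSd = 0.2,
                      geneSpacing = 10000L, expressionEffect = 2,
                      seed = 1L) {
  new("SimConfig",
      nChroms = as.integer(nChroms), chromLength = as.integer(chromLength),
      windowWidth = as.integer(windowWidth),
      nReplicates = as.integer(nReplicates),
      meanDepth = as.numeric(meanDepth), dispersion = as.numeric(dispersion),
      gainFraction = as.numeric(gainFraction),
      gainEffect = as.numeric(gainEffect),
      wgaArtifactFraction = as.numeric(wgaArtifactFraction),
      wgaArtifactEffect = as.numeric(wgaArtifactEffect),
      wgaArtifactSignalEffect = as.numeric(wgaArtifactSignalEffect),
      inputBiasSd = as.numeric(inputBiasSd),
      geneSpacing = as.integer(geneSpacing),
      expressionEffect = as.numeric(expressionEffect),
      seed = as.integer(seed))
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nChroms, "chrom(s) x", object@chromLength, "bp,",
      object@windowWidth, "bp windows\n")
  cat("  counts: depth", object@meanDepth, "phi", object@dispersion,
      "reps", object@nReplicates, "\n")
  cat("  planted: gain", object@gainFraction, "x", object@gainEffect,
      "| wga artifact", object@wgaArtifactFraction, "x",
      object@wgaArtifactEffect, "(signal x",
      object@wgaArtifactSignalEffect, ")\n")
  cat("  seed:", object@seed, "\n")
})

# ---------------------------------------------------------------------------
# TruthTable

#' Ground truth of a synthetic study
#'
#' Records, per window, whether a gain-of-6mA effect or a WGA amplification
#' artifact was planted (the two sets are disjoint by construction), and per
#' gene whether it is differentially expressed and which planted window it
#' is linked to. This is the acceptance surface for recovery tests.
#'
#' @slot windows `data.frame` with columns `window_id`, `is_gain`,
#'   `is_wga_artifact`, `effect`.
#' @slot genes `data.frame` with columns `gene_id`, `is_de`,
#'   `linked_window` (`NA` when unlinked).
#' @export
setClass("TruthTable",
         representation(windows = "data.frame", genes = "data.frame"))

setValidity("TruthTable", function(object) {
  msg <- character()
  w <- object@windows
  need <- c("window_id", "is_gain", "is_wga_artifact", "effect")
  if (!all(need %in% names(w)))
    msg <- c(msg, "windows must have window_id/is_gain/is_wga_artifact/effect")
  else if (any(w$is_gain & w$is_wga_artifact))
    msg <- c(msg, "gain and artifact window sets must be disjoint")
  g <- object@genes
  if (nrow(g)) {
    if (!all(c("gene_id", "is_de", "linked_window") %in% names(g)))
      msg <- c(msg, "genes must have gene_id/is_de/linked_window")
    else {
      lw <- g$linked_window[!is.na(g$linked_window)]
      if (!all(lw %in% w$window_id))
        msg <- c(msg, "every linked_window must exist among windows")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "TruthTable", function(object) {
  cat("TruthTable:", nrow(object@windows), "windows (",
      sum(object@windows$is_gain), "gain,",
      sum(object@windows$is_wga_artifact), "WGA artifact );",
      nrow(object@genes), "genes (", sum(object@genes$is_de), "DE )\n")
})

# ---------------------------------------------------------------------------
# WindowCounts

#' Windowed (or gene-level) count container
#'
#' A `RangedSummarizedExperiment` holding one integer `counts` assay over
#' genomic windows (or genes), with the sample sheet in `colData`
#' (`condition`, `track`, `replicate`, `lib.size`). Library sizes default to
#' column sums but may be overridden at construction.
#'
#' @seealso [WindowCounts()], [libSizes()], [sampleSheet()]
#' @export
setClass("WindowCounts",
         contains = "RangedSummarizedExperiment")

setValidity("WindowCounts", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    y <- SummarizedExperiment::assay(object, "counts")
    if (any(y < 0) || any(y != round(y)))
      msg <- c(msg, "counts must be non-negative integers")
  }
  cd <- SummarizedExperiment::colData(object)
  need <- c("condition", "track", "replicate", "lib.size")
  if (!all(need %in% names(cd)))
    msg <- c(msg, "colData needs condition, track, replicate, lib.size")
  else {
    if (!all(cd$track %in% c("signal", "input", "wga", "rna")))
      msg <- c(msg, "track must be one of signal/input/wga/rna")
    if (any(cd$lib.size <= 0))
      msg <- c(msg, "lib.size must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a WindowCounts object
#'
#' @param counts integer matrix, units (windows or genes) x samples.
#' @param rowRanges `GRanges` of the units, same length as `nrow(counts)`.
#' @param sampleSheet `data.frame` with one row per sample and columns
#'   `condition`, `track` (one of `"signal"`, `"input"`, `"wga"`, `"rna"`)
#'   and `replicate`.
#' @param libSizes optional numeric vector of library sizes; defaults to
#'   column sums of `counts`.
#' @return A [WindowCounts-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 3001),
#'                                                       c(3000, 6000)))
#' y <- matrix(5:8, 2, 2, dimnames = list(NULL, c("s1", "s2")))
#' sheet <- data.frame(condition = c("normoxia", "hypoxia"),
#'                     track = "signal", replicate = 1L)
#' wc <- WindowCounts(y, gr, sheet)
#' libSizes(wc)
#' @export
WindowCounts <- function(counts, rowRanges, sampleSheet, libSizes = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (is.null(libSizes)) libSizes <- colSums(counts)
  if (is.null(colnames(counts)))
    colnames(counts) <- paste0(sampleSheet$condition, ".",
                               sampleSheet$track, ".", sampleSheet$replicate)
  if (is.null(names(rowRanges)) || !length(names(rowRanges)))
    names(rowRanges) <- .windowIds(rowRanges)
  rownames(counts) <- names(rowRanges)
  cd <- S4Vectors::DataFrame(sampleSheet, lib.size = as.numeric(libSizes),
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowRanges = rowRanges, colData = cd)
  new("WindowCounts", se)
}

# ---------------------------------------------------------------------------
# DispersionEstimate

#' Common negative-binomial dispersion estimate
#'
#' Result of the quantile-adjusted conditional maximum-likelihood (qCML)
#' fit: the common dispersion maximizing the summed conditional
#' log-likelihood over units after library-size equalization to the common
#' pseudo-library.
#'
#' @slot phi estimated common dispersion (>= 0, finite).
#' @slot pseudoLib common pseudo-library size N* (geometric mean of the
#'   library sizes).
#' @slot logLik conditional log-likelihood at the maximum.
#' @slot nPasses number of equalize/maximize passes performed.
#' @export
setClass("DispersionEstimate", representation(
  phi = "numeric", pseudoLib = "numeric", logLik = "numeric",
  nPasses = "integer"))

setValidity("DispersionEstimate", function(object) {
  if (!is.finite(object@phi) || object@phi < 0)
    "phi must be finite and >= 0" else TRUE
})

setMethod("show", "DispersionEstimate", function(object) {
  cat(sprintf("DispersionEstimate: phi = %.6g (N* = %.1f, %d passes)\n",
              object@phi, object@pseudoLib, object@nPasses))
})

# ---------------------------------------------------------------------------
# ComparisonSpec

#' Specification of one differential 6mA comparison
#'
#' Defines a condition contrast (B vs A), the direction in which a window
#' must move to pass, the input-normalized log2 fold-change threshold
#' `tau` (default `log2(1.1)`), and the exact-test p-value gate `alpha`
#' (default 0.05; `NA` disables the p gate so only the fold cut-off
#' applies).
#'
#' @slot name comparison label.
#' @slot conditionA,conditionB condition labels resolved in the sample
#'   sheet; the fold change and the test are B vs A.
#' @slot direction `"up"` (pass when delta > tau) or `"down"` (pass when
#'   delta < -tau).
#' @slot tau positive log2 fold-change threshold.
#' @slot alpha p-value threshold in (0, 1), or `NA` to gate on fold change
#'   only.
#' @seealso [comparisonSpec()], [runComparison()]
#' @export
setClass("ComparisonSpec", representation(
  name = "character", conditionA = "character", conditionB = "character",
  direction = "character", tau = "numeric", alpha = "numeric"))

setValidity("ComparisonSpec", function(object) {
  msg <- character()
  if (!object@direction %in% c("up", "down"))
    msg <- c(msg, "direction must be 'up' or 'down'")
  if (object@tau <= 0) msg <- c(msg, "tau must be > 0")
  if (!is.na(object@alpha) && (object@alpha <= 0 || object@alpha >= 1))
    msg <- c(msg, "alpha must be in (0, 1) or NA")
  if (length(msg)) msg else TRUE
})

#' @rdname ComparisonSpec-class
#' @param name,conditionA,conditionB,direction,tau,alpha see slots.
#' @return A [ComparisonSpec-class].
#' @examples
#' comparisonSpec("c1", "normoxia", "hypoxia", "up")
#' @export
comparisonSpec <- function(name, conditionA, conditionB,
                           direction = c("up", "down"), tau = log2(1.1),
                           alpha = 0.05) {
  new("ComparisonSpec", name = name, conditionA = conditionA,
      conditionB = conditionB, direction = match.arg(direction),
      tau = as.numeric(tau), alpha = as.numeric(alpha))
}

setMethod("show", "ComparisonSpec", function(object) {
  cat(sprintf("ComparisonSpec '%s': %s vs %s, %s, tau = %.4f, alpha = %s\n",
              object@name, object@conditionB, object@conditionA,
              object@direction, object@tau, format(object@alpha)))
})

# ---------------------------------------------------------------------------
# GainRegionSet

#' Called gain-of-6mA regions with provenance
#'
#' The windows surviving every comparison gate and the hypoxia/WGA
#' positivity filter. Each emitted region carries provenance flags (one
#' logical column per filter, all `TRUE` by construction) and the p-value
#' of the first comparison; `stageCounts` records how many windows passed
#' each individual stage before intersection.
#'
#' @slot regions `GRanges` of emitted windows (or merged runs) with
#'   provenance columns in `mcols`.
#' @slot stageCounts named integer vector of per-stage passing counts,
#'   ending in `"final"`.
#' @seealso [callGainRegions()]
#' @export
setClass("GainRegionSet",
         representation(regions = "GRanges", stageCounts = "integer"))

setValidity("GainRegionSet", function(object) {
  flags <- S4Vectors::mcols(object@regions)
  lg <- vapply(seq_len(ncol(flags)), function(i) is.logical(flags[[i]]),
               logical(1))
  if (any(lg)) {
    ok <- vapply(which(lg), function(i) all(flags[[i]]), logical(1))
    if (!all(ok))
      return("every emitted region must have passed all recorded filters")
  }
  TRUE
})

setMethod("show", "GainRegionSet", function(object) {
  cat("GainRegionSet:", length(object@regions), "regions\n")
  sc <- object@stageCounts
  if (length(sc))
    cat("  stages:", paste(names(sc), sc, sep = "=", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GeneModels

#' Gene models for annotation
#'
#' Minimal strand-aware gene models: gene bodies, exons and UTRs as
#' `GRanges` keyed by `gene_id`. The TSS is the 5' end of the gene body
#' (start on `+`, end on `-`).
#'
#' @slot genes `GRanges` with `mcols` column `gene_id` (unique).
#' @slot exons `GRanges` with `mcols` column `gene_id`.
#' @slot utrs `GRanges` with `mcols` column `gene_id`.
#' @seealso [geneModels()], [readGeneModels()], [annotateRegions()]
#' @export
setClass("GeneModels", representation(
  genes = "GRanges", exons = "GRanges", utrs = "GRanges"))

setValidity("GeneModels", function(object) {
  msg <- character()
  gid <- S4Vectors::mcols(object@genes)$gene_id
  if (is.null(gid)) msg <- c(msg, "genes must carry mcols column gene_id")
  else if (anyDuplicated(gid)) msg <- c(msg, "duplicate gene_id in genes")
  for (s in c("exons", "utrs")) {
    part <- slot(object, s)
    pid <- S4Vectors::mcols(part)$gene_id
    if (length(part) && (is.null(pid) || !all(pid %in% gid)))
      msg <- c(msg, sprintf("%s gene_id must exist among genes", s))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname GeneModels-class
#' @param genes,exons,utrs see slots.
#' @return A [GeneModels-class].
#' @export
geneModels <- function(genes, exons = GenomicRanges::GRanges(),
                       utrs = GenomicRanges::GRanges()) {
  if (length(exons) && is.null(S4Vectors::mcols(exons)$gene_id))
    stop("exons need a gene_id column")
  new("GeneModels", genes = genes, exons = exons, utrs = utrs)
}

setMethod("show", "GeneModels", function(object) {
  cat("GeneModels:", length(object@genes), "genes,",
      length(object@exons), "exons,", length(object@utrs), "UTRs\n")
})

# ---------------------------------------------------------------------------
# CalibrationCurve

#' Linear standard curve
#'
#' Ordinary least-squares line `response = slope * amount + intercept`
#' fitted to calibration standards, e.g. MRM peak area against nucleoside
#' amount, or qPCR Ct against log10 template copies.
#'
#' @slot slope,intercept fitted coefficients.
#' @slot r.squared coefficient of determination in [0, 1].
#' @slot analyte label of the calibrated analyte.
#' @slot xUnits,yUnits axis units (documentation only).
#' @slot n number of standard points.
#' @seealso [fitCalibration()]
#' @export
setClass("CalibrationCurve", representation(
  slope = "numeric", intercept = "numeric", r.squared = "numeric",
  analyte = "character", xUnits = "character", yUnits = "character",
  n = "integer"))

setValidity("CalibrationCurve", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "a curve needs >= 2 standard points")
  if (!is.na(object@r.squared) &&
      (object@r.squared < -1e-9 || object@r.squared > 1 + 1e-9))
    msg <- c(msg, "r.squared must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CalibrationCurve", function(object) {
  cat(sprintf(
    "CalibrationCurve [%s]: y = %.6g x + %.6g (R2 = %.4f, n = %d)\n",
    object@analyte, object@slope, object@intercept, object@r.squared,
    object@n))
})
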