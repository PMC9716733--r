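# From per-window counts to gain-of-6mA regions: CPM normalization,
# input-normalized fold-change gates per comparison, hypoxia/WGA positivity
# and cross-comparison intersection.

#' Counts per million
#'
#' @param count non-negative counts (vectorized).
#' @param libSize positive library size(s).
#' @return `count / libSize * 1e6`.
#' @examples
#' cpm(30, 1e6)  # 30
#' @export
cpm <- function(count, libSize) {
  if (any(libSize <= 0)) stop("library size must be positive")
  count / libSize * 1e6
}

# cpm matrix of selected samples of a WindowCounts
.cpmMatrix <- function(wc, samples) {
  y <- counts(wc)[, samples, drop = FALSE]
  sweep(y, 2, libSizes(wc)[samples], "/") * 1e6
}

# row means of cpm over the samples of a condition/track
.meanCpm <- function(wc, condition, track) {
  sh <- sampleSheet(wc)
  j <- which(sh$condition == condition & sh$track == track)
  if (!length(j))
    stop(sprintf("no '%s' samples for condition '%s' in the sample sheet",
                 track, condition))
  rowMeans(.cpmMatrix(wc, j))
}

#' Input-normalized log2 fold enrichment
#'
#' `log2((signal + pseudo) / (input + pseudo))` on the CPM scale; replicate
#' CPM values are averaged within condition before the ratio is taken. The
#' pseudo-count (default 1 CPM) keeps the ratio bounded at zero coverage:
#' with both sides zero the value is exactly 0.
#'
#' @param signalCpm,inputCpm non-negative CPM values (vectorized).
#' @param pseudo pseudo-count in CPM units, added to both sides.
#' @return Input-normalized log2 ratio.
#' @examples
#' inputNormalizedLog2FC(44, 20)  # log2(45/21) ~ 1.0995
#' @export
inputNormalizedLog2FC <- function(signalCpm, inputCpm, pseudo = 1) {
  if (any(signalCpm < 0) || any(inputCpm < 0))
    stop("CPM values must be non-negative")
  log2((signalCpm + pseudo) / (inputCpm + pseudo))
}

#' Run one differential 6mA comparison over windows
#'
#' Exact-test p-values come from the raw signal counts of the two
#' conditions (library-size equalized, common dispersion estimated by qCML
#' within the comparison); input normalization enters the fold-change gate
#' only. The input-normalized log2 fold change is
#' `inorm(conditionB) - inorm(conditionA)`, each condition normalized by
#' its own matched input track. A window passes when the fold change clears
#' `tau` in the spec's direction and (if `alpha` is set) `p < alpha`.
#'
#' @param wc a [WindowCounts-class] with `signal` and `input` tracks for
#'   both conditions of `spec`.
#' @param spec a [ComparisonSpec-class].
#' @param phi optional common dispersion; estimated from the comparison's
#'   signal samples when `NULL`.
#' @param pseudo pseudo-count (CPM) of the input normalization.
#' @return `data.frame` with one row per window: mean signal/input CPM per
#'   condition, input-normalized values, `delta`, `p`, and `passed`.
#' @seealso [callGainRegions()]
#' @export
runComparison <- function(wc, spec, phi = NULL, pseudo = 1) {
  sh <- sampleSheet(wc)
  for (cond in c(spec@conditionA, spec@conditionB)) {
    if (!any(sh$condition == cond & sh$track == "signal"))
      stop(sprintf("no signal samples for condition '%s'", cond))
    if (!any(sh$condition == cond & sh$track == "input"))
      stop(sprintf("missing input track for condition '%s'", cond))
  }
  jA <- which(sh$condition == spec@conditionA & sh$track == "signal")
  jB <- which(sh$condition == spec@conditionB & sh$track == "signal")
  y <- counts(wc)[, c(jA, jB), drop = FALSE]
  grp <- rep(c("A", "B"), c(length(jA), length(jB)))
  ls <- libSizes(wc)[c(jA, jB)]
  if (is.null(phi)) phi <- dispersion(estimateCommonDispersion(y, grp, ls))
  eq <- equalizeLibSizes(y, grp, ls, phi)
  et <- exactTestNB(eq$pseudo[, grp == "A", drop = FALSE],
                    eq$pseudo[, grp == "B", drop = FALSE], phi)
  inormA <- inputNormalizedLog2FC(.meanCpm(wc, spec@conditionA, "signal"),
                                  .meanCpm(wc, spec@conditionA, "input"),
                                  pseudo)
  inormB <- inputNormalizedLog2FC(.meanCpm(wc, spec@conditionB, "signal"),
                                  .meanCpm(wc, spec@conditionB, "input"),
                                  pseudo)
  delta <- inormB - inormA
  passed <- if (spec@direction == "up") delta > spec@tau else
    delta < -spec@tau
  if (!is.na(spec@alpha)) passed <- passed & et$p < spec@alpha
  data.frame(window_id = rownames(counts(wc)),
             inormA = inormA, inormB = inormB, delta = delta,
             log2FC_signal = et$log2FC, p = et$p, passed = passed,
             row.names = NULL)
}

#' Hypoxia/WGA-positive windows
#'
#' Windows whose mean hypoxia signal CPM exceeds the mean WGA CPM by more
#' than `tau` on the pseudo-counted log2 scale. Windows inflated in the WGA
#' track (amplification artifacts) fail this filter.
#'
#' @param wc a [WindowCounts-class] carrying a `wga` track.
#' @param signalCondition condition whose signal is compared against WGA
#'   (default `"hypoxia"`).
#' @param pseudo pseudo-count in CPM.
#' @param tau log2 threshold (default `log2(1.1)`).
#' @return Character vector of passing window ids.
#' @export
wgaPositiveWindows <- function(wc, signalCondition = "hypoxia", pseudo = 1,
                               tau = log2(1.1)) {
  sh <- sampleSheet(wc)
  if (!any(sh$track == "wga"))
    stop("no WGA track present in the sample sheet")
  j <- which(sh$track == "wga")
  wgaCpm <- rowMeans(.cpmMatrix(wc, j))
  hypCpm <- .meanCpm(wc, signalCondition, "signal")
  ids <- rownames(counts(wc))
  ids[inputNormalizedLog2FC(hypCpm, wgaCpm, pseudo) > tau]
}

#' Intersect comparisons and the WGA filter into gain-of-6mA regions
#'
#' Emits the windows passing every comparison and the hypoxia/WGA
#' positivity filter. Per-region provenance flags (one column per filter)
#' and per-stage passing counts are recorded. Optionally adjacent emitted
#' windows are merged into maximal runs (off by default; regions are
#' reported at window granularity).
#'
#' @param comparisons named list of comparison tables from
#'   [runComparison()], all over the same window tiling.
#' @param wgaSet character vector of hypoxia/WGA-positive window ids from
#'   [wgaPositiveWindows()].
#' @param windows the window `GRanges` (named by id), e.g.
#'   `rowRanges(wc)`.
#' @param merge merge adjacent emitted windows into maximal runs.
#' @return A [GainRegionSet-class].
#' @examples
#' # see the package vignette for a full pipeline example
#' @export
callGainRegions <- function(comparisons, wgaSet, windows, merge = FALSE) {
  if (!length(comparisons)) stop("at least one comparison is required")
  if (is.null(names(comparisons)))
    names(comparisons) <- paste0("comparison", seq_along(comparisons))
  universe <- comparisons[[1]]$window_id
  for (cmp in comparisons) {
    if (!.sameWindowUniverse(cmp$window_id, universe))
      stop("comparisons are not on the same window tiling")
  }
  if (!.sameWindowUniverse(names(windows), universe))
    stop("windows do not match the comparisons' tiling")
  passSets <- lapply(comparisons, function(cmp) cmp$window_id[cmp$passed])
  emitted <- Reduce(intersect, c(passSets, list(wgaSet)))
  stages <- c(vapply(passSets, length, integer(1)),
              wga_positive = length(wgaSet),
              final = length(emitted))
  regions <- windows[emitted]
  mc <- S4Vectors::DataFrame(row.names = emitted)
  for (nm in names(comparisons))
    mc[[paste0("passed_", nm)]] <- rep(TRUE, length(emitted))
  mc$wga_positive <- rep(TRUE, length(emitted))
  mc$p <- comparisons[[1]]$p[match(emitted, universe)]
  S4Vectors::mcols(regions) <- mc
  if (merge && length(regions)) {
    merged <- GenomicRanges::reduce(GenomicRanges::granges(regions),
                                    min.gapwidth = 1L)
    names(merged) <- .windowIds(merged)
    regions <- merged
  }
  new("GainRegionSet", regions = regions, stageCounts = stages)
}

#' The two comparisons of the hypoxia/knockdown gain design
#'
#' Comparison 1 asks for induction under hypoxia versus normoxia
#' (input-normalized log2 fold change > log2(1.1), exact-test p < 0.05);
#' comparison 2 asks for reversion under methyltransferase knockdown versus
#' control knockdown in hypoxia (fold change < -log2(1.1), p < 0.05).
#'
#' @param tau log2 fold-change threshold for both comparisons.
#' @param alpha p-value gate applied within each comparison (`NA`
#'   disables).
#' @param conditions named character vector mapping the roles `normoxia`,
#'   `hypoxia`, `knockdown`, `control` to condition labels of the sample
#'   sheet.
#' @return Named list of two [ComparisonSpec-class] objects.
#' @export
hypoxiaGainSpecs <- function(tau = log2(1.1), alpha = 0.05,
                             conditions = c(normoxia = "normoxia",
                                            hypoxia = "hypoxia",
                                            knockdown = "hypoxia_kd",
                                            control = "hypoxia_ctrlkd")) {
  list(
    hypoxia_vs_normoxia = comparisonSpec(
      "hypoxia_vs_normoxia", conditions[["normoxia"]],
      conditions[["hypoxia"]], "up", tau, alpha),
    kd_vs_ctrl = comparisonSpec(
      "kd_vs_ctrl", conditions[["control"]], conditions[["knockdown"]],
      "down", tau, alpha))
}
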