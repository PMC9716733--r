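# Synthetic 6mA study generator: toy genome and gene models, NB-distributed
# multi-condition window counts with planted gain-of-6mA windows and WGA
# amplification artifacts, linked expression matrices, promoter peak sets
# and calibration standards -- all with a recorded TruthTable.

#' @importFrom Biostrings DNAString DNAStringSet reverseComplement
NULL

# run expr under a derived sub-seed, restoring the caller's RNG state
.withStreamSeed <- function(seed, stream, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(.subSeed(seed, stream))
  expr
}

.CONDITIONS <- c("normoxia", "hypoxia", "hypoxia_kd", "hypoxia_ctrlkd")
# hypoxic-state conditions; the gain effect appears in those still carrying
# active methyltransferase (hypoxia and control knockdown)
.GAIN_CONDITIONS <- c("hypoxia", "hypoxia_ctrlkd")
.HYPOXIC_CONDITIONS <- c("hypoxia", "hypoxia_kd", "hypoxia_ctrlkd")

# The consensus motifs planted upstream of every TSS, at the TSS-relative
# positions where the pipeline expects to recover them.
.PLANTED_MOTIFS <- list(
  list(motif = "TCGGAAGT", from = -231L),
  list(motif = "ACGTG",    from = -147L))

#' Simulate a toy genome with gene models
#'
#' Builds a genome layout of `nChroms` chromosomes of `chromLength` bp,
#' places genes along each chromosome with approximately `geneSpacing` bp
#' of intergenic space, gene bodies of 2-8 kb split into 2-5 exons with
#' 150-bp UTRs at both transcript ends (genes cover roughly a third of the
#' genome), and draws a random sequence in which the 6mA-site motif
#' `TCGGAAGT` (starting at -231) and the HRE core `ACGTG` (starting at
#' -147) are planted upstream of every TSS. Deterministic under the
#' config seed.
#'
#' @param config a [SimConfig-class].
#' @return List with `layout` (from [genomeLayout()]), `models`
#'   (a [GeneModels-class]) and `genome` (a `DNAStringSet`).
#' @examples
#' sim <- simulateGenome(simConfig(seed = 7))
#' sim$models
#' @export
simulateGenome <- function(config) {
  validObject(config)
  layout <- genomeLayout(paste0("chr", seq_len(config@nChroms)),
                         rep(config@chromLength, config@nChroms))
  .withStreamSeed(config@seed, "genome", {
    geneRows <- list(); exonRows <- list(); utrRows <- list()
    gidx <- 0L
    for (ci in seq_len(nrow(layout))) {
      chrom <- layout$chrom[ci]
      pos <- 1L
      repeat {
        gap <- round(runif(1, 0.5, 1.5) * config@geneSpacing)
        len <- round(runif(1, 2000, 8000))
        gs <- pos + gap
        ge <- gs + len - 1L
        if (ge > layout$length[ci] - 500) break
        gidx <- gidx + 1L
        gid <- sprintf("gene%04d", gidx)
        strand <- sample(c("+", "-"), 1)
        geneRows[[gidx]] <- data.frame(chrom = chrom, start = gs, end = ge,
                                       strand = strand, gene_id = gid)
        # alternating exon/intron segments, first and last are exons
        nEx <- sample(2:5, 1)
        nSeg <- 2L * nEx - 1L
        w <- runif(nSeg, 0.5, 1.5)
        segw <- pmax(400L, as.integer(round(w / sum(w) * len)))
        bnd <- gs + cumsum(c(0L, segw[-nSeg]))
        segEnd <- pmin(bnd + segw - 1L, ge)
        exI <- seq(1L, nSeg, by = 2L)
        ex <- data.frame(chrom = chrom, start = bnd[exI],
                         end = segEnd[exI], strand = strand, gene_id = gid)
        ex <- ex[ex$start <= ex$end, , drop = FALSE]
        ex$end[nrow(ex)] <- ge
        exonRows[[gidx]] <- ex
        # 150-bp UTRs at both transcript ends, inside the terminal exons
        utrRows[[gidx]] <- data.frame(
          chrom = chrom,
          start = c(gs, ge - 149L), end = c(gs + 149L, ge),
          strand = strand, gene_id = gid)
        pos <- ge
      }
    }
    geneDf <- do.call(rbind, geneRows)
    exonDf <- do.call(rbind, exonRows)
    utrDf <- do.call(rbind, utrRows)
    si <- .layoutSeqinfo(layout)
    asGR <- function(df) GenomicRanges::GRanges(
      df$chrom, IRanges::IRanges(df$start, df$end), strand = df$strand,
      gene_id = df$gene_id, seqinfo = si)
    models <- geneModels(asGR(geneDf), asGR(exonDf), asGR(utrDf))
    # random sequence with motifs planted upstream of every TSS
    seqs <- lapply(seq_len(nrow(layout)), function(ci) {
      sample(c("A", "C", "G", "T"), layout$length[ci], replace = TRUE)
    })
    names(seqs) <- layout$chrom
    tss <- tssOf(models)
    gstr <- as.character(GenomicRanges::strand(models@genes))
    gchr <- as.character(GenomicRanges::seqnames(models@genes))
    for (k in seq_along(tss)) {
      for (pm in .PLANTED_MOTIFS) {
        m <- pm$motif; L <- nchar(m)
        if (gstr[k] == "+") {
          # relative position -j maps to genomic tss - j
          at <- tss[k] + pm$from  # upstream-most base
          if (at >= 1) seqs[[gchr[k]]][at:(at + L - 1L)] <-
              strsplit(m, "")[[1]]
        } else {
          at <- tss[k] - pm$from  # genomic position of relative 'from'
          rc <- strsplit(as.character(
            Biostrings::reverseComplement(Biostrings::DNAString(m))),
            "")[[1]]
          if (at - L + 1L >= 1) seqs[[gchr[k]]][(at - L + 1L):at] <- rc
        }
      }
    }
    genome <- Biostrings::DNAStringSet(vapply(seqs, paste0, character(1),
                                              collapse = ""))
    list(layout = layout, models = models, genome = genome)
  })
}

#' Simulate multi-condition window counts with planted effects
#'
#' Tiles the genome into `windowWidth` windows and draws, for every window
#' i and sample s, `count ~ NB(mean = depth * b_i * e_is, dispersion phi)`
#' where `b_i` is a shared log-normal per-window propensity applied to
#' signal, input and WGA tracks alike. The planted gain effect multiplies
#' hypoxic signal tracks that retain the methyltransferase (hypoxia and
#' control knockdown); knockdown reverts it. WGA-artifact windows receive
#' `wgaArtifactEffect` in the WGA track and the smaller
#' `wgaArtifactSignalEffect` bleed-through in hypoxic signal tracks. Gain
#' and artifact sets are disjoint; with `gainEffect = 1` the gain set is
#' behaviourally empty and none is recorded.
#'
#' @param config a [SimConfig-class].
#' @param genome output of [simulateGenome()] (only the layout is used).
#' @return List with `counts` (a [WindowCounts-class]: 4 conditions x
#'   signal/input plus a WGA track, `nReplicates` each) and `truth`
#'   (a [TruthTable-class] with the window table filled in).
#' @export
simulateCounts <- function(config, genome) {
  validObject(config)
  if (config@meanDepth * max(config@gainEffect, config@wgaArtifactEffect) *
      exp(4 * config@inputBiasSd) > 1e9)
    stop("expected counts overflow the supported range")
  windows <- tileWindows(genome$layout, config@windowWidth)
  nwin <- length(windows)
  .withStreamSeed(config@seed, "counts", {
    b <- rlnorm(nwin, 0, config@inputBiasSd)
    nGain <- if (config@gainEffect > 1)
      round(config@gainFraction * nwin) else 0L
    nArt <- round(config@wgaArtifactFraction * nwin)
    gainIdx <- sample.int(nwin, nGain)
    artIdx <- sample(setdiff(seq_len(nwin), gainIdx), nArt)
    isGain <- seq_len(nwin) %in% gainIdx
    isArt <- seq_len(nwin) %in% artIdx
    sheet <- rbind(
      expand.grid(replicate = seq_len(config@nReplicates),
                  track = c("signal", "input"),
                  condition = .CONDITIONS, stringsAsFactors = FALSE),
      expand.grid(replicate = seq_len(config@nReplicates),
                  track = "wga", condition = "common",
                  stringsAsFactors = FALSE))
    sheet <- sheet[, c("condition", "track", "replicate")]
    drawSample <- function(cond, track) {
      e <- rep(1, nwin)
      if (track == "signal") {
        if (cond %in% .GAIN_CONDITIONS) e[isGain] <- config@gainEffect
        if (cond %in% .HYPOXIC_CONDITIONS)
          e[isArt] <- e[isArt] * config@wgaArtifactSignalEffect
      } else if (track == "wga") {
        e[isArt] <- config@wgaArtifactEffect
      }
      mu <- config@meanDepth * b * e
      if (config@dispersion < .PHI_POISSON) rpois(nwin, mu)
      else rnbinom(nwin, mu = mu, size = 1 / config@dispersion)
    }
    mat <- mapply(function(cond, track) drawSample(cond, track),
                  sheet$condition, sheet$track)
    colnames(mat) <- paste0(sheet$condition, ".", sheet$track, ".",
                            sheet$replicate)
    wc <- WindowCounts(mat, windows, sheet)
    truth <- new("TruthTable",
                 windows = data.frame(
                   window_id = names(windows),
                   is_gain = isGain, is_wga_artifact = isArt,
                   effect = ifelse(isGain, config@gainEffect, 1)),
                 genes = data.frame(gene_id = character(),
                                    is_de = logical(),
                                    linked_window = character()))
    list(counts = wc, truth = truth)
  })
}

#' Simulate gene expression linked to planted gain windows
#'
#' Genes whose body or 10-kb upstream promoter overlaps a planted gain
#' window are differentially expressed: their mean is multiplied by
#' `expressionEffect` in hypoxic conditions that retain the
#' methyltransferase, mirroring the 6mA gain design. All other genes stay
#' flat. Counts are NB with the config dispersion; the per-gene baseline is
#' log-normal around 100.
#'
#' @param config a [SimConfig-class].
#' @param genome output of [simulateGenome()].
#' @param truth the [TruthTable-class] from [simulateCounts()]; its gene
#'   table is filled in.
#' @param stream seed stream label, so independent "cell lines" can be
#'   drawn from the same config.
#' @return List with `counts` (gene-level [WindowCounts-class], track
#'   `"rna"`) and `truth` (updated [TruthTable-class]).
#' @export
simulateExpression <- function(config, genome, truth, stream = "expression") {
  models <- genome$models
  g <- models@genes
  windows <- tileWindows(genome$layout, config@windowWidth)
  wt <- windowTruth(truth)
  gainWin <- windows[wt$window_id[wt$is_gain]]
  ext <- .extendUpstream(g, 10000L)
  ov <- GenomicRanges::findOverlaps(ext, gainWin)
  linked <- rep(NA_character_, length(g))
  linked[S4Vectors::queryHits(ov)[!duplicated(S4Vectors::queryHits(ov))]] <-
    names(gainWin)[S4Vectors::subjectHits(ov)[
      !duplicated(S4Vectors::queryHits(ov))]]
  isDe <- !is.na(linked)
  .withStreamSeed(config@seed, stream, {
    base <- rlnorm(length(g), log(100), 0.5)
    sheet <- expand.grid(replicate = seq_len(config@nReplicates),
                         track = "rna", condition = .CONDITIONS,
                         stringsAsFactors = FALSE)
    sheet <- sheet[, c("condition", "track", "replicate")]
    mat <- mapply(function(cond, track) {
      e <- rep(1, length(g))
      if (cond %in% .GAIN_CONDITIONS) e[isDe] <- config@expressionEffect
      mu <- base * e
      if (config@dispersion < .PHI_POISSON) rpois(length(g), mu)
      else rnbinom(length(g), mu = mu, size = 1 / config@dispersion)
    }, sheet$condition, sheet$track)
    ids <- S4Vectors::mcols(g)$gene_id
    colnames(mat) <- paste0(sheet$condition, ".rna.", sheet$replicate)
    gg <- g
    names(gg) <- ids
    wc <- WindowCounts(mat, gg, sheet)
    newTruth <- new("TruthTable", windows = windowTruth(truth),
                    genes = data.frame(gene_id = ids, is_de = isDe,
                                       linked_window = linked))
    list(counts = wc, truth = newTruth)
  })
}

#' Simulate a transcription-factor peak set over DE-gene promoters
#'
#' Half of the differentially expressed genes (rounded up) receive a peak
#' spanning their TSS, emulating direct binding; the rest stay unbound.
#'
#' @param config a [SimConfig-class].
#' @param genome output of [simulateGenome()].
#' @param truth [TruthTable-class] with the gene table filled in.
#' @return List with `peaks` (`GRanges`) and `boundGenes` (character).
#' @export
simulatePeaks <- function(config, genome, truth) {
  gt <- geneTruth(truth)
  de <- gt$gene_id[gt$is_de]
  .withStreamSeed(config@seed, "peaks", {
    bound <- sort(sample(de, ceiling(length(de) / 2)))
    g <- genome$models@genes
    idx <- match(bound, S4Vectors::mcols(g)$gene_id)
    tss <- tssOf(genome$models)[idx]
    minus <- as.character(GenomicRanges::strand(g)[idx]) == "-"
    start <- ifelse(minus, tss - 200L, tss - 500L)
    end <- ifelse(minus, tss + 500L, tss + 200L)
    peaks <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(g)[idx],
      IRanges::IRanges(pmax(start, 1L), end))
    names(peaks) <- paste0("peak_", seq_along(peaks))
    list(peaks = peaks, boundGenes = bound)
  })
}

#' Simulate calibration standards with known truth
#'
#' Generates (i) MRM standard curves for 6mA and dA (peak area linear in
#' the injected amount, relative Gaussian noise) together with sample areas
#' corresponding to a true 6mA/dA ratio of `truePpm`, and (ii) a qPCR
#' standard curve of Ct against log10 template copies (slope -3.3219, one
#' cycle per two-fold dilution) with a sample Ct corresponding to
#' `trueCopiesPerCell` transcripts in `nCells` cells.
#'
#' @param config a [SimConfig-class] (supplies the seed).
#' @param truePpm planted 6mA/dA ratio, ppm.
#' @param msNoiseFrac relative sd of the MRM response noise (>= 0).
#' @param nStandards points per standard curve (>= 2).
#' @param qpcrNoiseSd sd of the Ct noise, cycles (>= 0).
#' @param trueCopiesPerCell planted transcript copies per cell.
#' @param nCells cells in the quantified sample.
#' @return List with elements `ms` (`standards`, `sample`, `truth`) and
#'   `qpcr` (`standards`, `sample_ct`, `truth`).
#' @export
simulateCalibration <- function(config, truePpm = 10, msNoiseFrac = 0.01,
                                nStandards = 6, qpcrNoiseSd = 0.1,
                                trueCopiesPerCell = 46, nCells = 500000) {
  if (nStandards < 2) stop("at least 2 standard points are required")
  if (msNoiseFrac < 0 || qpcrNoiseSd < 0) stop("noise sd must be >= 0")
  .withStreamSeed(config@seed, "calibration", {
    slope6 <- 250; int6 <- 50
    slopeA <- 180; intA <- 100
    noisy <- function(y, frac) y * (1 + rnorm(length(y), 0, frac))
    amt6 <- seq(0.5, 4, length.out = nStandards)
    amtA <- seq(50000, 400000, length.out = nStandards)
    std <- rbind(
      data.frame(analyte = "6mA", amount = amt6,
                 response = noisy(slope6 * amt6 + int6, msNoiseFrac)),
      data.frame(analyte = "dA", amount = amtA,
                 response = noisy(slopeA * amtA + intA, msNoiseFrac)))
    amountDA <- 200000
    amount6 <- truePpm * 1e-6 * amountDA
    smp <- data.frame(
      analyte = c("6mA", "dA"),
      area = c(noisy(slope6 * amount6 + int6, msNoiseFrac),
               noisy(slopeA * amountDA + intA, msNoiseFrac)))
    qSlope <- -3.3219; qInt <- 40
    l10 <- seq(3, 8, length.out = nStandards)
    qstd <- data.frame(
      log10_copies = l10,
      ct = qInt + qSlope * l10 + rnorm(nStandards, 0, qpcrNoiseSd))
    totCopies <- trueCopiesPerCell * nCells
    sampleCt <- qInt + qSlope * log10(totCopies) +
      rnorm(1, 0, qpcrNoiseSd)
    list(
      ms = list(standards = std, sample = smp,
                truth = list(ppm = truePpm, slope6mA = slope6,
                             intercept6mA = int6, slopeDA = slopeA,
                             interceptDA = intA)),
      qpcr = list(standards = qstd, sample_ct = sampleCt,
                  truth = list(copies_per_cell = trueCopiesPerCell,
                               n_cells = nCells, slope = qSlope,
                               intercept = qInt)))
  })
}

#' Simulate a complete synthetic 6mA study
#'
#' Convenience wrapper chaining [simulateGenome()], [simulateCounts()],
#' [simulateExpression()], [simulatePeaks()] and [simulateCalibration()]
#' under one config.
#'
#' @param config a [SimConfig-class].
#' @return List with `config`, `layout`, `models`, `genome`, `counts`,
#'   `expression`, `peaks`, `boundGenes`, `calibration` and `truth`.
#' @examples
#' study <- simulateStudy(simConfig(nChroms = 1, chromLength = 60000L,
#'                                  seed = 3))
#' study$truth
#' @export
simulateStudy <- function(config) {
  genome <- simulateGenome(config)
  cnt <- simulateCounts(config, genome)
  expr <- simulateExpression(config, genome, cnt$truth)
  pk <- simulatePeaks(config, genome, expr$truth)
  calib <- simulateCalibration(config)
  list(config = config, layout = genome$layout, models = genome$models,
       genome = genome$genome, counts = cnt$counts,
       expression = expr$counts, peaks = pk$peaks,
       boundGenes = pk$boundGenes, calibration = calib,
       truth = expr$truth)
}
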