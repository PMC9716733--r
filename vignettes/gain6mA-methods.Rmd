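---
title: "Windowed differential 6mA analysis: models and methods"
author: "gain6mA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed differential 6mA analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gain6mA)
```

# The problem

DNA N6-methyladenine (6mA) in mammalian genomes is rare (parts-per-million
of adenines) and its ChIP-exo signal is low-complexity, so peak-shaped
enrichment models fit poorly. This package instead scores fixed 3-kb
genomic windows: tags are deduplicated, counted per window, and window
counts are compared across conditions with a small-sample
negative-binomial test. The question the pipeline answers is *which
windows gain 6mA under hypoxia in a methyltransferase-dependent way*,
i.e. rise in hypoxia versus normoxia, fall again when the
methyltransferase is knocked down under hypoxia, and are not explained by
amplification or antibody-independent background.

# Counting model

Window counts are modelled as negative binomial,
$y \sim \mathrm{NB}(\mu, \phi)$ with $\mathrm{Var}(y) = \mu + \phi\mu^2$.
The NB accommodates the biological variability between replicate cultures
that a Poisson model would understate. Two assumptions matter:

* **A common dispersion per contrast.** With three replicates per group
  there is little information for per-window dispersions; a single
  $\phi$ estimated across all windows of a comparison is the stabilising
  choice (tagwise or trended shrinkage is deliberately out of scope).
* **Library-size differences are pure scaling.** Column sums serve as
  library sizes. Composition effects (a large one-directional shift in a
  sizeable fraction of windows dragging the column sum) are not corrected
  — the unit tests document this limitation explicitly.

## Quantile equalization

The conditional-likelihood machinery below requires exchangeable
replicates, i.e. equal library sizes. Counts are therefore mapped to a
common pseudo-library $N^*$, the geometric mean of the observed library
sizes. For a count $y$ with estimated per-sample mean $\mu_s$ (group
total divided by summed group library sizes, scaled by $N_s$), the
mapping averages the left- and right-continuity percentiles of the
discrete CDF,

$$p_{\text{mid}} = \tfrac12\left[F(y-1;\mu_s,\phi) + F(y;\mu_s,\phi)\right],$$

and inverts at the target distribution:
$\tilde y = F^{-1}(p_{\text{mid}};\ \mu^{*},\phi)$ with
$\mu^{*}$ the same per-unit mean rescaled to $N^*$. The mid-percentile
form makes the mapping exactly the identity when library sizes are
already equal (including $y = 0$), keeps pseudo-counts non-negative and
monotone in the input count, and quantizes to integers — appropriate,
since the exact test conditions on integer totals. At $\phi = 0$ the
mapping passes through Poisson quantiles.

## Common dispersion (qCML)

For one unit's replicate vector $y$ in one group with equalized library
sizes, the likelihood of $\phi$ conditional on the total $z = \sum_i y_i$
is, dropping $\phi$-free terms,

$$\ell(\phi) = \sum_i \ln\Gamma(y_i + \phi^{-1}) + \ln\Gamma(n\phi^{-1})
 - \ln\Gamma(z + n\phi^{-1}) - n\ln\Gamma(\phi^{-1}).$$

`estimateCommonDispersion()` maximizes the sum of $\ell(\phi)$ over
units and groups with Brent search on $\log\phi$ over
$[10^{-6}, 10]$, in two passes: equalize through Poisson quantiles,
maximize, re-equalize at the estimate, maximize again, then stop. The
procedure is fully deterministic; the boundary values are explicitly
compared against the interior optimum so Poisson-like data honestly
report the floor. With one replicate $\ell$ is identically zero
(conditioning on the total leaves no information), and as
$\phi \to 0^+$ it approaches the multinomial limit $-z\ln n$. Units with
all-zero counts carry no information and are dropped before estimation.

## The exact test

Under $H_0$ of equal means, the equalized group totals are
$S_A \sim \mathrm{NB}(n_A\hat\mu N^*,\ n_A/\phi)$ and likewise $S_B$.
The two-sided *doubletail* p-value enumerates all partitions
$a + b = s_{\text{obs}}$ and sums the probabilities
$P(S_A = a)P(S_B = b)$ that do not exceed the observed one, normalized
by the total over all partitions. Numerical choices:

* ties with the observed probability are included within $10^{-12}$
  relative tolerance (evaluated on the log scale);
* probabilities are accumulated from log densities after subtracting the
  maximum, so long enumerations do not underflow;
* $\phi < 10^{-12}$ switches to Poisson densities, whose conditional is
  the binomial — the analytic small-dispersion limit;
* a unit with $s_{\text{obs}} = 0$ returns $p = 1$ and
  $\log_2\mathrm{FC} = 0$ by convention;
* fold changes use per-replicate group means with a pseudo-fraction of
  0.125 per side, so zero counts never produce infinite ratios.

The test suite checks the implementation against an independent
enumeration oracle (sort/cumsum thresholding, a different algorithm) over
every replicate configuration $n_A, n_B \in \{1,2,3\}$, and against
`edgeR`'s doubletail on shared inputs. `edgeR` — the tool the window
strategy descends from — is used only as a cross-check, never as the
implementation.

# The gain-region decision rule

Per comparison (`runComparison()`):

* the **p-value** comes from the exact test on the raw signal counts of
  the two conditions (library-size equalized);
* the **fold gate** uses input-normalized values: replicate CPM averaged
  within condition, then
  $\mathrm{inorm}(c) = \log_2\frac{\overline{\mathrm{cpm}}_{\text{signal}}(c) + 1}
  {\overline{\mathrm{cpm}}_{\text{input}}(c) + 1}$,
  and $\Delta = \mathrm{inorm}(B) - \mathrm{inorm}(A)$ compared against
  $\tau = \log_2 1.1 \approx 0.1375$.

Input normalization enters only the fold gate, not the test: the input
track measures position-specific background that shifts the *level* of
enrichment, while replicate-to-replicate count noise — what the p-value
must calibrate against — lives in the signal counts themselves. An
input-as-offset testing mode was considered and rejected as it conflates
the two roles; the ordering of normalization and testing is genuinely
underdetermined in the field's descriptions of this design, and this
split is the package's documented choice.

Each comparison applies both its fold threshold and its own p-gate
(`alpha = 0.05` by default); passing `alpha = NA` restores a fold-only
gate for analysts who prefer to gate significance on a single contrast.
The hypoxia/WGA filter is a fold-only gate by construction (WGA tracks
are unreplicated background), using the same pseudo-counted CPM
log-ratio and threshold. `callGainRegions()` intersects all passing
sets, records per-region provenance flags and per-stage counts, and by
default reports regions at window granularity (merging adjacent windows
into maximal runs is available but off, so region counts remain
window-based).

The 1 CPM pseudo-count in all log-ratios bounds every ratio at zero
coverage; with both sides zero the log-ratio is exactly 0, which no gate
passes. Raw p-values are gated at 0.05; Benjamini–Hochberg adjustment is
available behind `fdr = TRUE` in `callDE()` but off by default, matching
the window pipeline's raw-p design.

# Annotation, motifs, profiles

`annotateRegions()` classifies each region by its **midpoint** — a 3-kb
window can span several features, and the midpoint gives the single-label
contract a deterministic answer — with precedence
proximal promoter > distal promoter > UTR > exon > intron > intergenic.
Promoter windows are measured upstream of the TSS on the coding strand:
proximal $(TSS-1000,\ TSS]$, distal $(TSS-10000,\ TSS-1000]$; both
distances are configurable since annotation tools differ here. Ties
between equidistant genes break lexicographically by gene id, so output
is reproducible.

`scanMotif()` reports exact IUPAC-consensus matches in TSS-relative
coordinates with $-1$ the base immediately upstream of the TSS, $+1$ the
TSS itself, and inclusive ranges — the convention in which the planted
6mA site `TCGGAAGT` spans $-231..-224$ and the HRE core `ACGTG` spans
$-147..-143$. For minus-strand genes the reverse complement of the motif
is located in plus-strand sequence and coordinates are reported in gene
orientation. `tssProfile()` bins strand-oriented tag offsets into
fixed-width bins over $\pm$flank and averages per-bp density over genes;
because bins are half-open, exact strand-mirror symmetry holds for
offsets away from bin edges, which is how the tests probe it.

# Calibration

Both quantifications are linear standard curves fitted by ordinary least
squares with a free intercept (through-origin is available by flag, but a
free intercept absorbs instrument offsets and is the default).

* **6mA/dA ppm:** each analyte's MRM peak area is inverted through its
  own curve; $\mathrm{ppm} = \mathrm{amount}_{6mA} /
  \mathrm{amount}_{dA} \times 10^6$. A 6mA amount inverting at or below
  zero is clamped to 0 and flagged below the limit of detection rather
  than erroring — undetectable baseline levels are an expected outcome,
  not a failure. The flag's zero threshold carries a float-scale epsilon
  so an area exactly at the fitted intercept is recognized as zero.
* **Copies per cell:** the qPCR curve is Ct against $\log_{10}$ template
  copies (standard absolute-quantification practice); the sample Ct
  inverts to total copies $10^{(ct - b)/m}$, divided by the number of
  cells (500,000 by default).

# What the generator emulates — and what it does not

`simConfig()` defaults are the study conditions under which every
recovery claim in the test suite is made:

| parameter | default | rationale |
|---|---|---|
| `windowWidth` | 3000 bp | the pipeline's 3-kb windows |
| `nReplicates` | 3 | three hypoxia replicates enter each comparison |
| `meanDepth` | 50 tags/window | adequately powered but realistic coverage |
| `dispersion` | 0.02 | BCV ≈ 0.14, typical of replicate cell-line cultures |
| `gainFraction`, `gainEffect` | 0.02, 2.0 | sparse planted gains at two-fold |
| `wgaArtifactEffect` | 3.0 (WGA track) | amplification bias is strongest in the amplified material |
| `wgaArtifactSignalEffect` | 1.5 (hypoxic signal) | partial bleed-through that makes the artifact look like a spurious gain |
| `inputBiasSd` | 0.2 | log-normal per-window propensity shared by signal, input and WGA |

Counts are drawn as
$y \sim \mathrm{NB}(\text{depth} \cdot b_i \cdot e_{is},\ \phi)$ with a
shared per-window propensity $b_i$ — the minimal structure under which
input normalization is meaningful. The gain effect multiplies hypoxic
signal tracks that retain the methyltransferase (hypoxia and control
knockdown); knockdown reverts it. WGA-artifact folds are asymmetric by
design: a symmetric fold would centre the hypoxia/WGA log-ratio at zero
and the filter could only ever exclude artifacts at the noise rate,
whereas amplification bias concentrated in the WGA track is both the
phenomenon the control exists to catch and what makes the filter's job
well-posed. Gain and artifact window sets are disjoint by construction.
One master seed drives deterministically derived per-stream sub-seeds
(genome, counts, expression, peaks, calibration), so identical configs
give byte-identical outputs while streams stay independent.

The generator does **not** emulate read-level sequence errors, fragment
lengths, mappability, copy-number variation, GC effects, or the spatial
autocorrelation of real ChIP background. Passing recovery tests
therefore demonstrates that the statistical machinery is correct and
well-calibrated under the stated NB model — not that real 6mA ChIP-exo
data satisfy that model.

# Problem sizes and numerical settings in the validation suite

The validation suite runs at sizes chosen to make sampling error small
relative to the tolerances while staying quick on a single CPU: 5000
windows for the end-to-end spike-in and null-calibration checks, 2000
windows for dispersion recovery (means spanning roughly 20–200,
$\phi = 0.2$), $10^5$ tags for counting conservation, 1000 random regions
for the annotation oracle, and ten independently seeded generator runs
for the stochastic calibration recoveries (averaging removes the
single-draw sampling noise, which at 0.1-cycle Ct noise exceeds the 5%
recovery band being checked). The dispersion search tolerance is
$10^{-8}$ on $\log\phi$; doubletail tie tolerance $10^{-12}$ relative;
annotation fraction normalization $10^{-9}$.

# Known limitations

* Column-sum library sizes are vulnerable to composition bias under
  strong one-directional differential signal; no TMM-style correction is
  applied.
* A single common dispersion can under- or over-state the variability of
  individual windows; p-values are calibrated on average, not per window.
* Midpoint annotation assigns one label to windows that genuinely span
  feature boundaries.
* The exact test requires integer totals; the quantile equalization's
  integer rounding discards sub-integer information, a deliberate trade
  for exactness of the conditional reference distribution.
* Replicate-selection QC (choosing which replicates enter a comparison)
  is upstream of this package: the sample sheet is taken as given.
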