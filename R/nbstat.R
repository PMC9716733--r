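# Negative-binomial small-sample inference: conditional likelihood for the
# common dispersion, quantile-based library-size equalization, and the
# two-sided ("doubletail") exact test. This core serves both window-level
# 6mA testing and gene-level differential expression.

#' @importFrom stats pnbinom qnbinom dnbinom ppois qpois dpois optimize
#'   rnbinom rpois rlnorm runif rnorm lm coef residuals p.adjust
NULL

# Dispersions below this are treated as Poisson in density/quantile work;
# dnbinom/qnbinom lose accuracy once size = 1/phi overflows usefully.
.PHI_POISSON <- 1e-12

#' Conditional log-likelihood of the common dispersion for one group
#'
#' For replicate counts `y` of a single group with equalized library sizes,
#' the log-likelihood of the dispersion `phi` conditional on the group total
#' `z = sum(y)` is
#' \deqn{\ell(\phi) = \sum_i \ln\Gamma(y_i + 1/\phi) + \ln\Gamma(n/\phi)
#'   - \ln\Gamma(z + n/\phi) - n \ln\Gamma(1/\phi),}
#' terms constant in `phi` omitted. With a single replicate the conditional
#' likelihood carries no information and the function is identically zero.
#' As `phi` tends to 0 the value approaches the Poisson conditional
#' (multinomial) limit `-z log(n)` (again up to phi-free constants), which
#' is what `phi = 0` returns.
#'
#' @param y non-negative counts of one group (vector), or a units x
#'   replicates matrix for a per-unit vectorized evaluation.
#' @param phi dispersion, >= 0.
#' @return Scalar log-likelihood (vector input) or per-unit vector (matrix
#'   input).
#' @examples
#' condLogLik(c(3, 5), 0.5)   # about -5.953
#' @export
condLogLik <- function(y, phi) {
  .assertScalarNumber(phi, "phi", lower = 0)
  if (is.null(dim(y))) y <- matrix(y, nrow = 1L)
  n <- ncol(y)
  z <- rowSums(y)
  if (phi < .PHI_POISSON) {
    ll <- -z * log(n)
  } else {
    r <- 1 / phi
    ll <- rowSums(lgamma(y + r)) + lgamma(n * r) - lgamma(z + n * r) -
      n * lgamma(r)
  }
  if (length(ll) == 1L) ll <- as.numeric(ll)
  ll
}

# Mid-quantile CDF mapping of one count vector from NB(muIn, phi) to
# NB(muOut, phi): average the left- and right-continuity percentiles of the
# observed count, then invert at the target distribution. Exactly the
# identity when muIn == muOut.
.q2qCount <- function(y, muIn, muOut, phi) {
  if (phi < .PHI_POISSON) {
    pmid <- (ppois(y - 1, muIn) + ppois(y, muIn)) / 2
    qpois(pmin(pmid, 1 - 1e-15), muOut)
  } else {
    size <- 1 / phi
    pmid <- (pnbinom(y - 1, size = size, mu = muIn) +
             pnbinom(y, size = size, mu = muIn)) / 2
    qnbinom(pmin(pmid, 1 - 1e-15), size = size, mu = muOut)
  }
}

#' Equalize library sizes by negative-binomial quantile mapping
#'
#' Maps every count to the equivalent quantile of the same NB distribution
#' rescaled to the common pseudo-library `N*` (the geometric mean of the
#' library sizes). Each count's left- and right-continuity percentiles are
#' averaged before inversion, so equal library sizes reproduce the original
#' counts exactly. Per-unit means are estimated within each group as the
#' group total divided by the summed group library sizes.
#'
#' @param y integer count matrix, units x samples.
#' @param group factor/character of length `ncol(y)`.
#' @param libSizes positive library sizes, length `ncol(y)`.
#' @param phi common dispersion used for the mapping (>= 0; 0 maps through
#'   Poisson quantiles).
#' @return List with `pseudo` (matrix of pseudo-counts on the `N*` scale)
#'   and `pseudoLib` (the common library size `N*`).
#' @examples
#' y <- matrix(c(10L, 20L, 12L, 18L), 2)
#' equalizeLibSizes(y, c("a", "a"), c(1e6, 1e6), phi = 0.1)$pseudo
#' @export
equalizeLibSizes <- function(y, group, libSizes, phi) {
  y <- as.matrix(y)
  if (any(libSizes <= 0)) stop("library sizes must be positive")
  if (length(libSizes) != ncol(y) || length(group) != ncol(y))
    stop("group and libSizes must match the number of samples")
  .assertScalarNumber(phi, "phi", lower = 0)
  nstar <- exp(mean(log(libSizes)))
  pseudo <- y * 0
  for (g in unique(group)) {
    j <- which(group == g)
    lambda <- rowSums(y[, j, drop = FALSE]) / sum(libSizes[j])
    for (s in j) {
      pseudo[, s] <- .q2qCount(y[, s], lambda * libSizes[s],
                               lambda * nstar, phi)
    }
  }
  list(pseudo = pseudo, pseudoLib = nstar)
}

# Maximize the summed conditional log-likelihood over units and groups on
# log(phi) within [lower, upper].
.maximizeCondLik <- function(pseudo, group, lower = 1e-6, upper = 10) {
  groups <- unique(group)
  obj <- function(lphi) {
    phi <- exp(lphi)
    sum(vapply(groups, function(g) {
      sum(condLogLik(pseudo[, group == g, drop = FALSE], phi))
    }, numeric(1)))
  }
  # include the boundaries: optimize() never returns an endpoint
  opt <- optimize(obj, interval = log(c(lower, upper)),
                  maximum = TRUE, tol = 1e-8)
  cand <- c(exp(opt$maximum), lower, upper)
  ll <- c(opt$objective, obj(log(lower)), obj(log(upper)))
  i <- which.max(ll)
  list(phi = cand[i], logLik = ll[i])
}

#' Estimate the common dispersion by quantile-adjusted conditional ML
#'
#' Two-pass qCML: counts are first equalized to the common pseudo-library
#' through Poisson quantiles, the conditional likelihood is maximized for
#' the common dispersion, the equalization is repeated at that estimate,
#' and the likelihood is maximized once more. The search is a bounded
#' golden-section/Brent maximization on log(phi) within [1e-6, 10] and is
#' fully deterministic.
#'
#' @param y integer count matrix, units x samples. Units with zero counts
#'   across all samples carry no conditional information and are dropped.
#' @param group factor/character of sample group labels; at least one group
#'   needs two or more replicates.
#' @param libSizes library sizes; defaults to column sums.
#' @return A [DispersionEstimate-class].
#' @examples
#' set.seed(1)
#' y <- matrix(rnbinom(600, mu = 50, size = 10), 100)
#' dispersion(estimateCommonDispersion(y, rep(c("a", "b"), each = 3)))
#' @export
estimateCommonDispersion <- function(y, group,
                                     libSizes = colSums(as.matrix(y))) {
  y <- as.matrix(y)
  group <- as.character(group)
  if (max(table(group)) < 2L)
    stop("at least one group needs >= 2 replicates")
  keep <- rowSums(y) > 0
  if (!any(keep)) stop("no information for dispersion: all units are zero")
  y <- y[keep, , drop = FALSE]
  eq <- equalizeLibSizes(y, group, libSizes, phi = 0)
  fit <- .maximizeCondLik(eq$pseudo, group)
  eq <- equalizeLibSizes(y, group, libSizes, phi = fit$phi)
  fit <- .maximizeCondLik(eq$pseudo, group)
  new("DispersionEstimate", phi = fit$phi, pseudoLib = eq$pseudoLib,
      logLik = fit$logLik, nPasses = 2L)
}

# Doubletail p for one unit given group-total pseudo-counts. sA, sB are
# (rounded) totals, nA, nB replicate numbers. Under H0 the group totals are
# NB with means nA*m0 and nB*m0 (m0 = common per-sample mean) and sizes
# nA/phi and nB/phi; the p-value sums, over all partitions a + b = s, the
# probabilities no larger than the observed one (ties included within 1e-12
# relative), normalized by the total over all partitions.
.doubletailP <- function(sA, sB, nA, nB, phi) {
  s <- sA + sB
  if (s == 0) return(1)
  m0 <- s / (nA + nB)
  a <- 0:s
  if (phi < .PHI_POISSON) {
    lpA <- dpois(a, lambda = nA * m0, log = TRUE)
    lpB <- dpois(s - a, lambda = nB * m0, log = TRUE)
  } else {
    lpA <- dnbinom(a, size = nA / phi, mu = nA * m0, log = TRUE)
    lpB <- dnbinom(s - a, size = nB / phi, mu = nB * m0, log = TRUE)
  }
  joint <- lpA + lpB
  mx <- max(joint)
  w <- exp(joint - mx)
  keep <- joint <= joint[sA + 1] + 1e-12
  min(1, sum(w[keep]) / sum(w))
}

#' Two-group negative-binomial exact test
#'
#' Exact doubletail test on library-size-equalized pseudo-counts. For each
#' unit the two group totals are compared against their conditional null
#' distribution (NB totals with a common mean and sizes `n/phi`); the
#' two-sided p-value aggregates all partitions of the observed total whose
#' probability does not exceed that of the observed split. The log2 fold
#' change is computed from the per-replicate group means with a
#' pseudo-fraction of 0.125 added to each side; a unit with total zero gets
#' `p = 1` and `log2FC = 0` by convention.
#'
#' @param yA,yB pseudo-count matrices (units x replicates) of groups A and
#'   B, already on a common library scale (see [equalizeLibSizes()]).
#'   Vectors are treated as single-unit groups.
#' @param phi common dispersion (>= 0; 0 gives the conditional binomial
#'   limit).
#' @return `data.frame` with columns `log2FC` (B vs A) and `p`.
#' @examples
#' exactTestNB(c(0), c(10), phi = 1e-8)  # p = 2/1024
#' @export
exactTestNB <- function(yA, yB, phi) {
  if (is.null(dim(yA))) yA <- matrix(yA, nrow = 1L)
  if (is.null(dim(yB))) yB <- matrix(yB, nrow = 1L)
  if (nrow(yA) != nrow(yB)) stop("yA and yB must have the same units")
  .assertScalarNumber(phi, "phi", lower = 0)
  nA <- ncol(yA); nB <- ncol(yB)
  sA <- round(rowSums(yA)); sB <- round(rowSums(yB))
  p <- vapply(seq_along(sA), function(i) {
    .doubletailP(sA[i], sB[i], nA, nB, phi)
  }, numeric(1))
  log2FC <- log2((sB / nB + 0.125) / (sA / nA + 0.125))
  data.frame(log2FC = log2FC, p = p)
}

#' Call differentially expressed units with fold-change and p-value gates
#'
#' Full small-sample NB pipeline for a two-group contrast: estimate the
#' common dispersion by qCML, equalize library sizes at the estimate, run
#' the exact test per unit, and flag units passing the default gates of
#' 1.3-fold change (either direction) and p < 0.05.
#'
#' @param y integer count matrix, units x samples (rownames are unit ids).
#' @param group sample group labels (exactly two distinct values).
#' @param contrast character of length 2, `c(A, B)`: the test and fold
#'   change are B vs A. Defaults to the order of first appearance.
#' @param libSizes library sizes; defaults to column sums.
#' @param fcThreshold fold-change gate on the natural scale (default 1.3).
#' @param pThreshold p-value gate (default 0.05).
#' @param fdr if `TRUE`, gate on Benjamini-Hochberg adjusted p-values
#'   instead of raw p-values (off by default; the region pipeline gates on
#'   raw p).
#' @return `data.frame` with `id`, `log2FC`, `p` (plus `padj` when
#'   `fdr = TRUE`) and `flag` in `c("up", "down", "ns")`.
#' @examples
#' set.seed(1)
#' y <- matrix(rnbinom(300, mu = 60, size = 20), 50)
#' de <- callDE(y, rep(c("ctrl", "trt"), each = 3))
#' table(de$flag)
#' @export
callDE <- function(y, group, contrast = NULL,
                   libSizes = colSums(as.matrix(y)),
                   fcThreshold = 1.3, pThreshold = 0.05, fdr = FALSE) {
  y <- as.matrix(y)
  group <- as.character(group)
  lev <- unique(group)
  if (length(lev) != 2L) stop("exactly two groups are required")
  if (is.null(contrast)) contrast <- lev
  if (!all(contrast %in% lev))
    stop("unknown group labels in contrast: ",
         paste(setdiff(contrast, lev), collapse = ", "))
  ids <- rownames(y)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(y)))
  disp <- estimateCommonDispersion(y, group, libSizes)
  phi <- dispersion(disp)
  eq <- equalizeLibSizes(y, group, libSizes, phi)
  a <- eq$pseudo[, group == contrast[1], drop = FALSE]
  b <- eq$pseudo[, group == contrast[2], drop = FALSE]
  res <- exactTestNB(a, b, phi)
  pgate <- if (fdr) {
    res$padj <- stats::p.adjust(res$p, method = "BH")
    res$padj
  } else res$p
  tau <- log2(fcThreshold)
  flag <- ifelse(pgate < pThreshold & res$log2FC > tau, "up",
                 ifelse(pgate < pThreshold & res$log2FC < -tau, "down",
                        "ns"))
  cbind(data.frame(id = ids), res, flag = flag)
}
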