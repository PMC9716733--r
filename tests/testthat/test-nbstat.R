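test_that("conditional log-likelihood matches direct lgamma arithmetic", {
  # independent evaluation of the conditional likelihood for y = c(3, 5)
  y <- c(3, 5); phi <- 0.5; r <- 1 / phi; n <- 2; z <- sum(y)
  direct <- sum(lgamma(y + r)) + lgamma(n * r) - lgamma(z + n * r) -
    n * lgamma(r)
  expect_equal(condLogLik(y, phi), direct)
  expect_equal(condLogLik(y, phi), -5.95324, tolerance = 1e-5)
})

test_that("single-sample conditional likelihood carries no information", {
  for (phi in c(0.01, 0.5, 3)) {
    expect_equal(condLogLik(17, phi), 0, tolerance = 1e-10)
  }
})

test_that("phi -> 0 approaches the multinomial conditional limit", {
  y <- c(4, 9, 2)
  limit <- -sum(y) * log(3)  # equiprobable multinomial, phi-free terms off
  expect_equal(condLogLik(y, 1e-9), limit, tolerance = 1e-4)
  expect_equal(condLogLik(y, 0), limit)
})

test_that("equalization is the identity at equal library sizes", {
  set.seed(41)
  y <- matrix(rnbinom(60, mu = 30, size = 5), 10)
  eq <- equalizeLibSizes(y, rep(c("a", "b"), each = 3), rep(1e6, 6),
                         phi = 0.2)
  expect_equal(eq$pseudo, y + 0)
  expect_equal(eq$pseudoLib, 1e6)
})

test_that("doubling a library size halves the pseudo-count within the quantile step", {
  # one unit, two samples of the same group; N* = sqrt(2) * 1e6
  y <- matrix(c(200L, 100L), 1)
  eq <- equalizeLibSizes(y, c("a", "a"), c(2e6, 1e6), phi = 0.1)
  lambda <- 300 / 3e6  # both samples map near lambda * N*
  expect_lt(abs(eq$pseudo[1] - lambda * eq$pseudoLib), 8)
  expect_lt(abs(eq$pseudo[2] - lambda * eq$pseudoLib), 8)
  # direct NB quantile cross-check for the first sample
  size <- 10
  pmid <- (pnbinom(199, size = size, mu = lambda * 2e6) +
           pnbinom(200, size = size, mu = lambda * 2e6)) / 2
  expect_equal(eq$pseudo[1],
               qnbinom(pmid, size = size, mu = lambda * eq$pseudoLib))
})

test_that("pseudo-counts are non-negative and monotone in the input count", {
  for (phi in c(0, 0.05, 0.7)) {
    y <- matrix(c(0:40, rep(15L, 41)), ncol = 2)
    eq <- equalizeLibSizes(y, c("a", "a"), c(1.7e6, 0.9e6), phi)
    expect_true(all(eq$pseudo >= 0))
    expect_true(all(diff(eq$pseudo[, 1]) >= 0))
  }
})

test_that("exact test equals enumeration and is symmetric", {
  set.seed(7)
  for (rep in 1:40) {
    nA <- sample(1:3, 1); nB <- sample(1:3, 1)
    phi <- sample(c(0, 0.05, 0.4, 1.5), 1)
    s <- sample(0:120, 1); sA <- sample(0:s, 1)
    yA <- c(sA, rep(0, nA - 1)); yB <- c(s - sA, rep(0, nB - 1))
    got <- exactTestNB(yA, yB, phi)
    expect_equal(got$p, oracleDoubletailAll(s, nA, nB, phi)[sA + 1],
                 tolerance = 1e-12)
    swapped <- exactTestNB(yB, yA, phi)
    expect_equal(swapped$p, got$p, tolerance = 1e-12)
    expect_equal(swapped$log2FC, -got$log2FC, tolerance = 1e-12)
    expect_gt(got$p, 0)
    expect_lte(got$p, 1)
  }
})

test_that("balanced splits and zero totals take their conventional values", {
  expect_equal(exactTestNB(2, 2, 1e-8)$p, 1)
  r0 <- exactTestNB(c(0, 0), c(0, 0), 0.3)
  expect_equal(r0$p, 1)
  expect_equal(r0$log2FC, 0)
})

test_that("exact test agrees with edgeR's doubletail on shared inputs", {
  skip_if_not_installed("edgeR")
  set.seed(11)
  y1 <- matrix(rnbinom(200, mu = 40, size = 8), 100)
  y2 <- matrix(rnbinom(200, mu = 40, size = 8), 100)
  phi <- 0.15
  ours <- exactTestNB(y1, y2, phi)$p
  theirs <- edgeR::exactTestDoubleTail(y1, y2, dispersion = phi)
  expect_equal(ours, theirs, tolerance = 1e-6)
})

test_that("common dispersion is recovered and identical-unit additivity holds", {
  set.seed(5)
  mu <- runif(2000, 20, 200)
  y <- matrix(rnbinom(2000 * 6, mu = rep(mu, 6), size = 1 / 0.2), 2000)
  est <- estimateCommonDispersion(y, rep(c("a", "b"), each = 3))
  expect_lt(abs(dispersion(est) - 0.2), 0.05)
  # Poisson data pushes the estimate to the lower boundary
  yp <- matrix(rpois(2000 * 6, rep(mu, 6)), 2000)
  estP <- estimateCommonDispersion(yp, rep(c("a", "b"), each = 3))
  expect_lte(dispersion(estP), 0.01)
  # duplicating one unit 100x leaves the maximizer unchanged (likelihood
  # additivity); unit chosen so the maximum is interior to the search range
  one <- matrix(c(2L, 8L, 3L, 7L), 1)
  grp <- c("a", "a", "b", "b")
  ls <- rep(1e5, 4)
  e1 <- estimateCommonDispersion(one, grp, ls)
  e100 <- estimateCommonDispersion(one[rep(1, 100), ], grp, ls)
  expect_gt(dispersion(e1), 0.01)
  expect_equal(dispersion(e1), dispersion(e100), tolerance = 1e-6)
})

test_that("dispersion estimate roughly matches edgeR's qCML on the same data", {
  skip_if_not_installed("edgeR")
  set.seed(9)
  y <- matrix(rnbinom(1200 * 6, mu = 60, size = 1 / 0.1), 1200)
  grp <- rep(c("a", "b"), each = 3)
  ours <- dispersion(estimateCommonDispersion(y, grp))
  d <- edgeR::estimateCommonDisp(edgeR::DGEList(y, group = grp))
  expect_lt(abs(ours - d$common.dispersion), 0.02)
})

test_that("callDE applies the 1.3-fold and p gates and is replicate-order invariant", {
  set.seed(21)
  # balanced planted effects (20 up, 20 down at 3x) and explicit library
  # sizes: column sums would carry the composition bias of the planted
  # effects, which library-size normalization alone cannot remove
  mu <- rep(50, 400)
  mu[1:20] <- 150; mu[21:40] <- 50 / 3
  yA <- matrix(rnbinom(400 * 3, mu = 50, size = 50), 400)
  yB <- matrix(rnbinom(400 * 3, mu = rep(mu, 3), size = 50), 400)
  y <- cbind(yA, yB)
  rownames(y) <- sprintf("u%03d", 1:400)
  grp <- rep(c("ctrl", "trt"), each = 3)
  ls <- rep(400 * 50, 6)
  de <- callDE(y, grp, contrast = c("ctrl", "trt"), libSizes = ls)
  expect_true(all(de$flag[1:20] == "up"))
  expect_true(all(de$flag[21:40] == "down"))
  expect_lt(mean(de$flag[-(1:40)] != "ns"), 0.08)
  # permuting samples within groups leaves flags unchanged
  perm <- c(3, 1, 2, 5, 6, 4)
  de2 <- callDE(y[, perm], grp[perm], contrast = c("ctrl", "trt"),
                libSizes = ls[perm])
  expect_identical(de$flag, de2$flag)
  # gates: log2FC above log2(1.3) but failing p is not flagged
  expect_true(all(de$flag[de$p >= 0.05] == "ns"))
  expect_true(all(abs(de$log2FC[de$flag != "ns"]) > log2(1.3)))
  expect_error(callDE(y, grp, contrast = c("ctrl", "nope")), "unknown")
})
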