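# SparCC estimation, permutation significance, network thresholding, CAG
# definition and CAG-phenotype correlation.

test_that("SparCC output is a well-formed correlation matrix", {
  me <- simulateCounts(smallConfig(nSamples = 30, nTaxa = 8, seed = 41))
  rho <- sparcc(me, nOuter = 5, seed = 1)
  expect_equal(diag(rho), setNames(rep(1, 8), rownames(me)))
  expect_equal(rho, t(rho))
  expect_true(all(abs(rho) <= 1))
  expect_identical(rho, sparcc(me, nOuter = 5, seed = 1))  # deterministic
  expect_error(sparcc(t(counts(me))[, 1:2]), "at least 3 taxa")
  expect_error(sparcc(t(counts(me))[1:3, ]), "at least 4 samples")
})

test_that("independent taxa give near-zero SparCC correlations", {
  cfg <- nullConfig(nSamples = 300, nTaxa = 30, seed = 43,
                    prevalenceRange = c(1, 1))
  rho <- sparcc(simulateCounts(cfg), nOuter = 10, seed = 2)
  expect_lt(mean(abs(rho[upper.tri(rho)])), 0.1)
})

test_that("a planted basis pair dominates the estimated matrix", {
  cfg <- nullConfig(nSamples = 300, nTaxa = 20, seed = 45,
                    prevalenceRange = c(1, 1),
                    basisCorrelationPairs = data.frame(i = 3, j = 11,
                                                       rho = 0.8))
  rho <- sparcc(simulateCounts(cfg), seed = 3)
  off <- abs(rho)
  diag(off) <- 0
  expect_equal(sort(which(off == max(off), arr.ind = TRUE)[1, ]),
               c(3, 11), ignore_attr = TRUE)
  expect_lt(abs(rho[3, 11] - 0.8), 0.2)
})

test_that("deterministic zero replacement makes SparCC scale-invariant", {
  cfg <- smallConfig(nSamples = 25, nTaxa = 10, seed = 47)
  cnt <- t(counts(simulateCounts(cfg)))
  set.seed(9)
  scaled <- cnt * sample(1:10, nrow(cnt), replace = TRUE)
  r1 <- sparcc(cnt, pseudocount = "multiplicative")
  r2 <- sparcc(scaled, pseudocount = "multiplicative")
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("permutation pseudo-p values are calibrated and floor correctly", {
  cfg <- nullConfig(nSamples = 300, nTaxa = 50, seed = 49,
                    prevalenceRange = c(1, 1),
                    basisCorrelationPairs = data.frame(i = 1, j = 2,
                                                       rho = 0.9))
  sp <- sparccPvalues(simulateCounts(cfg), nPerm = 100, nOuter = 5, seed = 4)
  expect_equal(sp$p[1, 2], 1 / 101)   # planted pair at the analytic floor
  nullP <- sp$p[upper.tri(sp$p)]
  nullP <- nullP[-1]                  # drop the planted pair itself
  expect_lt(abs(mean(nullP < 0.05) - 0.05), 0.02)
})

test_that("network thresholding applies both rules and is monotone", {
  rho <- matrix(c(1, 0.5, 0.5, 1), 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  qHigh <- matrix(c(NA, 0.2, 0.2, NA), 2, 2, dimnames = dimnames(rho))
  qLow <- matrix(c(NA, 0.01, 0.01, NA), 2, 2, dimnames = dimnames(rho))
  expect_equal(nrow(buildNetwork(rho, qHigh)), 0)
  expect_equal(nrow(buildNetwork(rho, qLow)), 1)

  cfg <- nullConfig(nSamples = 100, nTaxa = 12, seed = 51,
                    prevalenceRange = c(1, 1))
  sp <- sparccPvalues(simulateCounts(cfg), nPerm = 50, nOuter = 5, seed = 5)
  loose <- buildNetwork(sp$rho, sp$q, rThreshold = 0.35)
  strict <- buildNetwork(sp$rho, sp$q, rThreshold = 0.45)
  expect_true(nrow(strict) <= nrow(loose))
  key <- function(e) paste(e$source, e$target)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("PERMANOVA pseudo-F matches the exhaustive oracle on 4 taxa", {
  d <- matrix(c(0, 1, 4, 5,
                1, 0, 5, 4,
                4, 5, 0, 1,
                5, 4, 1, 0), 4, 4)
  labels <- c("A", "A", "B", "B")
  got <- permanovaDistance(d, labels, nPerm = 99, seed = 1)
  expect_equal(got$F, permanovaFOracle(d, labels), tolerance = 1e-10)
  # exhaustive p over all 24 relabellings for reference: clean separation
  expect_equal(permanovaPOracle(d, labels), 8 / 24)
})

test_that("PERMANOVA p is calibrated for exchangeable labels", {
  set.seed(12)
  pts <- matrix(rnorm(16), 8, 2)
  d <- as.matrix(dist(pts))
  ps <- sapply(1:100, function(k) {
    labels <- sample(rep(c("A", "B"), 4))
    permanovaDistance(d, labels, nPerm = 99, seed = k)$p
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.65)
})

test_that("Ward clustering of a two-block SparCC matrix recovers the blocks", {
  cfg <- nullConfig(nSamples = 300, nTaxa = 10, seed = 53,
                    prevalenceRange = c(1, 1),
                    basisCorrelationPairs = twoBlockPairs(1:5, 6:10))
  rho <- sparcc(simulateCounts(cfg), seed = 6)
  cg <- defineCags(rho, k = 2, nPerm = 999, seed = 7)
  expect_equal(length(unique(cg$cagLabels[1:5])), 1)
  expect_equal(length(unique(cg$cagLabels[6:10])), 1)
  expect_true(cg$cagLabels[1] != cg$cagLabels[6])
  expect_true(cg$supported)
  expect_error(defineCags(rho, k = 10), "smaller")
})

test_that("CAG-phenotype Spearman correlation hits the exact bounds and ties", {
  F <- cbind(t1 = (1:8) / 100, t2 = (1:8) / 50)
  rownames(F) <- paste0("s", 1:8)
  y <- c(5, 9, 11, 20, 22, 30, 41, 55)
  labels <- factor(c(t1 = "CAG1", t2 = "CAG2"))
  names(labels) <- c("t1", "t2")
  res <- cagPhenotypeCorrelation(labels, F, pheno = y)
  expect_equal(res$rho, c(1, 1))
  resRev <- cagPhenotypeCorrelation(labels, F, pheno = rev(y))
  expect_equal(resRev$rho, c(-1, -1))

  # tied abundances: average-rank handling must match the oracle
  Ft <- cbind(t1 = c(1, 2, 2, 3, 4, 4, 4, 5) / 30)
  rownames(Ft) <- paste0("s", 1:8)
  lab1 <- factor(c(t1 = "CAG1"))
  names(lab1) <- "t1"
  yt <- c(3, 1, 4, 1, 5, 9, 2, 6)
  got <- cagPhenotypeCorrelation(lab1, Ft, pheno = yt)
  expect_equal(got$rho, spearmanRhoOracle(Ft[, 1], yt), tolerance = 1e-12)
})
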