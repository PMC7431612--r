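# Two-part association model: feature construction, the three component
# tests against regression oracles, Stouffer meta-analysis, BH, and the
# permutation-corrected scan.

test_that("two-part features standardize log abundance among present samples", {
  ft <- twoPartFeatures(c(0.1, 0.2, 0))
  expect_equal(ft$b, c(1, 1, 0))
  expect_equal(ft$q[3], 0)
  expect_equal(mean(ft$q[1:2]), 0)
  expect_equal(ft$nPresent, 2)

  # log fractions equally spaced => symmetric standardized values +-sqrt(3/2)
  ft <- twoPartFeatures(c(0.01, 0.04, 0.16, 0))
  expect_equal(ft$q[1:3], c(-1, 0, 1) * sqrt(1.5), tolerance = 1e-12)
  expect_equal(ft$q[4], 0)

  allp <- twoPartFeatures(c(0.2, 0.3, 0.5))
  expect_equal(allp$b, c(1, 1, 1))
  expect_true(twoPartFeatures(c(0, 0, 0))$degenerate)
  expect_true(twoPartFeatures(c(0.5, 0.5))$degenerate)  # constant when present
})

test_that("binary association matches the closed-form regression oracle", {
  set.seed(1)
  b <- c(0, 0, 0, 1, 1, 1)
  y <- c(-1, -1, -1, 1, 1, 1) + rnorm(6, sd = 1e-4)
  ft <- list(b = b, q = numeric(6), nPresent = 3, logMean = 0, logSd = 1)
  got <- binaryAssociation(ft, y)
  fit <- summary(lm(y ~ b))
  expect_equal(got$beta1, unname(coef(fit)[2, 1]), tolerance = 1e-10)
  expect_equal(got$p, unname(coef(fit)[2, 4]), tolerance = 1e-10)
  expect_equal(got$beta1, 2, tolerance = 1e-3)

  constant <- list(b = rep(1, 6), q = numeric(6), nPresent = 6,
                   logMean = 0, logSd = 1)
  expect_true(is.na(binaryAssociation(constant, y)$p))
})

test_that("binary p-values are uniform under the null", {
  set.seed(2)
  n <- 100
  ps <- replicate(2000, {
    b <- rbinom(n, 1, 0.5)
    y <- rnorm(n)
    ft <- list(b = b, q = numeric(n), nPresent = sum(b), logMean = 0, logSd = 1)
    binaryAssociation(ft, y)$p
  })
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("quantitative association restricts to present samples", {
  f <- c(0.01, 0.02, 0.05, 0.11, 0.21, 0.4, 0, 0)
  ft <- twoPartFeatures(f)
  y <- c(3 * ft$q[1:6], 5, -5)   # exact slope 3 among present, junk elsewhere
  got <- quantAssociation(ft, y)
  expect_equal(got$beta2, 3, tolerance = 1e-10)
  expect_lt(got$p, 1e-12)
  expect_equal(got$n, 6)

  set.seed(3)
  y2 <- rnorm(8)
  fit <- summary(lm(y2[1:6] ~ ft$q[1:6]))
  got2 <- quantAssociation(ft, y2)
  expect_equal(got2$beta2, unname(coef(fit)[2, 1]), tolerance = 1e-10)
  expect_equal(got2$p, unname(coef(fit)[2, 4]), tolerance = 1e-10)

  few <- twoPartFeatures(c(0.1, 0.2, 0, 0, 0, 0, 0, 0))
  expect_true(is.na(quantAssociation(few, y2)$p))
})

test_that("Stouffer meta-analysis follows the weighted-Z closed form", {
  expect_equal(metaCombine(0, 0, 50, 50), 1)
  expect_equal(metaCombine(1.96, 1.96, 100, 100),
               2 * pnorm(-1.96 * sqrt(2)), tolerance = 1e-12)
  expect_lt(abs(metaCombine(1.96, 1.96, 100, 100) - 0.00557), 1e-4)
  # vanishing weight on one component recovers the other's two-sided p
  expect_equal(metaCombine(2.5, 0.7, 1e9, 1e-9), 2 * pnorm(-2.5),
               tolerance = 1e-4)
  expect_true(is.na(metaCombine(NA, 1, 10, 10)))
})

test_that("BH adjustment matches the closed form and its properties", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  p <- rep(0.04, 5)
  expect_equal(bhAdjust(p), p)
  set.seed(4)
  p <- runif(50)
  q <- bhAdjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  withNA <- bhAdjust(c(0.01, NA, 0.02, 0.03))
  expect_true(is.na(withNA[2]))
  expect_equal(withNA[-2], c(0.03, 0.03, 0.03))
})

test_that("the scan is deterministic and invariant to affine phenotype maps", {
  cfg <- smallConfig(nSamples = 60, nTaxa = 12, seed = 15)
  me <- preparedExperiment(cfg)
  r1 <- twoPartScan(me, B = 50, seed = 99)
  r2 <- twoPartScan(me, B = 50, seed = 99)
  expect_identical(associationTable(r1), associationTable(r2))

  F <- t(fractions(me))
  y <- SummarizedExperiment::colData(me)$residual
  ra <- twoPartScan(F, pheno = y, B = 50, seed = 99)
  rb <- twoPartScan(F, pheno = 2 * y + 3, B = 50, seed = 99)
  expect_equal(associationTable(ra)$pPerm, associationTable(rb)$pPerm)
  expect_equal(associationTable(ra)$pFinal, associationTable(rb)$pFinal,
               tolerance = 1e-9)
  expect_error(twoPartScan(me, B = 0), "at least 1")
})

test_that("an overwhelming planted effect reaches the permutation floor", {
  cfg <- simulationConfig(nSamples = 120, nTaxa = 15, nCausalTaxa = 1,
                          beta1Effects = 6, beta2Effects = 6,
                          targetMicrobialVarianceFraction = NA,
                          sexEffect = 0, cageEffectSd = 0, noiseSd = 1,
                          intercept = 0, seed = 21)
  me <- preparedExperiment(cfg)
  res <- associationTable(twoPartScan(me, B = 200, seed = 5))
  hit <- res[res$taxon == "OTU0001", ]
  expect_equal(hit$pPerm, 1 / 201)
  expect_equal(which.min(res$qValue), which(res$taxon == "OTU0001"))
})

test_that("a 1.5-SD presence effect is detected with the smallest q", {
  cfg <- simulationConfig(nSamples = 300, nTaxa = 30, nCausalTaxa = 1,
                          beta1Effects = 1.5, beta2Effects = 0,
                          targetMicrobialVarianceFraction = NA,
                          sexEffect = 0, cageEffectSd = 0, noiseSd = 1,
                          intercept = 0, prevalenceRange = c(0.4, 0.7),
                          seed = 23)
  me <- preparedExperiment(cfg)
  res <- associationTable(twoPartScan(me, B = 1000, seed = 6))
  expect_equal(res$taxon[which.min(res$qValue)], "OTU0001")
  expect_lt(res$qValue[res$taxon == "OTU0001"], 0.05)
})

test_that("degenerate taxa are flagged and kept out of the FDR family", {
  F <- cbind(t1 = c(0.5, 0.4, 0.3, 0.6, 0.5, 0.2),
             t2 = rep(0, 6),
             t3 = c(0.5, 0.6, 0.7, 0.4, 0.5, 0.8))
  rownames(F) <- paste0("s", 1:6)
  set.seed(8)
  res <- associationTable(twoPartScan(F, pheno = rnorm(6), B = 20, seed = 1))
  expect_true(res$degenerate[res$taxon == "t2"])
  expect_true(is.na(res$qValue[res$taxon == "t2"]))
  expect_false(any(res$degenerate[res$taxon != "t2"]))
})
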