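# Extreme-group construction and the high/low contrast statistics.

test_that("extreme groups are the exact top and bottom ranks", {
  set.seed(61)
  w <- sample(seq(2000, 3040, by = 10))  # 105 distinct weights
  pheno <- data.frame(sampleId = sprintf("s%03d", seq_along(w)), weight = w)
  des <- selectExtremes(pheno, nPerGroup = 5)
  expect_setequal(des$weight[des$group == "high"], sort(w, TRUE)[1:5])
  expect_setequal(des$weight[des$group == "low"], sort(w)[1:5])
  expect_error(selectExtremes(pheno[1:8, ], nPerGroup = 5), "exceeds")
})

test_that("boundary ties are broken deterministically by sample id", {
  pheno <- data.frame(sampleId = paste0("s", 1:6),
                      weight = c(10, 9, 9, 2, 1, 1))
  expect_message(d1 <- selectExtremes(pheno, nPerGroup = 2), "tie")
  expect_message(d2 <- selectExtremes(pheno, nPerGroup = 2), "tie")
  expect_identical(d1, d2)
  expect_setequal(d1$sampleId[d1$group == "high"], c("s1", "s2"))
  expect_setequal(d1$sampleId[d1$group == "low"], c("s5", "s6"))
})

test_that("Wilcoxon contrasts match exhaustive enumeration", {
  design <- data.frame(sampleId = paste0("s", 1:10),
                       group = factor(rep(c("high", "low"), each = 5),
                                      levels = c("low", "high")))
  sep <- matrix(c(11:15, 1:5) / 100, ncol = 1,
                dimnames = list(paste0("s", 1:10), "f1"))
  res <- wilcoxonFdr(sep, design)
  expect_equal(res$p, 2 / 252, tolerance = 1e-12)   # complete 5v5 separation
  expect_equal(res$direction, "high")

  flat <- matrix(rep(0.3, 10), ncol = 1,
                 dimnames = list(paste0("s", 1:10), "f1"))
  expect_equal(wilcoxonFdr(flat, design)$p, 1)

  # random untied 4v4 inputs: exact equality with the brute-force oracle
  set.seed(63)
  d44 <- data.frame(sampleId = paste0("s", 1:8),
                    group = factor(rep(c("high", "low"), each = 4),
                                   levels = c("low", "high")))
  for (rep_ in 1:5) {
    v <- rnorm(8)
    M <- matrix(v, ncol = 1, dimnames = list(paste0("s", 1:8), "f1"))
    expect_equal(wilcoxonFdr(M, d44)$p, wilcoxOracle(v[1:4], v[5:8]),
                 tolerance = 1e-12)
  }
})

test_that("t-test contrasts match the closed form and its invariances", {
  design <- data.frame(sampleId = paste0("s", 1:6),
                       group = factor(rep(c("high", "low"), each = 3),
                                      levels = c("low", "high")))
  scfa <- data.frame(sampleId = paste0("s", 1:6),
                     acetate = c(52.1, 60.4, 57.3, 48.9, 50.2, 47.7),
                     propionate = rep(5, 6),
                     butyrate = c(9.5, 10.2, 11.1, 7.3, 8.1, 7.9))
  res <- ttestFdr(scfa, design)
  # hand-computed pooled t for butyrate
  xh <- c(9.5, 10.2, 11.1); xl <- c(7.3, 8.1, 7.9)
  sp <- sqrt((2 * var(xh) + 2 * var(xl)) / 4)
  tHand <- (mean(xh) - mean(xl)) / (sp * sqrt(1 / 3 + 1 / 3))
  expect_equal(res$t[res$analyte == "butyrate"], tHand, tolerance = 1e-12)
  expect_equal(res$p[res$analyte == "butyrate"], 2 * pt(-abs(tHand), 4),
               tolerance = 1e-12)
  expect_equal(res$p[res$analyte == "propionate"], 1)
  expect_equal(res$t[res$analyte == "propionate"], 0)

  scaled <- scfa
  scaled$butyrate <- scfa$butyrate * 7
  res2 <- ttestFdr(scaled, design)
  expect_equal(res2$t[res2$analyte == "butyrate"], tHand, tolerance = 1e-12)
})

test_that("Spearman feature-SCFA correlations match exact enumeration", {
  M <- matrix(c(1, 2, 3, 4, 5) / 20, ncol = 1,
              dimnames = list(paste0("s", 1:5), "sp1"))
  scfa <- data.frame(sampleId = paste0("s", 1:5),
                     butyrate = c(2, 4, 6, 8, 10))
  res <- spearmanFdr(M, scfa)
  expect_equal(res$rho, 1)
  expect_equal(res$p, 2 / 120, tolerance = 1e-12)

  set.seed(65)
  for (rep_ in 1:3) {
    x <- rnorm(5)
    y <- rnorm(5)
    M2 <- matrix(x, ncol = 1, dimnames = list(paste0("s", 1:5), "sp1"))
    s2 <- data.frame(sampleId = paste0("s", 1:5), butyrate = y)
    expect_equal(spearmanFdr(M2, s2)$p, spearmanOracle(x, y),
                 tolerance = 1e-12)
  }

  # tied 8-point input: average-rank rho equals the oracle
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5)
  yt <- c(3, 1, 4, 1, 5, 9, 2, 6)
  Mt <- matrix(xt, ncol = 1, dimnames = list(paste0("s", 1:8), "sp1"))
  st <- data.frame(sampleId = paste0("s", 1:8), butyrate = yt)
  expect_equal(spearmanFdr(Mt, st)$rho, spearmanRhoOracle(xt, yt),
               tolerance = 1e-12)
})

test_that("FDR families are scoped per call and never shrink p", {
  set.seed(67)
  M <- matrix(runif(40), 10, 4,
              dimnames = list(paste0("s", 1:10), paste0("f", 1:4)))
  design <- data.frame(sampleId = paste0("s", 1:10),
                       group = factor(rep(c("high", "low"), each = 5),
                                      levels = c("low", "high")))
  res <- wilcoxonFdr(M, design)
  expect_true(all(res$q >= res$p))
})

test_that("a strongly planted butyrate link wins the SCFA contrast", {
  wins <- 0L
  for (k in 1:10) {
    cfg <- simulationConfig(nSamples = 60, nTaxa = 20, nCausalTaxa = 3,
                            beta1Effects = rep(2, 3), beta2Effects = rep(2, 3),
                            targetMicrobialVarianceFraction = NA,
                            sexEffect = 0, cageEffectSd = 0, noiseSd = 0.5,
                            intercept = 0, prevalenceRange = c(0.9, 1),
                            seed = 700 + k)
    me <- simulatePhenotype(simulateCounts(cfg), cfg)
    producers <- S4Vectors::metadata(me)$phenotype$causalTaxa
    scfa <- simulateScfa(me, producers, effect = 2, noiseSd = 0.3,
                         seed = 800 + k)
    des <- selectExtremes(me, nPerGroup = 5)
    res <- ttestFdr(scfa, des)
    if (res$analyte[which.min(res$q)] == "butyrate") wins <- wins + 1L
  }
  expect_gte(wins, 9L)
})
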