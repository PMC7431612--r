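# Shared simulation shorthands for the unit tests.

smallConfig <- function(...) {
  args <- list(nSamples = 40, nTaxa = 10, librarySizeMean = 5000, seed = 7)
  args[names(list(...))] <- list(...)
  do.call(simulationConfig, args)
}

# Fully null study: no causal taxa, no covariate effects.
nullConfig <- function(nSamples, nTaxa, seed, ...) {
  simulationConfig(nSamples = nSamples, nTaxa = nTaxa, nCausalTaxa = 0,
                   targetMicrobialVarianceFraction = NA,
                   sexEffect = 0, cageEffectSd = 0, noiseSd = 1,
                   intercept = 0, seed = seed, ...)
}

# All pairwise correlations of a two-block latent design.
twoBlockPairs <- function(block1, block2, within = 0.7, between = -0.3) {
  w1 <- t(utils::combn(block1, 2))
  w2 <- t(utils::combn(block2, 2))
  cr <- expand.grid(i = block1, j = block2)
  rbind(data.frame(i = w1[, 1], j = w1[, 2], rho = within),
        data.frame(i = w2[, 1], j = w2[, 2], rho = within),
        data.frame(i = cr$i, j = cr$j, rho = between))
}

# A residualized experiment ready for association scanning.
preparedExperiment <- function(config) {
  me <- simulatePhenotype(simulateCounts(config), config)
  residualizeWeight(toRelative(me))
}
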