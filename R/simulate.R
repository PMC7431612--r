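# Synthetic study generator: zero-inflated compositional counts, an additively
# microbially driven phenotype, and SCFA profiles. The generator mirrors the
# statistical structure the downstream analyses assume (log-normal latent
# basis, structural presence masks, multinomial sampling at Poisson depths) so
# every stage of the pipeline is testable without external data.

#' Create a simulation configuration
#'
#' Defaults describe a realistic small-cohort 16S study of finishing weight in
#' meat rabbits: 105 animals, a 50-taxon panel, Poisson(50000) sequencing
#' depths, structural prevalences between 0.4 and 0.95, five causal taxa with
#' alternating-sign presence and abundance effects whose joint contribution is
#' rescaled to 10% of phenotypic variance, a 50 g sex effect, cage blocks of
#' five with 30 g SD block effects, and 150 g residual noise around a 2500 g
#' mean weight.
#'
#' @param nSamples,nTaxa cohort and panel size.
#' @param librarySizeMean mean Poisson sequencing depth per sample.
#' @param prevalenceRange range of structural presence probabilities.
#' @param nCausalTaxa number of taxa with planted effects.
#' @param causalTaxa indices of the causal taxa (default: the first
#'   `nCausalTaxa`).
#' @param beta1Effects,beta2Effects presence and abundance effect sizes per
#'   causal taxon (phenotype units; default alternating +1/-1, rescaled when a
#'   target variance fraction is set).
#' @param targetMicrobialVarianceFraction `NA` to use the raw effects, or a
#'   value in `[0, 1)` to rescale the microbial terms to that share of total
#'   phenotypic variance.
#' @param sexEffect,cageEffectSd,noiseSd,intercept phenotype model parameters.
#' @param cageSize animals per cage block.
#' @param basisCorrelationPairs data.frame (`i`, `j`, `rho`) of latent
#'   log-basis correlations to plant, e.g. for network recovery experiments.
#' @param seed RNG seed; all generated objects are bit-identical under it.
#' @return A validated [SimulationConfig-class].
#' @examples
#' cfg <- simulationConfig(nSamples = 40, nTaxa = 20, seed = 7)
#' cfg
#' @export
simulationConfig <- function(nSamples = 105, nTaxa = 50,
                             librarySizeMean = 50000,
                             prevalenceRange = c(0.4, 0.95),
                             nCausalTaxa = 5,
                             causalTaxa = seq_len(nCausalTaxa),
                             beta1Effects = NULL, beta2Effects = NULL,
                             targetMicrobialVarianceFraction = 0.10,
                             sexEffect = 50, cageEffectSd = 30,
                             noiseSd = 150, intercept = 2500,
                             cageSize = 5,
                             basisCorrelationPairs = NULL,
                             seed = 1) {
  if (is.null(beta1Effects)) {
    beta1Effects <- rep_len(c(1, -1), nCausalTaxa)
  }
  if (is.null(beta2Effects)) {
    beta2Effects <- rep_len(c(1, -1), nCausalTaxa)
  }
  if (is.null(basisCorrelationPairs)) {
    basisCorrelationPairs <- data.frame(i = integer(), j = integer(),
                                        rho = numeric())
  }
  methods::new("SimulationConfig",
    nSamples = as.integer(nSamples), nTaxa = as.integer(nTaxa),
    librarySizeMean = as.numeric(librarySizeMean),
    prevalenceRange = as.numeric(prevalenceRange),
    nCausalTaxa = as.integer(nCausalTaxa),
    causalTaxa = as.integer(causalTaxa),
    beta1Effects = as.numeric(beta1Effects),
    beta2Effects = as.numeric(beta2Effects),
    targetMicrobialVarianceFraction = as.numeric(targetMicrobialVarianceFraction),
    sexEffect = as.numeric(sexEffect), cageEffectSd = as.numeric(cageEffectSd),
    noiseSd = as.numeric(noiseSd), intercept = as.numeric(intercept),
    cageSize = as.integer(cageSize),
    basisCorrelationPairs = basisCorrelationPairs,
    seed = as.integer(seed))
}

# Correlation matrix of the latent log basis implied by the configured pairs.
.basisCorrelationMatrix <- function(config) {
  m <- config@nTaxa
  C <- diag(m)
  bp <- config@basisCorrelationPairs
  if (nrow(bp)) {
    for (r in seq_len(nrow(bp))) {
      C[bp$i[r], bp$j[r]] <- bp$rho[r]
      C[bp$j[r], bp$i[r]] <- bp$rho[r]
    }
  }
  C
}

#' Generate a synthetic zero-inflated compositional count table
#'
#' Draws a latent log-normal basis (with any configured pairwise
#' correlations), applies Bernoulli structural presence masks, closes to
#' compositions and samples counts multinomially at Poisson-distributed
#' library sizes. Zeros therefore arise both structurally and from sampling.
#' The latent basis, presence mask, prevalence probabilities and drawn library
#' sizes are kept in `metadata(x)$simulation` for downstream assertions.
#'
#' @param config a [SimulationConfig-class].
#' @return A [MicrobiomeExperiment-class] with a `"counts"` assay.
#' @examples
#' me <- simulateCounts(simulationConfig(nSamples = 30, nTaxa = 10, seed = 3))
#' me
#' @export
simulateCounts <- function(config) {
  methods::validObject(config)
  n <- config@nSamples
  m <- config@nTaxa
  C <- .basisCorrelationMatrix(config)
  ch <- tryCatch(chol(C), error = function(e) {
    stop("invalid config: basisCorrelationPairs do not form a positive-",
         "definite correlation matrix", call. = FALSE)
  })
  .withSeed(config@seed, {
    mu <- rnorm(m, 0, 1.5)
    sigma <- runif(m, 0.5, 1.5)
    Z <- matrix(rnorm(n * m), n, m) %*% ch
    A <- sweep(sweep(Z, 2, sigma, `*`), 2, mu, `+`)
    pj <- runif(m, config@prevalenceRange[1], config@prevalenceRange[2])
    mask <- matrix(rbinom(n * m, 1L, rep(pj, each = n)), n, m)
    empty <- which(rowSums(mask) == 0L)
    for (i in empty) mask[i, which.max(A[i, ])] <- 1L
    W <- exp(A) * mask
    frac <- W / rowSums(W)
    lib <- pmax(rpois(n, config@librarySizeMean), 1L)
    cnt <- vapply(seq_len(n),
                  function(i) stats::rmultinom(1, lib[i], frac[i, ])[, 1],
                  numeric(m))
    # cnt is taxa x samples already
    taxa <- sprintf("OTU%04d", seq_len(m))
    samples <- sprintf("S%03d", seq_len(n))
    dimnames(cnt) <- list(taxa, samples)
    dimnames(A) <- list(samples, taxa)
    dimnames(mask) <- list(samples, taxa)
    names(pj) <- taxa
    names(lib) <- samples
    MicrobiomeExperiment(cnt, metadata = list(simulation = list(
      config = config, latentBasis = A, presenceMask = mask,
      prevalenceProbs = pj, librarySizes = lib)))
  })
}

#' Generate a phenotype additively driven by planted taxa
#'
#' The phenotype is `intercept + sexEffect * male + cage + sum_causal(beta1 *
#' b + beta2 * q) + noise`, where `b` is presence (count > 0) and `q` is the
#' log relative abundance standardized (population SD) among present samples
#' and 0 where absent — exactly the feature definitions the two-part model
#' uses downstream. When `targetMicrobialVarianceFraction` is set, the summed
#' microbial term is rescaled so its realized variance share matches it. Sex
#' and cage labels, the realized components and the (rescaled) true effects
#' are stored in `metadata(x)$phenotype`; `weight`, `sex` and `cage` are added
#' to `colData`.
#'
#' @param x a [MicrobiomeExperiment-class] produced by [simulateCounts()] with
#'   the same `config`.
#' @param config the [SimulationConfig-class] used to generate `x`.
#' @return `x` with phenotype columns in `colData` and truth in metadata.
#' @export
simulatePhenotype <- function(x, config) {
  methods::validObject(config)
  if (ncol(x) != config@nSamples || nrow(x) != config@nTaxa) {
    stop("alignment error: count table dimensions do not match config",
         call. = FALSE)
  }
  n <- config@nSamples
  frac <- t(fractions(x))
  g <- numeric(n)
  if (config@nCausalTaxa > 0) {
    for (k in seq_len(config@nCausalTaxa)) {
      j <- config@causalTaxa[k]
      f <- frac[, j]
      b <- as.numeric(f > 0)
      q <- numeric(n)
      pres <- which(b == 1)
      if (length(pres) >= 2) {
        lf <- log(f[pres])
        s <- .popSd(lf)
        if (s > 0) q[pres] <- (lf - mean(lf)) / s
      }
      g <- g + config@beta1Effects[k] * b + config@beta2Effects[k] * q
    }
  }
  .withSeed(.subSeed(config@seed, 1), {
    sex <- factor(ifelse(rbinom(n, 1L, 0.5) == 1L, "M", "F"),
                  levels = c("F", "M"))
    cage <- factor(sprintf("C%03d", ceiling(seq_len(n) / config@cageSize)))
    cageEff <- rnorm(nlevels(cage), 0, config@cageEffectSd)
    sexTerm <- config@sexEffect * (sex == "M")
    cageTerm <- cageEff[as.integer(cage)]
    eps <- rnorm(n, 0, config@noiseSd)
    scale <- 1
    tv <- config@targetMicrobialVarianceFraction
    if (!is.na(tv) && config@nCausalTaxa > 0 && .popSd(g) > 0) {
      vOther <- .popSd(sexTerm + cageTerm + eps)^2
      scale <- if (tv == 0) 0 else sqrt(tv / (1 - tv) * vOther / .popSd(g)^2)
    }
    g <- g * scale
    y <- config@intercept + sexTerm + cageTerm + g + eps
    cd <- SummarizedExperiment::colData(x)
    cd$weight <- as.numeric(y)
    cd$sex <- sex
    cd$cage <- cage
    SummarizedExperiment::colData(x) <- cd
    md <- S4Vectors::metadata(x)
    md$phenotype <- list(
      causalTaxa = rownames(x)[config@causalTaxa],
      beta1 = config@beta1Effects * scale,
      beta2 = config@beta2Effects * scale,
      effectScale = scale,
      components = data.frame(sampleId = colnames(x), microbial = g,
                              sexTerm = as.numeric(sexTerm),
                              cageTerm = cageTerm, noise = eps),
      seed = config@seed)
    S4Vectors::metadata(x) <- md
    x
  })
}

#' Generate synthetic SCFA concentrations
#'
#' Butyrate is a noisy linear function of the summed relative abundance of the
#' designated producer taxa (slope sign = `sign(effect)`); acetate and
#' propionate are independent noise around realistic fecal concentrations.
#' Concentrations are in mM and truncated at a small positive floor.
#'
#' @param x a [MicrobiomeExperiment-class] with counts.
#' @param producerTaxa character vector of taxon ids treated as butyrate
#'   producers.
#' @param effect butyrate shift (mM) per SD of summed producer abundance.
#' @param noiseSd SD of the butyrate noise (mM).
#' @param seed RNG seed.
#' @return data.frame with columns `sampleId`, `acetate`, `propionate`,
#'   `butyrate`.
#' @export
simulateScfa <- function(x, producerTaxa, effect = 1, noiseSd = 0.5, seed = 1) {
  missing <- setdiff(producerTaxa, rownames(x))
  if (length(missing)) {
    stop("unknown taxon id(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  frac <- t(fractions(x))
  ps <- rowSums(frac[, producerTaxa, drop = FALSE])
  z <- if (stats::sd(ps) > 0) (ps - mean(ps)) / stats::sd(ps) else numeric(length(ps))
  .withSeed(seed, {
    n <- ncol(x)
    data.frame(
      sampleId = colnames(x),
      acetate = pmax(rnorm(n, 60, 12), 0.05),
      propionate = pmax(rnorm(n, 6, 1.2), 0.05),
      butyrate = pmax(8 + effect * z + rnorm(n, 0, noiseSd), 0.05))
  })
}

#' Write the simulation ground truth as a JSON sidecar
#'
#' Records the causal taxon set, (rescaled) effect sizes, seed and realized
#' microbial variance fraction so tests and downstream scripts can assert
#' against the generating truth without touching the R objects.
#'
#' @param x a [MicrobiomeExperiment-class] carrying phenotype metadata.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSimulationTruth <- function(x, path) {
  ph <- S4Vectors::metadata(x)$phenotype
  if (is.null(ph)) stop("no phenotype metadata; run simulatePhenotype() first",
                        call. = FALSE)
  comp <- ph$components
  totVar <- .popSd(comp$microbial + comp$sexTerm + comp$cageTerm + comp$noise)^2
  truth <- list(
    causalTaxa = ph$causalTaxa, beta1 = ph$beta1, beta2 = ph$beta2,
    effectScale = ph$effectScale, seed = ph$seed,
    realizedMicrobialVarianceFraction =
      if (totVar > 0) .popSd(comp$microbial)^2 / totVar else 0)
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
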