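#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom stats cor median pnorm pt qnorm rbinom rgamma rnorm rpois runif
#'   sd var cov cor.test t.test wilcox.test hclust cutree as.dist lm residuals
#'   model.matrix p.adjust setNames ks.test
NULL

#' Simulation configuration for the synthetic study generator
#'
#' Holds every knob of the synthetic data generator: cohort and panel size,
#' sequencing-depth model, structural prevalence range, the planted causal
#' taxa with their presence (beta1) and abundance (beta2) effects, host
#' covariate effects (sex, cage), residual noise, optional latent basis
#' correlations, and the RNG seed. Construct with [simulationConfig()].
#'
#' @slot nSamples number of animals in the cohort.
#' @slot nTaxa number of taxa (OTU proxies) in the panel.
#' @slot librarySizeMean mean sequencing depth; per-sample depths are Poisson.
#' @slot prevalenceRange length-2 numeric in (0, 1]; structural presence
#'   probabilities are drawn uniformly from this interval.
#' @slot nCausalTaxa number of taxa with planted phenotype effects.
#' @slot causalTaxa integer indices of the causal taxa.
#' @slot beta1Effects per-causal-taxon phenotype shift for presence.
#' @slot beta2Effects per-causal-taxon phenotype slope per SD of log abundance.
#' @slot targetMicrobialVarianceFraction if not `NA`, the microbial terms are
#'   rescaled so their realized share of phenotypic variance equals this value.
#' @slot sexEffect additive phenotype shift for males.
#' @slot cageEffectSd SD of Gaussian cage (block) effects.
#' @slot noiseSd SD of the residual phenotype noise.
#' @slot intercept phenotype intercept (e.g. grams of finishing weight).
#' @slot cageSize number of animals per cage block.
#' @slot basisCorrelationPairs data.frame with columns `i`, `j`, `rho` giving
#'   latent log-basis correlations to plant.
#' @slot seed RNG seed; all generated objects are bit-identical under it.
#'
#' @seealso [simulationConfig()], [simulateCounts()], [simulatePhenotype()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  slots = c(
    nSamples = "integer",
    nTaxa = "integer",
    librarySizeMean = "numeric",
    prevalenceRange = "numeric",
    nCausalTaxa = "integer",
    causalTaxa = "integer",
    beta1Effects = "numeric",
    beta2Effects = "numeric",
    targetMicrobialVarianceFraction = "numeric",
    sexEffect = "numeric",
    cageEffectSd = "numeric",
    noiseSd = "numeric",
    intercept = "numeric",
    cageSize = "integer",
    basisCorrelationPairs = "data.frame",
    seed = "integer"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@nSamples < 1L) msg <- c(msg, "nSamples must be positive")
  if (object@nTaxa < 1L) msg <- c(msg, "nTaxa must be positive")
  if (object@librarySizeMean <= 0) msg <- c(msg, "librarySizeMean must be positive")
  pr <- object@prevalenceRange
  if (length(pr) != 2L || any(pr <= 0) || any(pr > 1) || pr[1] > pr[2]) {
    msg <- c(msg, "prevalenceRange must be an ordered pair in (0, 1]")
  }
  if (object@nCausalTaxa < 0L) msg <- c(msg, "nCausalTaxa must be non-negative")
  if (object@nCausalTaxa > object@nTaxa) {
    msg <- c(msg, "nCausalTaxa must not exceed nTaxa")
  }
  if (length(object@causalTaxa) != object@nCausalTaxa) {
    msg <- c(msg, "causalTaxa must have length nCausalTaxa")
  }
  if (any(object@causalTaxa < 1L) || any(object@causalTaxa > object@nTaxa)) {
    msg <- c(msg, "causalTaxa indices out of range")
  }
  if (anyDuplicated(object@causalTaxa)) msg <- c(msg, "causalTaxa must be unique")
  if (length(object@beta1Effects) != object@nCausalTaxa ||
      length(object@beta2Effects) != object@nCausalTaxa) {
    msg <- c(msg, "beta1Effects/beta2Effects must have length nCausalTaxa")
  }
  tv <- object@targetMicrobialVarianceFraction
  if (length(tv) != 1L || (!is.na(tv) && (tv < 0 || tv >= 1))) {
    msg <- c(msg, "targetMicrobialVarianceFraction must be NA or in [0, 1)")
  }
  if (object@cageEffectSd < 0) msg <- c(msg, "cageEffectSd must be non-negative")
  if (object@noiseSd <= 0) msg <- c(msg, "noiseSd must be positive")
  if (object@cageSize < 1L) msg <- c(msg, "cageSize must be positive")
  bp <- object@basisCorrelationPairs
  if (nrow(bp) > 0) {
    if (!all(c("i", "j", "rho") %in% colnames(bp))) {
      msg <- c(msg, "basisCorrelationPairs needs columns i, j, rho")
    } else {
      if (any(bp$i < 1) || any(bp$i > object@nTaxa) ||
          any(bp$j < 1) || any(bp$j > object@nTaxa) || any(bp$i == bp$j)) {
        msg <- c(msg, "basisCorrelationPairs indices invalid")
      }
      if (any(abs(bp$rho) >= 1)) {
        msg <- c(msg, "basisCorrelationPairs rho must lie in (-1, 1)")
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Container for a microbiome count study
#'
#' A thin [SummarizedExperiment::SummarizedExperiment] subclass. Rows are taxa,
#' columns are samples. The `"counts"` assay stores non-negative integer
#' counts; [toRelative()] adds a `"fractions"` assay. Phenotype columns
#' (`weight`, `sex`, `cage`, `residual`) live in `colData`; simulation truth
#' and preprocessing reports live in `metadata()`.
#'
#' @seealso [MicrobiomeExperiment()], [readCountTable()], [simulateCounts()]
#' @exportClass MicrobiomeExperiment
setClass("MicrobiomeExperiment",
         contains = "SummarizedExperiment")

setValidity("MicrobiomeExperiment", function(object) {
  an <- SummarizedExperiment::assayNames(object)
  if (!length(an)) return("at least one assay required")
  msg <- character()
  if ("counts" %in% an) {
    cnt <- SummarizedExperiment::assay(object, "counts")
    if (any(!is.finite(cnt)) || any(cnt < 0)) {
      msg <- c(msg, "counts must be finite and non-negative")
    }
    if (any(cnt != round(cnt))) msg <- c(msg, "counts must be integers")
  }
  if ("fractions" %in% an) {
    fr <- SummarizedExperiment::assay(object, "fractions")
    if (any(!is.finite(fr)) || any(fr < 0) || any(fr > 1)) {
      msg <- c(msg, "fractions must lie in [0, 1]")
    }
  }
  if (is.null(rownames(object)) || is.null(colnames(object))) {
    msg <- c(msg, "taxon (row) and sample (column) names are required")
  } else if (anyDuplicated(rownames(object)) || anyDuplicated(colnames(object))) {
    msg <- c(msg, "taxon and sample names must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a MicrobiomeExperiment
#'
#' @param counts taxa x samples non-negative integer matrix with dimnames.
#' @param phenotype optional data.frame with columns `sampleId`, `weight`,
#'   `sex`, `cage` (order must match the count columns).
#' @param metadata optional list stored in `metadata()`.
#' @return A [MicrobiomeExperiment-class] object.
#' @examples
#' cnt <- matrix(rpois(12, 50), nrow = 3,
#'               dimnames = list(paste0("OTU", 1:3), paste0("S", 1:4)))
#' me <- MicrobiomeExperiment(cnt)
#' @export
MicrobiomeExperiment <- function(counts, phenotype = NULL, metadata = list()) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  cd <- if (is.null(phenotype)) {
    S4Vectors::DataFrame(row.names = colnames(counts))
  } else {
    .checkAligned(phenotype$sampleId, colnames(counts))
    S4Vectors::DataFrame(phenotype[, setdiff(colnames(phenotype), "sampleId"),
                                   drop = FALSE],
                         row.names = phenotype$sampleId)
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd, metadata = metadata)
  methods::new("MicrobiomeExperiment", se)
}

#' Per-taxon two-part association results
#'
#' Result of [twoPartScan()]: one row per taxon with the binary, quantitative
#' and meta-analysis statistics, the min-p `pFinal`, the permutation-corrected
#' `pPerm`, and BH `qValue`. Retrieve the table with [associationTable()].
#'
#' @slot results data.frame of per-taxon statistics.
#' @slot B number of permutations used for the skewness correction.
#' @slot seed RNG seed of the permutation stream.
#' @slot nSamples number of samples scanned.
#' @exportClass TwoPartResult
setClass("TwoPartResult",
  slots = c(results = "data.frame", B = "integer", seed = "integer",
            nSamples = "integer"))

#' SparCC co-abundance network with CAG structure
#'
#' Bundles the SparCC correlation matrix, permutation pseudo-p and BH q
#' matrices, the thresholded edge list, Ward/PERMANOVA co-abundance group
#' (CAG) labels and the CAG-phenotype correlations. Built by
#' [coabundanceNetwork()].
#'
#' @slot taxonIds taxa in the network.
#' @slot rho symmetric SparCC correlation matrix, unit diagonal.
#' @slot p permutation pseudo-p matrix (diagonal NA).
#' @slot q BH-adjusted p matrix (adjusted over the upper triangle).
#' @slot edges data.frame of edges passing both thresholds.
#' @slot cagLabels factor of CAG memberships, one per taxon.
#' @slot permanovaF,permanovaP PERMANOVA pseudo-F and p for the CAG labels.
#' @slot cagCorrelations data.frame of per-CAG Spearman correlations with the
#'   residual phenotype (empty if no phenotype supplied).
#' @slot rThreshold,qThreshold the edge thresholds used.
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  slots = c(taxonIds = "character", rho = "matrix", p = "matrix", q = "matrix",
            edges = "data.frame", cagLabels = "factor",
            permanovaF = "numeric", permanovaP = "numeric",
            cagCorrelations = "data.frame",
            rThreshold = "numeric", qThreshold = "numeric"))

#' Cross-validated variance explained by the microbiome
#'
#' Result of [estimateVarianceExplained()]: per p-value threshold, the mean and
#' SD over cross-validation repeats of the validation R-squared between the
#' additive microbial predictor and the residual phenotype, and the mean
#' number of selected taxa. Retrieve the table with [varianceTable()].
#'
#' @slot table data.frame with columns `threshold`, `meanR2`, `sdR2`,
#'   `meanNSelected`.
#' @slot nRepeats number of cross-validation repeats.
#' @slot trainFraction discovery-set fraction.
#' @slot BInner permutations inside each discovery scan (0 = min-p selection).
#' @slot seed RNG seed.
#' @exportClass VarianceExplained
setClass("VarianceExplained",
  slots = c(table = "data.frame", nRepeats = "integer",
            trainFraction = "numeric", BInner = "integer", seed = "integer"))
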