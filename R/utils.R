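# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      stats::runif(1)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

# Deterministic derived seed, kept inside 32-bit integer range.
.subSeed <- function(seed, k) {
  as.integer((abs(as.numeric(seed)) + 9973 * as.numeric(k)) %% 2147483647)
}

# Population (divide-by-n) standard deviation.
.popSd <- function(x) sqrt(mean((x - mean(x))^2))

.checkAligned <- function(a, b, what = "sample ids") {
  if (length(a) != length(b) || !all(a == b)) {
    stop("alignment error: ", what, " do not match", call. = FALSE)
  }
  invisible(TRUE)
}

# Fractions matrix in samples x taxa orientation from a MicrobiomeExperiment
# or a plain matrix (assumed samples x taxa already).
.fractionMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    t(fractions(x))
  } else {
    m <- as.matrix(x)
    if (is.null(colnames(m))) colnames(m) <- paste0("taxon", seq_len(ncol(m)))
    if (is.null(rownames(m))) rownames(m) <- paste0("sample", seq_len(nrow(m)))
    m
  }
}

# Residualized phenotype vector aligned to the samples of `x`.
.residualVector <- function(x, pheno = NULL) {
  if (is.null(pheno) && is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (!"residual" %in% colnames(cd)) {
      stop("no 'residual' column in colData; run residualizeWeight() first",
           call. = FALSE)
    }
    y <- cd$residual
    names(y) <- colnames(x)
    return(y)
  }
  if (is.data.frame(pheno)) {
    if (!"residual" %in% colnames(pheno)) {
      stop("phenotype table has no 'residual' column; run residualizeWeight() first",
           call. = FALSE)
    }
    ids <- if (is(x, "SummarizedExperiment")) colnames(x) else rownames(.fractionMatrix(x))
    .checkAligned(pheno$sampleId, ids)
    y <- pheno$residual
    names(y) <- pheno$sampleId
    return(y)
  }
  y <- as.numeric(pheno)
  ids <- if (is(x, "SummarizedExperiment")) colnames(x) else rownames(.fractionMatrix(x))
  if (length(y) != length(ids)) {
    stop("alignment error: phenotype length does not match sample count",
         call. = FALSE)
  }
  names(y) <- ids
  y
}
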