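# I/O and preprocessing: tab-delimited table round-trips, relative-abundance
# closure, abundance/prevalence filtering, rarefaction, and phenotype
# residualization against sex and cage.

#' Read / write a count table
#'
#' Tab-delimited layout: header row of taxon ids, first column of sample ids,
#' integer counts. `readCountTable()` validates every cell and reports the
#' position of the first non-integer or negative value; `writeCountTable()`
#' writes the same layout so that write-then-read is the identity.
#'
#' @param path file path.
#' @return `readCountTable()` a [MicrobiomeExperiment-class];
#'   `writeCountTable()` the path, invisibly.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' me <- simulateCounts(simulationConfig(nSamples = 6, nTaxa = 4, seed = 2))
#' writeCountTable(me, f)
#' me2 <- readCountTable(f)
#' all.equal(counts(me), counts(me2))
#' @export
readCountTable <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2) stop("count table needs sample ids plus at least one taxon",
                         call. = FALSE)
  sampleIds <- df[[1]]
  taxonIds <- colnames(df)[-1]
  cnt <- matrix(NA_real_, nrow = length(sampleIds), ncol = length(taxonIds),
                dimnames = list(sampleIds, taxonIds))
  for (j in seq_along(taxonIds)) {
    v <- suppressWarnings(as.numeric(df[[j + 1]]))
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad)) {
      i <- bad[1]
      stop(sprintf(
        "format error: row %d (sample %s), column %d (taxon %s): value '%s' is not a non-negative integer",
        i, sampleIds[i], j, taxonIds[j], df[[j + 1]][i]), call. = FALSE)
    }
    cnt[, j] <- v
  }
  MicrobiomeExperiment(t(cnt))
}

#' @rdname readCountTable
#' @param x a [MicrobiomeExperiment-class].
#' @export
writeCountTable <- function(x, path) {
  cnt <- t(counts(x))
  df <- data.frame(sample_id = rownames(cnt), cnt, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the phenotype or SCFA table as tab-delimited text
#'
#' @param x for `writePhenotypeTable()` a [MicrobiomeExperiment-class] with
#'   phenotype columns in `colData`; for `writeScfaTable()` the data.frame
#'   returned by [simulateScfa()].
#' @param path file path.
#' @return the path, invisibly.
#' @export
writePhenotypeTable <- function(x, path) {
  cd <- as.data.frame(SummarizedExperiment::colData(x))
  df <- data.frame(sample_id = colnames(x), cd, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePhenotypeTable
#' @export
writeScfaTable <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Convert counts to relative abundances
#'
#' Row-wise (per-sample) closure of the count assay. Samples with zero total
#' counts are an upstream error and rejected.
#'
#' @param x a [MicrobiomeExperiment-class] with a `"counts"` assay.
#' @return `x` with an added `"fractions"` assay.
#' @export
toRelative <- function(x) {
  cnt <- counts(x)
  cs <- colSums(cnt)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ", paste(colnames(x)[cs == 0], collapse = ", "),
         call. = FALSE)
  }
  SummarizedExperiment::assay(x, "fractions") <- sweep(cnt, 2, cs, `/`)
  x
}

#' Filter rare taxa
#'
#' Retains taxa whose mean relative abundance across samples is at least
#' `minMeanAbundance` (default 0.1%) and which are present (fraction > 0) in
#' at least `ceiling(minPrevalence * nSamples)` samples (default 1%). The
#' sample set is unchanged; kept/dropped taxon lists are stored in
#' `metadata(x)$filterReport`. With `method = "max"` the abundance criterion
#' uses the per-taxon maximum instead of the mean.
#'
#' @param x a [MicrobiomeExperiment-class] (fractions computed on the fly if
#'   absent).
#' @param minMeanAbundance minimum mean relative abundance.
#' @param minPrevalence minimum fraction of samples with the taxon present.
#' @param method `"mean"` (default) or `"max"` abundance summary.
#' @return The filtered [MicrobiomeExperiment-class].
#' @export
filterTaxa <- function(x, minMeanAbundance = 0.001, minPrevalence = 0.01,
                       method = c("mean", "max")) {
  method <- match.arg(method)
  fr <- fractions(x)                       # taxa x samples
  n <- ncol(fr)
  ab <- if (method == "mean") rowMeans(fr) else apply(fr, 1, max)
  presentCount <- rowSums(fr > 0)
  keep <- ab >= minMeanAbundance & presentCount >= ceiling(minPrevalence * n)
  if (!any(keep)) warning("all taxa filtered out", call. = FALSE)
  report <- list(kept = rownames(x)[keep], dropped = rownames(x)[!keep],
                 minMeanAbundance = minMeanAbundance,
                 minPrevalence = minPrevalence, method = method)
  out <- x[keep, ]
  md <- S4Vectors::metadata(out)
  md$filterReport <- report
  S4Vectors::metadata(out) <- md
  out
}

#' Rarefy counts to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) to exactly `depth`. Samples whose
#' library size is below `depth` are dropped with a warning. Deterministic
#' under `seed`.
#'
#' @param x a [MicrobiomeExperiment-class] with counts.
#' @param depth target library size (default 40000 tags).
#' @param seed RNG seed.
#' @return The rarefied [MicrobiomeExperiment-class] (counts assay only).
#' @export
rarefyCounts <- function(x, depth = 40000, seed = 1) {
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  cnt <- counts(x)
  libs <- colSums(cnt)
  low <- libs < depth
  if (any(low)) {
    warning(sum(low), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(x)[low], collapse = ", "), call. = FALSE)
    x <- x[, !low]
    cnt <- cnt[, !low, drop = FALSE]
  }
  if (ncol(cnt) == 0) stop("no samples at or above depth", call. = FALSE)
  # vegan warns when the table has no singleton counts; irrelevant here
  rar <- .withSeed(seed, withCallingHandlers(
    vegan::rrarefy(t(cnt), depth),
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  out <- x
  SummarizedExperiment::assays(out) <- list(counts = t(rar))
  out
}

#' Residualize the phenotype on sex and cage
#'
#' Ordinary least-squares fit of the phenotype on the indicator expansion of
#' the categorical covariates; the residuals carry all downstream association
#' analyses. Rank-deficient designs are handled by the pivoting QR solver
#' (residuals remain the projection onto the covariate complement). A
#' categorical level observed once absorbs its own residual to zero, which is
#' flagged with a warning.
#'
#' @param x a [MicrobiomeExperiment-class] with `weight`, `sex`, `cage` in
#'   `colData`, or a data.frame with columns `sampleId`, `weight`, `sex`,
#'   `cage`.
#' @return `x` with a `residual` column added.
#' @export
residualizeWeight <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    cd$sampleId <- colnames(x)
    cd <- .residualizeFrame(cd)
    SummarizedExperiment::colData(x)$residual <- cd$residual
    return(x)
  }
  .residualizeFrame(x)
}

.residualizeFrame <- function(df) {
  need <- c("weight", "sex", "cage")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("phenotype table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df$sex <- factor(df$sex)
  df$cage <- factor(df$cage)
  singles <- c(names(which(table(df$sex) == 1)), names(which(table(df$cage) == 1)))
  if (length(singles)) {
    warning("covariate level(s) with a single observation (residual absorbed ",
            "to 0): ", paste(singles, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm(weight ~ sex + cage, data = df)
  df$residual <- as.numeric(stats::residuals(fit))
  df
}
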