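# High/low extreme-group construction and the univariate contrasts: Wilcoxon
# rank-sum with FDR for feature tables, unpaired Student's t with FDR for
# SCFAs, and Spearman correlations with FDR for species-SCFA relationships.
# The classical tests are delegated to stats::wilcox.test / t.test /
# cor.test; this module defines the group design, the FDR family scope, and
# tidy result tables.

#' Select extreme phenotype groups
#'
#' Sorts samples by phenotype value and assigns the top `nPerGroup` to the
#' `high` group and the bottom `nPerGroup` to the `low` group (default 5 and
#' 5, the usual design for extreme-group metagenomic sequencing). Ties at a
#' group boundary are broken by sample id order and reported with a message.
#'
#' @param pheno data.frame with columns `sampleId` and `weight`, or a
#'   [MicrobiomeExperiment-class] with `weight` in `colData`.
#' @param nPerGroup samples per group (default 5).
#' @return data.frame with columns `sampleId`, `weight`, `group` (factor
#'   `low`/`high`), sorted high group first.
#' @export
selectExtremes <- function(pheno, nPerGroup = 5) {
  if (is(pheno, "SummarizedExperiment")) {
    pheno <- data.frame(
      sampleId = colnames(pheno),
      weight = SummarizedExperiment::colData(pheno)$weight,
      stringsAsFactors = FALSE)
  }
  n <- nrow(pheno)
  if (2 * nPerGroup > n) {
    stop("2 * nPerGroup exceeds the number of samples", call. = FALSE)
  }
  ordHigh <- order(-pheno$weight, pheno$sampleId)
  ordLow <- order(pheno$weight, pheno$sampleId)
  high <- ordHigh[seq_len(nPerGroup)]
  low <- ordLow[seq_len(nPerGroup)]
  bnd <- c(pheno$weight[ordHigh[nPerGroup]], pheno$weight[ordLow[nPerGroup]])
  tied <- sum(pheno$weight == bnd[1]) > 1 || sum(pheno$weight == bnd[2]) > 1
  if (tied) {
    message("boundary tie(s) broken deterministically by sample id order")
  }
  out <- rbind(
    data.frame(sampleId = pheno$sampleId[high], weight = pheno$weight[high],
               group = "high", stringsAsFactors = FALSE),
    data.frame(sampleId = pheno$sampleId[low], weight = pheno$weight[low],
               group = "low", stringsAsFactors = FALSE))
  out$group <- factor(out$group, levels = c("low", "high"))
  out
}

# samples x features numeric matrix from the accepted inputs.
.featureMatrix <- function(features) {
  if (is(features, "SummarizedExperiment")) {
    t(fractions(features))
  } else {
    as.matrix(features)
  }
}

#' Wilcoxon rank-sum contrasts between high and low groups
#'
#' Two-sided Mann-Whitney/Wilcoxon test per feature (exact distribution for
#' small untied samples, normal approximation with tie correction otherwise,
#' as implemented by [stats::wilcox.test()]), BH correction across the
#' features of the table, and the direction as the group with the higher
#' median.
#'
#' @param features samples x features matrix (rownames = sample ids) or a
#'   [MicrobiomeExperiment-class] (fractions used).
#' @param design output of [selectExtremes()].
#' @return data.frame with columns `feature`, `W`, `p`, `q`, `direction`.
#' @export
wilcoxonFdr <- function(features, design) {
  M <- .featureMatrix(features)
  miss <- setdiff(design$sampleId, rownames(M))
  if (length(miss)) stop("design samples missing from features: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  hi <- design$sampleId[design$group == "high"]
  lo <- design$sampleId[design$group == "low"]
  out <- do.call(rbind, lapply(colnames(M), function(f) {
    xh <- M[hi, f]
    xl <- M[lo, f]
    if (all(xh == xh[1]) && all(xl == xl[1]) && xh[1] == xl[1]) {
      W <- length(xh) * length(xl) / 2
      p <- 1
    } else {
      wt <- suppressWarnings(wilcox.test(xh, xl))
      W <- unname(wt$statistic)
      p <- wt$p.value
    }
    dir <- if (median(xh) > median(xl)) "high"
           else if (median(xh) < median(xl)) "low" else "none"
    data.frame(feature = f, W = W, p = p, direction = dir,
               stringsAsFactors = FALSE)
  }))
  out$q <- bhAdjust(out$p)
  out[, c("feature", "W", "p", "q", "direction")]
}

#' Student's t contrasts of SCFA levels between high and low groups
#'
#' Classical two-sided unpaired t-test per analyte (equal variances by
#' default, Welch with `varEqual = FALSE`), BH correction across the
#' analytes.
#'
#' @param scfa data.frame with `sampleId` and analyte columns (acetate,
#'   propionate, butyrate).
#' @param design output of [selectExtremes()].
#' @param varEqual pool variances (default TRUE).
#' @return data.frame with columns `analyte`, `t`, `p`, `q`, `direction`.
#' @export
ttestFdr <- function(scfa, design, varEqual = TRUE) {
  analytes <- setdiff(colnames(scfa), "sampleId")
  miss <- setdiff(design$sampleId, scfa$sampleId)
  if (length(miss)) stop("design samples missing from scfa table: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  rownames(scfa) <- scfa$sampleId
  hi <- design$sampleId[design$group == "high"]
  lo <- design$sampleId[design$group == "low"]
  out <- do.call(rbind, lapply(analytes, function(a) {
    xh <- scfa[hi, a]
    xl <- scfa[lo, a]
    if (sd(c(xh, xl)) == 0) {
      tv <- 0
      p <- 1
    } else {
      tt <- t.test(xh, xl, var.equal = varEqual)
      tv <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(analyte = a, t = tv, p = p,
               direction = if (mean(xh) > mean(xl)) "high"
                           else if (mean(xh) < mean(xl)) "low" else "none",
               stringsAsFactors = FALSE)
  }))
  out$q <- bhAdjust(out$p)
  out[, c("analyte", "t", "p", "q", "direction")]
}

#' Spearman correlations between features and SCFA levels
#'
#' Average-rank Spearman correlation for every feature x analyte pair
#' (exact p for small untied samples, t/Edgeworth approximation otherwise,
#' as implemented by [stats::cor.test()]), with BH correction jointly across
#' all pairs. The wide rho matrix backing a correlation heat map is attached
#' as `attr(, "rhoMatrix")`.
#'
#' @param features samples x features matrix or [MicrobiomeExperiment-class].
#' @param scfa data.frame with `sampleId` and analyte columns.
#' @return data.frame with columns `feature`, `analyte`, `rho`, `p`, `q`.
#' @export
spearmanFdr <- function(features, scfa) {
  M <- .featureMatrix(features)
  ids <- intersect(rownames(M), scfa$sampleId)
  if (!length(ids)) stop("no overlapping samples", call. = FALSE)
  rownames(scfa) <- scfa$sampleId
  analytes <- setdiff(colnames(scfa), "sampleId")
  out <- do.call(rbind, lapply(colnames(M), function(f) {
    do.call(rbind, lapply(analytes, function(a) {
      x <- M[ids, f]
      y <- scfa[ids, a]
      if (sd(x) == 0 || sd(y) == 0) {
        rho <- NA_real_
        p <- NA_real_
      } else {
        ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
        rho <- unname(ct$estimate)
        p <- ct$p.value
      }
      data.frame(feature = f, analyte = a, rho = rho, p = p,
                 stringsAsFactors = FALSE)
    }))
  }))
  out$q <- bhAdjust(out$p)
  rhoM <- matrix(out$rho, nrow = ncol(M), byrow = TRUE,
                 dimnames = list(colnames(M), analytes))
  attr(out, "rhoMatrix") <- rhoM
  out
}
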