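# Cross-validated estimate of the fraction of phenotypic variance explained
# by the microbiome. Effects (beta1, beta2) and feature standardization
# parameters are learned on a discovery split; the additive predictor
# r_m = sum_j (beta1_j * b_j + beta2_j * q_j) over taxa passing a discovery
# p-value threshold is evaluated on the held-out validation split, and the
# squared Pearson correlation between r_m and the residual phenotype is the
# variance explained at that threshold.

#' Additive microbial predictor on new samples
#'
#' Sums `beta1 * b + beta2 * q` over taxa whose discovery p-value passes the
#' threshold. Presence `b` and standardized log abundance `q` are computed on
#' the new samples, with the q standardization parameters (per-taxon
#' mean/SD of log abundance among present discovery samples) carried over
#' from discovery. Taxa degenerate in discovery contribute 0. An empty
#' selection yields all-zero predictions, flagged via `attr(, "empty")`.
#'
#' @param assoc a [TwoPartResult-class] (or its `associationTable()`
#'   data.frame) fit on the discovery samples.
#' @param newdata a samples x taxa fraction matrix, or a
#'   [MicrobiomeExperiment-class], covering the discovery taxa.
#' @param threshold discovery p-value threshold for taxon selection.
#' @param selectOn `"pFinal"` (default) or `"pPerm"`.
#' @return Numeric vector of per-sample predictions `r_m`.
#' @export
predictMicrobialValue <- function(assoc, newdata, threshold,
                                  selectOn = c("pFinal", "pPerm")) {
  selectOn <- match.arg(selectOn)
  tab <- if (is(assoc, "TwoPartResult")) associationTable(assoc) else assoc
  F <- .fractionMatrix(newdata)
  sel <- which(!is.na(tab[[selectOn]]) & tab[[selectOn]] <= threshold)
  rm_ <- numeric(nrow(F))
  names(rm_) <- rownames(F)
  if (!length(sel)) {
    attr(rm_, "empty") <- TRUE
    attr(rm_, "nSelected") <- 0L
    return(rm_)
  }
  idx <- match(tab$taxon[sel], colnames(F))
  if (anyNA(idx)) {
    stop("selected taxa missing from newdata: ",
         paste(tab$taxon[sel][is.na(idx)], collapse = ", "), call. = FALSE)
  }
  Fs <- F[, idx, drop = FALSE]
  P <- Fs > 0
  b1 <- ifelse(is.na(tab$beta1[sel]), 0, tab$beta1[sel])
  b2 <- ifelse(is.na(tab$beta2[sel]), 0, tab$beta2[sel])
  lm_ <- tab$logMean[sel]
  ls_ <- tab$logSd[sel]
  useQ <- !is.na(lm_) & !is.na(ls_) & ls_ > 0
  L <- matrix(0, nrow(Fs), ncol(Fs))
  L[P] <- log(Fs[P])
  Q <- sweep(L, 2, ifelse(useQ, lm_, 0), `-`)
  Q <- sweep(Q, 2, ifelse(useQ, ls_, 1), `/`)
  Q[!P] <- 0
  Q[, !useQ] <- 0
  Bm <- P
  storage.mode(Bm) <- "double"
  rm_[] <- as.vector(Bm %*% b1 + Q %*% b2)
  attr(rm_, "empty") <- FALSE
  attr(rm_, "nSelected") <- length(sel)
  rm_
}

#' Cross-validated variance explained by the microbiome
#'
#' Repeatedly splits the cohort into a discovery fraction (default 80%) and a
#' validation remainder, runs the two-part scan on the discovery split, and
#' for each p-value threshold evaluates the additive predictor on the
#' validation split. `R2` is the squared Pearson correlation between `r_m`
#' and the residual phenotype (0 when `r_m` is constant or the selection is
#' empty). Reports the mean and SD of `R2` and the mean number of selected
#' taxa per threshold, across repeats.
#'
#' With `BInner = 0` (fast mode, default) selection uses the min-p `pFinal`;
#' with `BInner > 0` each discovery scan runs that many permutations and
#' selection uses `pPerm`.
#'
#' @param x a [MicrobiomeExperiment-class] with fractions and a residualized
#'   phenotype, or a samples x taxa fraction matrix.
#' @param pheno optional phenotype (see [twoPartScan()]).
#' @param thresholds ascending p-value grid (default `1e-5` to `0.1`).
#' @param nRepeats number of random splits (default 100).
#' @param trainFraction discovery fraction in (0, 1) (default 0.8).
#' @param BInner permutations per discovery scan (default 0 = fast mode).
#' @param seed RNG seed; repeat r uses a seed derived from it.
#' @param minPresent minimum present samples for the quantitative part.
#' @return A [VarianceExplained-class].
#' @export
estimateVarianceExplained <- function(x, pheno = NULL,
                                      thresholds = c(1e-5, 1e-4, 1e-3, 0.01,
                                                     0.05, 0.1),
                                      nRepeats = 100, trainFraction = 0.8,
                                      BInner = 0, seed = 1, minPresent = 4) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(thresholds <= 0) || any(thresholds >= 1)) {
    stop("thresholds must lie in (0, 1)", call. = FALSE)
  }
  thresholds <- sort(thresholds)
  F <- .fractionMatrix(x)
  y <- .residualVector(x, pheno)
  n <- nrow(F)
  nTrain <- round(trainFraction * n)
  if (nTrain < 3 || nTrain > n - 2) stop("split leaves too few samples",
                                         call. = FALSE)
  R2 <- matrix(NA_real_, nRepeats, length(thresholds))
  nSel <- matrix(NA_real_, nRepeats, length(thresholds))
  for (r in seq_len(nRepeats)) {
    idx <- .withSeed(.subSeed(seed, r), sample.int(n, nTrain))
    Ftr <- F[idx, , drop = FALSE]
    ytr <- y[idx]
    Fva <- F[-idx, , drop = FALSE]
    yva <- y[-idx]
    d <- .twoPartDesign(Ftr, minPresent = minPresent)
    obs <- .scanStats(d, ytr)
    pSel <- obs$pFinal
    if (BInner > 0) {
      permMin <- matrix(NA_real_, BInner, ncol(Ftr))
      .withSeed(.subSeed(seed, 100000 + r), {
        for (b in seq_len(BInner)) {
          permMin[b, ] <- .scanStats(d, ytr[sample.int(nTrain)])$pFinal
        }
      })
      exceed <- colSums(permMin <= rep(obs$pFinal, each = BInner))
      pSel <- ifelse(is.na(obs$pFinal), NA_real_, (1 + exceed) / (1 + BInner))
    }
    tab <- data.frame(taxon = colnames(F), beta1 = obs$beta1,
                      beta2 = obs$beta2, pFinal = pSel,
                      logMean = d$logMean, logSd = d$logSd,
                      stringsAsFactors = FALSE)
    for (ti in seq_along(thresholds)) {
      rm_ <- predictMicrobialValue(tab, Fva, thresholds[ti])
      nSel[r, ti] <- attr(rm_, "nSelected")
      R2[r, ti] <- if (stats::sd(rm_) > 0) cor(rm_, yva)^2 else 0
    }
  }
  tbl <- data.frame(threshold = thresholds,
                    meanR2 = colMeans(R2),
                    sdR2 = apply(R2, 2, stats::sd),
                    meanNSelected = colMeans(nSel))
  methods::new("VarianceExplained", table = tbl,
               nRepeats = as.integer(nRepeats),
               trainFraction = as.numeric(trainFraction),
               BInner = as.integer(BInner), seed = as.integer(seed))
}
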