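# SparCC correlation estimation on compositional counts, permutation
# significance, network thresholding, co-abundance group (CAG) definition by
# Ward clustering validated with PERMANOVA, and CAG-phenotype correlation.
#
# SparCC estimates correlations of the latent (basis) abundances from
# log-ratio variances: with T_ij = var(log(x_i/x_j)) and basis variances
# omega, T_ij = omega_i + omega_j - 2 rho_ij sqrt(omega_i omega_j). Under the
# sparsity assumption (most pairs uncorrelated) the row sums of T give a
# linear system for omega; the strongest pairs are then iteratively excluded
# from the system and it is re-solved, so a few dense correlations do not
# bias the basis variances.

# One SparCC estimation on a fixed fraction matrix (samples x taxa).
.sparccOnce <- function(frac, exclusionThreshold = 0.1, maxExclusions = 10) {
  L <- log(frac)
  m <- ncol(L)
  Cv <- cov(L)
  v <- diag(Cv)
  T_ <- outer(v, rep(1, m)) + outer(rep(1, m), v) - 2 * Cv
  active <- matrix(TRUE, m, m)
  diag(active) <- FALSE
  M <- matrix(1, m, m)
  diag(M) <- m - 1

  solveRho <- function() {
    t_ <- rowSums(T_ * active)
    omega <- tryCatch(solve(M, t_), error = function(e) rep(mean(t_) / m, m))
    pos <- omega[omega > 0]
    floorv <- if (length(pos)) min(pos) else .Machine$double.eps
    omega[omega <= 0] <- floorv
    denom <- 2 * sqrt(outer(omega, omega))
    rho <- (outer(omega, rep(1, m)) + outer(rep(1, m), omega) - T_) / denom
    rho[rho > 1] <- 1
    rho[rho < -1] <- -1
    diag(rho) <- 1
    rho
  }

  rho <- solveRho()
  for (iter in seq_len(maxExclusions)) {
    cand <- abs(rho)
    cand[!active | lower.tri(cand, diag = TRUE)] <- -Inf
    mx <- which.max(cand)
    if (!is.finite(cand[mx]) || cand[mx] <= exclusionThreshold) break
    i <- (mx - 1) %% m + 1
    j <- (mx - 1) %/% m + 1
    # never drive a taxon's equation degenerate
    if (M[i, i] <= 2 || M[j, j] <= 2) {
      active[i, j] <- active[j, i] <- FALSE
      next
    }
    active[i, j] <- active[j, i] <- FALSE
    M[i, j] <- M[j, i] <- M[i, j] - 1
    M[i, i] <- M[i, i] - 1
    M[j, j] <- M[j, j] - 1
    rho <- solveRho()
  }
  rho
}

# Draw fraction matrices from counts under the chosen zero-handling scheme.
.sparccFractions <- function(cnt, pseudocount) {
  if (pseudocount == "dirichlet") {
    g <- matrix(rgamma(length(cnt), shape = cnt + 1), nrow(cnt), ncol(cnt))
    g / rowSums(g)
  } else {
    f <- cnt / rowSums(cnt)
    for (i in seq_len(nrow(f))) {
      z <- f[i, ] == 0
      if (any(z)) {
        delta <- 0.5 * min(f[i, !z])
        f[i, z] <- delta
        f[i, !z] <- f[i, !z] * (1 - delta * sum(z))
      }
    }
    f
  }
}

#' SparCC correlation matrix of compositional counts
#'
#' Estimates basis correlations from log-ratio variances under the SparCC
#' sparsity approximation, iteratively excluding the strongest pairs (|rho| >
#' `exclusionThreshold`, up to `maxExclusions`) from the basis-variance
#' system. With `pseudocount = "dirichlet"` (default), fractions are drawn
#' per outer iteration from the per-sample Dirichlet posterior with unit
#' prior and the final matrix is the element-wise median over `nOuter`
#' draws. With `pseudocount = "multiplicative"` zeros are replaced
#' deterministically (multiplicative replacement at half the sample's
#' smallest nonzero fraction), which makes the estimate exactly invariant to
#' per-sample count rescaling.
#'
#' @param x a [MicrobiomeExperiment-class] or a samples x taxa count matrix.
#' @param nOuter outer resampling iterations (default 20).
#' @param exclusionThreshold |rho| above which a pair is excluded from the
#'   basis system (default 0.1).
#' @param maxExclusions maximum excluded pairs (default 10).
#' @param pseudocount `"dirichlet"` or `"multiplicative"` zero handling.
#' @param seed RNG seed (Dirichlet mode).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(x, nOuter = 20, exclusionThreshold = 0.1,
                   maxExclusions = 10,
                   pseudocount = c("dirichlet", "multiplicative"), seed = 1) {
  pseudocount <- match.arg(pseudocount)
  cnt <- if (is(x, "SummarizedExperiment")) t(counts(x)) else as.matrix(x)
  if (nrow(cnt) < 4) stop("need at least 4 samples", call. = FALSE)
  if (ncol(cnt) < 3) {
    stop("need at least 3 taxa (basis system underdetermined)", call. = FALSE)
  }
  ids <- colnames(cnt)
  if (is.null(ids)) ids <- paste0("taxon", seq_len(ncol(cnt)))
  if (pseudocount == "multiplicative") {
    rho <- .sparccOnce(.sparccFractions(cnt, pseudocount),
                       exclusionThreshold, maxExclusions)
  } else {
    rho <- .withSeed(seed, {
      draws <- vapply(seq_len(nOuter), function(k) {
        .sparccOnce(.sparccFractions(cnt, pseudocount),
                    exclusionThreshold, maxExclusions)
      }, matrix(0, ncol(cnt), ncol(cnt)))
      apply(draws, c(1, 2), median)
    })
  }
  dimnames(rho) <- list(ids, ids)
  rho
}

#' Permutation pseudo-p values for SparCC correlations
#'
#' For each of `nPerm` permutations, every taxon's counts are shuffled
#' independently across samples (destroying all between-taxon dependence
#' while keeping marginals) and the SparCC matrix is recomputed. Two-sided
#' `p = (1 + #\{|rho_perm| >= |rho_obs|\}) / (1 + nPerm)` per pair; BH over
#' the upper triangle gives the q matrix.
#'
#' @inheritParams sparcc
#' @param nPerm number of permutations (default 100).
#' @param ... passed to [sparcc()] (`nOuter`, thresholds, `pseudocount`).
#' @return list with `rho`, `p` and `q` matrices (diagonals NA for p/q).
#' @export
sparccPvalues <- function(x, nPerm = 100, seed = 1, ...) {
  cnt <- if (is(x, "SummarizedExperiment")) t(counts(x)) else as.matrix(x)
  rhoObs <- sparcc(cnt, seed = seed, ...)
  m <- ncol(cnt)
  exceed <- matrix(0, m, m)
  for (k in seq_len(nPerm)) {
    cntp <- .withSeed(.subSeed(seed, 1000 + k), {
      apply(cnt, 2, function(col) col[sample.int(nrow(cnt))])
    })
    rhoP <- sparcc(cntp, seed = .subSeed(seed, 500000 + k), ...)
    exceed <- exceed + (abs(rhoP) >= abs(rhoObs))
  }
  p <- (1 + exceed) / (1 + nPerm)
  diag(p) <- NA_real_
  q <- p
  ut <- upper.tri(p)
  q[ut] <- bhAdjust(p[ut])
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  dimnames(p) <- dimnames(q) <- dimnames(rhoObs)
  list(rho = rhoObs, p = p, q = q)
}

#' Threshold a correlation matrix into a network edge list
#'
#' Edges are pairs with `|rho| > rThreshold` and `q < qThreshold`. The
#' default thresholds follow the network construction rule FDR q < 0.05 and
#' |r| > 0.35; a stricter |r| > 0.45 variant is a common alternative.
#'
#' @param rho,q symmetric correlation and BH-adjusted p matrices.
#' @param rThreshold minimum |rho| (default 0.35).
#' @param qThreshold maximum q (default 0.05).
#' @return data.frame with columns `source`, `target`, `rho`, `q`, `sign`.
#' @export
buildNetwork <- function(rho, q, rThreshold = 0.35, qThreshold = 0.05) {
  ids <- rownames(rho)
  if (is.null(ids)) ids <- paste0("taxon", seq_len(nrow(rho)))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  keep <- abs(rho[ut]) > rThreshold & !is.na(q[ut]) & q[ut] < qThreshold
  ut <- ut[keep, , drop = FALSE]
  data.frame(source = ids[ut[, 1]], target = ids[ut[, 2]],
             rho = rho[ut], q = q[ut],
             sign = ifelse(rho[ut] >= 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' PERMANOVA of a distance matrix against group labels
#'
#' Permutational multivariate analysis of variance via [vegan::adonis2()],
#' returning the pseudo-F and permutation p-value. Deterministic under
#' `seed`.
#'
#' @param d a `dist` or symmetric distance matrix.
#' @param labels group labels (one per object).
#' @param nPerm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list with `F` and `p`.
#' @export
permanovaDistance <- function(d, labels, nPerm = 999, seed = 1) {
  d <- as.dist(d)
  grp <- factor(labels)
  df <- data.frame(grp = grp)
  fit <- .withSeed(seed, vegan::adonis2(d ~ grp, data = df,
                                        permutations = nPerm))
  list(F = fit$F[1], p = fit$`Pr(>F)`[1])
}

#' Define co-abundance groups by Ward clustering with PERMANOVA support
#'
#' Converts the SparCC matrix to the dissimilarity `d = 1 - rho`, cuts a
#' Ward-linkage dendrogram into `k` groups, and tests the partition with
#' PERMANOVA on `d` (999 permutations by default). Labels are `supported`
#' when the PERMANOVA p is below 0.05.
#'
#' @param rho symmetric SparCC correlation matrix.
#' @param k number of CAGs (default 2).
#' @param nPerm PERMANOVA permutations (default 999).
#' @param seed RNG seed for the permutation stream.
#' @return list with `cagLabels` (factor `CAG1..CAGk` named by taxon),
#'   `permanovaF`, `permanovaP`, `supported`.
#' @export
defineCags <- function(rho, k = 2, nPerm = 999, seed = 1) {
  if (k >= nrow(rho)) stop("k must be smaller than the number of taxa",
                           call. = FALSE)
  d <- 1 - rho
  hc <- hclust(as.dist(d), method = "ward.D2")
  raw <- cutree(hc, k = k)
  labels <- factor(paste0("CAG", raw), levels = paste0("CAG", seq_len(k)))
  names(labels) <- rownames(rho)
  pm <- permanovaDistance(d, labels, nPerm = nPerm, seed = seed)
  list(cagLabels = labels, permanovaF = pm$F, permanovaP = pm$p,
       supported = pm$p < 0.05)
}

#' Spearman correlation of CAG abundances with the residual phenotype
#'
#' A CAG's per-sample abundance is the sum of its member taxa's fractions;
#' each CAG is correlated with the residual phenotype by Spearman's rank
#' correlation (average ranks for ties), with BH correction across CAGs.
#'
#' @param cagLabels factor of CAG memberships named by taxon id.
#' @param x a [MicrobiomeExperiment-class] or samples x taxa fraction matrix
#'   containing those taxa.
#' @param pheno optional phenotype (see [twoPartScan()]).
#' @return data.frame with columns `cag`, `nTaxa`, `rho`, `p`, `q`.
#' @export
cagPhenotypeCorrelation <- function(cagLabels, x, pheno = NULL) {
  F <- .fractionMatrix(x)
  y <- .residualVector(x, pheno)
  taxa <- names(cagLabels)
  if (is.null(taxa) || !all(taxa %in% colnames(F))) {
    stop("cagLabels must be named by taxon ids present in x", call. = FALSE)
  }
  out <- do.call(rbind, lapply(levels(cagLabels), function(g) {
    members <- taxa[cagLabels == g]
    ab <- rowSums(F[, members, drop = FALSE])
    ct <- suppressWarnings(cor.test(ab, y, method = "spearman"))
    data.frame(cag = g, nTaxa = length(members),
               rho = unname(ct$estimate), p = ct$p.value,
               stringsAsFactors = FALSE)
  }))
  out$q <- bhAdjust(out$p)
  out
}

#' Full co-abundance network analysis
#'
#' Orchestrates [sparccPvalues()], [buildNetwork()], [defineCags()] and (when
#' a residualized phenotype is available) [cagPhenotypeCorrelation()] into a
#' single [CorrelationNetwork-class] object.
#'
#' @param x a [MicrobiomeExperiment-class] or samples x taxa count matrix.
#' @param pheno optional phenotype (see [twoPartScan()]); when neither `x`
#'   nor `pheno` carries residuals, the CAG-phenotype step is skipped.
#' @param subsetTaxa optional taxon ids to restrict the network to (e.g. the
#'   phenotype-associated taxa).
#' @param nPerm correlation permutations (default 100).
#' @param rThreshold,qThreshold edge thresholds (defaults 0.35 and 0.05).
#' @param k number of CAGs (default 2).
#' @param permanovaPerm PERMANOVA permutations (default 999).
#' @param seed RNG seed.
#' @param ... passed to [sparcc()].
#' @return A [CorrelationNetwork-class].
#' @export
coabundanceNetwork <- function(x, pheno = NULL, subsetTaxa = NULL,
                               nPerm = 100, rThreshold = 0.35,
                               qThreshold = 0.05, k = 2, permanovaPerm = 999,
                               seed = 1, ...) {
  me <- x
  if (!is.null(subsetTaxa)) {
    if (is(me, "SummarizedExperiment")) {
      me <- me[subsetTaxa, ]
    } else {
      me <- me[, subsetTaxa, drop = FALSE]
    }
  }
  cnt <- if (is(me, "SummarizedExperiment")) t(counts(me)) else as.matrix(me)
  sp <- sparccPvalues(cnt, nPerm = nPerm, seed = seed, ...)
  edg <- buildNetwork(sp$rho, sp$q, rThreshold, qThreshold)
  cg <- defineCags(sp$rho, k = k, nPerm = permanovaPerm,
                   seed = .subSeed(seed, 7))
  cc <- data.frame()
  hasResid <- !is.null(pheno) ||
    (is(x, "SummarizedExperiment") &&
       "residual" %in% colnames(SummarizedExperiment::colData(x)))
  if (hasResid) {
    cc <- cagPhenotypeCorrelation(cg$cagLabels, x, pheno)
  }
  methods::new("CorrelationNetwork",
    taxonIds = rownames(sp$rho), rho = sp$rho, p = sp$p, q = sp$q,
    edges = edg, cagLabels = cg$cagLabels,
    permanovaF = cg$permanovaF, permanovaP = cg$permanovaP,
    cagCorrelations = cc, rThreshold = rThreshold, qThreshold = qThreshold)
}
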