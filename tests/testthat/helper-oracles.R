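# Brute-force oracles, independent of the package implementation.

# Exhaustive two-sided Mann-Whitney p over all C(n1+n2, n1) group splits.
wilcoxOracle <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  r <- rank(c(x, y))
  splits <- utils::combn(nx + ny, nx)
  Ud <- apply(splits, 2, function(s) sum(r[s]) - nx * (nx + 1) / 2)
  Uobs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(Ud <= Uobs + 1e-9), mean(Ud >= Uobs - 1e-9)))
}

# Exhaustive two-sided Spearman p over all n! rank pairings.
spearmanOracle <- function(x, y) {
  rx <- rank(x)
  ry <- rank(y)
  obs <- stats::cor(rx, ry)
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(permute(v[-i]), function(p) c(v[i], p))
    }))
  }
  rhos <- vapply(permute(seq_along(x)),
                 function(p) stats::cor(rx, ry[p]), numeric(1))
  min(1, 2 * min(mean(rhos <= obs + 1e-9), mean(rhos >= obs - 1e-9)))
}

# Average-rank Spearman rho computed from first principles.
spearmanRhoOracle <- function(x, y) stats::cor(rank(x), rank(y))

# PERMANOVA pseudo-F from squared inter-object distances.
permanovaFOracle <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- factor(labels)
  k <- nlevels(labels)
  sst <- sum(d[upper.tri(d)]^2) / n
  ssw <- sum(vapply(levels(labels), function(g) {
    idx <- which(labels == g)
    dg <- d[idx, idx, drop = FALSE]
    sum(dg[upper.tri(dg)]^2) / length(idx)
  }, numeric(1)))
  ((sst - ssw) / (k - 1)) / (ssw / (n - k))
}

# Exhaustive PERMANOVA p over every relabelling (including the identity).
permanovaPOracle <- function(d, labels) {
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(permute(v[-i]), function(p) c(v[i], p))
    }))
  }
  Fobs <- permanovaFOracle(d, labels)
  Fs <- vapply(permute(seq_along(labels)),
               function(p) permanovaFOracle(d, labels[p]), numeric(1))
  mean(Fs >= Fobs - 1e-9)
}

# Least squares through the normal equations with a pseudo-inverse.
residualOracle <- function(y, X) {
  sv <- svd(X)
  keep <- sv$d > max(sv$d) * 1e-10
  beta <- sv$v[, keep, drop = FALSE] %*%
    ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
  as.numeric(y - X %*% beta)
}
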