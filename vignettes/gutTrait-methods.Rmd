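---
title: "Methods: two-part microbiome-phenotype association, microbiability and co-abundance networks"
author: "gutTrait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-part microbiome-phenotype association, microbiability and co-abundance networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
defaults it ships, the numerical choices behind them, and what the synthetic
data generator does and does not emulate.

## Setting

The target design is a small livestock cohort — on the order of a hundred
animals — with a per-animal production phenotype (finishing weight, in
grams), sex and cage covariates, a 16S-style taxon count table, fecal SCFA
concentrations (acetate, propionate, butyrate, mM), and a nested
extreme-group comparison in which only the five heaviest and five lightest
animals receive deeper profiling. All analyses operate on the *residualized*
phenotype: an ordinary least-squares fit of weight on the indicator
expansions of sex and cage, whose residuals carry the microbial association
testing. Rank-deficient covariate designs are handled by the pivoting QR
solver; a covariate level observed once absorbs its own residual to zero
and is flagged, because such observations contribute no information
downstream.

## Preprocessing

* **Rarefaction** (`rarefyCounts()`): subsampling without replacement
  (multivariate hypergeometric, via `vegan::rrarefy`) to a common depth,
  default 40,000 reads; samples below depth are dropped with a warning.
  Without-replacement subsampling matches the semantics of discarding
  surplus reads; a multinomial draw would add resampling noise to abundant
  taxa.
* **Closure** (`toRelative()`): per-sample division by the library size.
  All-zero samples are rejected as upstream errors.
* **Filtering** (`filterTaxa()`): retain taxa with mean relative abundance
  ≥ 0.1% *and* presence in at least `ceiling(0.01 · n)` samples. The
  abundance summary is the mean across all samples (a per-taxon maximum is
  available via `method = "max"`); the prevalence rule uses a strict
  count > 0 definition of presence. With 105 samples the 1% prevalence rule
  means presence in ≥ 2 animals. The default order is rarefy → closure →
  filter; the steps are plain functions, so any other order is one line
  away.
* **Presence** is defined once — count > 0 on the table entering the
  analysis — and reused by every downstream feature definition.

## The two-part model

For taxon $j$ with relative abundance $f_{ij}$ in sample $i$:

$$b_{ij} = \mathbf{1}[f_{ij} > 0], \qquad
q_{ij} = \begin{cases}
 (\log f_{ij} - \mu_j)/\sigma_j & b_{ij} = 1 \\
 0 & b_{ij} = 0
\end{cases}$$

where $\mu_j, \sigma_j$ are the mean and *population* (divide-by-$n$) SD of
$\log f_{ij}$ over the present samples. The population-SD convention makes
tiny carrier sets well defined and gives $\sum_i q_{ij}^2 = n_j$ (present
count), which the closed-form scan exploits.

Three analyses per taxon, on the residualized phenotype $y$:

1. **Binary**: OLS slope $\beta_1$ of $y$ on $b$, two-sided t-test.
   The phrase "binomial analysis" admits a logistic reading (presence on
   phenotype); the linear reading was chosen because the additive predictor
   below needs $\beta_1$ in phenotype units, and under permutation
   calibration the two give near-identical rankings.
2. **Quantitative**: OLS slope $\beta_2$ of $y$ on $q$ restricted to
   present samples; requires at least 4 carriers (`minPresent`, the point
   below which a slope t-test is vacuous).
3. **Meta**: Stouffer weighted-Z combining the two component z-scores with
   weights $\sqrt{n}$ and $\sqrt{n_j}$. Stouffer was preferred over
   inverse-variance weighting because the components are slope tests on
   different scales; only their z-scores are commensurable.

$p_\text{final}$ is the minimum of the defined component p-values. Because
a minimum of three dependent tests is anti-conservative and the residuals
may be skewed, $p_\text{final}$ is calibrated by `B` phenotype
permutations (default 1000): the *same* permutations are reused for every
taxon — preserving the between-taxon dependence and making the scan
deterministic under its seed — and

$$p_\text{perm} = \frac{1 + \#\{\min\text{-}p^{(b)} \le \min\text{-}p\}}{1 + B},$$

with the +1 correction so no p-value is ever zero. Shuffling the phenotype
(rather than each taxon vector) keeps the taxon correlation structure
intact. BH FDR is applied to $p_\text{perm}$ across taxa
(`fdrOn = "pFinal"` is available); taxa degenerate in all three analyses
are flagged and excluded from the FDR family size.

Component t statistics are mapped to z-scores through log-scale tail
probabilities (`pt(..., log.p = TRUE)` → `qnorm(..., log.p = TRUE)`), so
extreme associations do not underflow before the meta-combination.

## Microbiability

The additive microbial predictor for sample $i$ is

$$r_{m,i} = \sum_{j \in S(t)} \left(\beta_{1j} b_{ij} + \beta_{2j} q_{ij}\right),$$

where $S(t)$ are the taxa with discovery p-value ≤ $t$ and all parameters —
effects *and* the $(\mu_j, \sigma_j)$ standardization of $q$ — come from the
discovery split. `estimateVarianceExplained()` repeats an 80/20 random
split (default 100 times), scans the discovery split, and reports per
threshold (default grid $10^{-5}, 10^{-4}, 10^{-3}, 0.01, 0.05, 0.1$) the
mean and SD of the validation $R^2$ = squared Pearson correlation between
$r_m$ and the residual phenotype, plus the mean number of selected taxa.
Conventions: empty selections and constant $r_m$ contribute $R^2 = 0$
(predictive failure is counted, not dropped); selection uses
$p_\text{final}$ in the default fast mode (`BInner = 0`) and the
permutation-corrected p when `BInner > 0` (200 is a practical inner count).

**Known limitation — closure attenuation.** Relative-abundance features
share the composition's denominator: every $q_{ij}$ contains
$-\log \sum_k W_{ik}$. When the causal effect sizes share a sign this
common term correlates *every* taxon with the phenotype, so single-taxon
(marginal) effect estimates are misweighted and the additive predictor's
validation $R^2$ plateaus well below the true microbial variance share even
as noise vanishes; sign-balanced effect sets largely cancel the shared term
and recover most of it. This is a property of marginal additive models on
compositions, not of the implementation — the package's recovery tests
quantify it, and users should read absolute microbiability estimates as
lower bounds under same-sign effect regimes.

## SparCC and co-abundance groups

With $T_{ij} = \mathrm{var}\log(x_i/x_j)$ and basis (latent) variances
$\omega$, SparCC uses
$T_{ij} = \omega_i + \omega_j - 2\rho_{ij}\sqrt{\omega_i\omega_j}$ and the
sparsity approximation $\sum_j \rho_{ij} \approx 0$, giving the linear
system $\left[(m-2)I + J\right]\omega = t$ with $t_i = \sum_{j\ne i} T_{ij}$.
After solving, the strongest pair with $|\rho|$ above the exclusion
threshold (default 0.1) is removed from the system and it is re-solved, up
to 10 exclusions (pairs whose removal would degenerate a taxon's equation
are skipped); non-positive basis variances are floored at the smallest
positive solution. Fractions are drawn per outer iteration from the
per-sample Dirichlet posterior with unit prior (default, 20 iterations,
element-wise median — the robust aggregation), or deterministically via
multiplicative zero replacement at half the sample's smallest nonzero
fraction. The deterministic mode is *exactly* invariant to per-sample count
rescaling, because it depends on the counts only through the closed
fractions; the Dirichlet posterior, by contrast, deliberately encodes
sequencing depth, so its estimates are only asymptotically scale-free.

Significance: each taxon's counts are independently permuted across samples
`nPerm` times (default 100), the matrix re-estimated, and two-sided
pseudo-p values floored at $1/(n_\text{perm}+1)$; BH runs over the upper
triangle. Edges require $|\rho| > 0.35$ and $q < 0.05$ (the stricter 0.45
variant used for visualization-grade networks is a parameter away).

CAGs: Ward-linkage (`ward.D2`) clustering of $d = 1 - \rho$ — chosen as the
simplest dissimilarity monotone in $\rho$ — cut at $k = 2$ (two groups is
the canonical outcome for a trait-associated taxon set split by effect
direction; any $k$ below the taxon count is accepted), validated by
PERMANOVA on $d$ with 999 permutations via `vegan::adonis2`. Given the
distance matrix, the dendrogram and cut are fully deterministic. CAG
abundance is the summed member fraction per sample; CAG-phenotype
association uses Spearman's rank correlation with BH across CAGs.

## Extreme-group contrasts

`selectExtremes()` takes the top and bottom `nPerGroup` (default 5) by
phenotype, breaking boundary ties by sample id and reporting that a tie
occurred. Feature contrasts use the exact Wilcoxon rank-sum distribution
whenever the combined sample is small and untied (the normal approximation
is poor at 5 vs 5) and the tie-corrected normal approximation otherwise;
SCFA contrasts use the classical equal-variance two-sample t (Welch by
option) — the literal reading of "Student's t-test"; taxon-SCFA screens use
average-rank Spearman with exact small-sample p-values. Each operation
applies BH within its own call — features within one table; all
feature × analyte pairs jointly — a scoping choice that is documented
rather than universal.

## The synthetic generator

`simulateCounts()` draws a latent log-normal basis per taxon (means
$\mathcal{N}(0, 1.5^2)$, log-SDs $\mathcal{U}(0.5, 1.5)$ — heavy-tailed
abundance heterogeneity typical of 16S surveys), imposes any configured
pairwise basis correlations through a Cholesky factor (non-positive-definite
requests are rejected as invalid configurations), applies per-taxon
Bernoulli structural presence masks with probabilities drawn from the
prevalence range, closes to compositions, and samples counts multinomially
at Poisson library sizes. Zeros therefore arise both structurally and from
sampling, which is what the two-part model is built for.

`simulatePhenotype()` builds
$y = \text{intercept} + \text{sex} + \text{cage} + \sum_c (\beta_{1c} b_c + \beta_{2c} q_c) + \varepsilon$
using exactly the downstream feature definitions, and can rescale the
summed microbial term so its realized variance share equals a target
fraction. `simulateScfa()` makes butyrate a noisy linear function of summed
producer abundance and the other two analytes independent noise at
realistic fecal concentrations.

Defaults describe the emulated study: 105 animals, a 50-taxon panel (the
scale at which the network analyses operate), Poisson(50,000) depths with
40,000-read rarefaction, structural prevalences 0.4–0.95, five causal taxa
with alternating-sign unit effects rescaled to a 10% microbial variance
share (the magnitude such cohorts report), a 50 g sex effect, 30 g cage-
block SD, 150 g residual SD around a 2500 g mean. One deliberate divergence
from the real design: housing one animal per cage confounds cage with
individual, so synthetic cages are blocks of five (configurable) to keep
residualization estimable. The generator does not emulate sequencing reads,
taxonomy, real phenotype distributions beyond a Gaussian, or
prevalence-abundance coupling; passing tests therefore demonstrate correct
machinery under the stated statistical structure, not robustness to every
property of real surveys.

All three generators, the scan, the cross-validation, SparCC and the
pipeline restore the caller's RNG state and are bit-reproducible under
their seeds; derived seeds keep every stage's stream independent.

## Problem sizes used by the test suite

The suite exercises calibration at 200 taxa × 300 samples with 1000
permutations, recovery at 5 planted 1-SD effects (n = 300), microbiability
at n = 500 with 100 cross-validation repeats in fast mode, SparCC fidelity
at 50 taxa × 500 samples, CAG recovery on a 10+10-taxon two-block design,
and byte-identity of two full pipeline runs — sizes chosen so the whole
suite completes in about a minute on one core while keeping the binomial
bands on the calibration checks meaningful.
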