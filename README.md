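# gutTrait

Association analysis between the gut microbiome and a quantitative host
phenotype, built for small-cohort livestock studies in which finishing
weight (or a similar production trait) is measured alongside 16S/metagenomic
count tables and fecal short-chain fatty acid (SCFA) concentrations. The
package bundles four analyses that are usually scattered across ad hoc
scripts:

1. **Two-part association model.** Each taxon's zero-inflated relative
   abundance is split into a binary feature `b` (presence/absence) and a
   quantitative feature `q` (log relative abundance standardized among the
   samples where the taxon is present, 0 elsewhere). The residualized
   phenotype `y` (after OLS correction for sex and cage) is tested three
   ways per taxon:

   - binary: OLS of `y` on `b`, two-sided t-test on the slope `β₁`;
   - quantitative: OLS of `y` on `q` restricted to present samples, slope `β₂`;
   - meta: Stouffer weighted-Z, `Z = (√n_b·z_b + √n_q·z_q)/√(n_b + n_q)`.

   The per-taxon p-value is `p_final = min(p_b, p_q, p_meta)`; min-p
   selection and residual skewness are corrected by `B = 1000` phenotype
   permutations (`p_perm = (1 + #{min-p* ≤ min-p})/(1 + B)`), and BH FDR is
   applied across taxa.

2. **Microbiability (variance explained by the microbiome).** Repeated
   80/20 cross-validation: taxa passing a discovery p-value threshold
   contribute `β₁·b + β₂·q` to the additive predictor
   `r_m = Σ_j (β₁ⱼ·b_j + β₂ⱼ·q_j)`; the validation `R²` is the squared
   Pearson correlation between `r_m` and the residual phenotype, averaged
   over 100 repeats per threshold (default grid `10⁻⁵ … 0.1`).

3. **Co-abundance groups (CAGs).** SparCC correlations of the associated
   taxa (log-ratio variances under the sparsity approximation, strongest
   pairs iteratively excluded, median over 20 Dirichlet-posterior
   resamplings), permutation pseudo-p values with BH correction, network
   edges at `|r| > 0.35` and `q < 0.05`, Ward-linkage clustering of
   `d = 1 − ρ` validated by PERMANOVA (999 permutations), and Spearman
   correlation of CAG abundances with the phenotype.

4. **Extreme-group contrasts.** Top-5/bottom-5 phenotype groups; Wilcoxon
   rank-sum with FDR for feature tables (exact for the tiny group sizes),
   two-sided unpaired Student's t with FDR for SCFA levels, and Spearman
   correlations with FDR between taxa and SCFAs.

A synthetic-data module (`simulationConfig()`, `simulateCounts()`,
`simulatePhenotype()`, `simulateScfa()`) generates zero-inflated
compositional counts from a log-normal latent basis with structural
presence masks, a phenotype receiving additive `(b, q)` effects from a
configurable causal taxon set (optionally rescaled to a target share of
phenotypic variance), and SCFA profiles with a planted butyrate-producer
link — so the whole pipeline is testable end-to-end with no external data.

## Worked example

```r
library(gutTrait)

cfg <- simulationConfig(seed = 7)      # 105 samples, 50 taxa, 10% microbial
me  <- simulateCounts(cfg)             #   variance share, 5 causal taxa
me  <- simulatePhenotype(me, cfg)
me  <- rarefyCounts(me, depth = 40000, seed = 7)
me  <- filterTaxa(toRelative(me))      # mean abundance >= 0.1%, prevalence >= 1%
me  <- residualizeWeight(me)           # OLS on sex + cage
me
#> MicrobiomeExperiment: 46 taxa x 105 samples
#>   assays: counts, fractions
#>   colData: weight, sex, cage, residual
#>   metadata: simulation, phenotype, filterReport

twoPartScan(me, B = 1000, seed = 7)
#> TwoPartResult: 46 taxa, 105 samples, B = 1000 permutations
#>   taxa with FDR q < 0.05: 0
#>   top taxa by permutation p:
#>    taxon  beta1  beta2  pFinal   pPerm qValue
#>  OTU0018 -114.3   6.72 0.00126 0.00200 0.0919
#>  OTU0003   49.4  41.11 0.00359 0.00899 0.2068
#>  OTU0045  -75.3 -10.85 0.01163 0.02398 0.2573
#>  OTU0038   73.9   4.46 0.01026 0.02797 0.2573
#>  OTU0004  -68.4 -13.44 0.01121 0.02797 0.2573

estimateVarianceExplained(me, nRepeats = 50, seed = 7)
#> VarianceExplained: 50 repeats, 80%/20% discovery/validation split
#>  threshold    meanR2     sdR2 meanNSelected
#>      1e-05 0.0000000 0.000000          0.00
#>      1e-04 0.0004162 0.002234          0.04
#>      1e-03 0.0040301 0.009954          0.28
#>      1e-02 0.0376085 0.039599          2.66
#>      5e-02 0.0610516 0.069418          8.46
#>      1e-01 0.0757559 0.088117         13.14
```

Reading the output: `beta1` is the phenotype shift (here grams of finishing
weight) associated with the taxon's presence, `beta2` the shift per SD of
its log abundance among carriers; `pPerm` is the permutation-corrected
min-p and `qValue` its BH adjustment. At this cohort size (105 animals,
~10% true microbial variance share) no taxon clears `q < 0.05` and the
cross-validated `R²` rises with the selection threshold to ~0.08 — the
small-cohort behaviour the method is designed to quantify rather than hide.
Two of the five planted causal taxa (`OTU0003`, `OTU0004`) already sit in
the top five.

`runPipeline(cfg, dir)` executes every stage (including the SparCC/CAG
network on the associated taxa and the high/low-group contrasts) and writes
deterministic tab-delimited outputs plus JSON sidecars.

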