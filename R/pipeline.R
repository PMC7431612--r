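# End-to-end synthetic-study workflow: generate data, preprocess, run the
# two-part scan, estimate variance explained, build the co-abundance network
# on the associated taxa, and run the high/low group contrasts. All outputs
# are written as tab-delimited text (plus JSON sidecars) so that two runs
# with the same seed are byte-identical.

#' Run the full analysis pipeline on a synthetic study
#'
#' Generates a synthetic cohort from `config`, rarefies, converts to relative
#' abundances, filters rare taxa, residualizes the phenotype, and runs the
#' two-part association scan, the cross-validated variance-explained
#' estimate, the SparCC/CAG network on the phenotype-associated taxa, and the
#' high/low group contrasts (SCFA t-tests, feature Wilcoxon tests,
#' species-SCFA Spearman correlations). Every stage's result is written under
#' `dir` as deterministic tab-delimited text or JSON.
#'
#' @param config a [SimulationConfig-class] (defaults: [simulationConfig()]).
#' @param dir output directory (created if needed).
#' @param B permutations for the association scan (default 200).
#' @param depth rarefaction depth (default 80% of the mean library size).
#' @param mveRepeats cross-validation repeats (default 20).
#' @param scfaEffect planted butyrate effect per SD of producer abundance.
#' @param networkPerm correlation permutations for the network (default 100).
#' @param seed master seed; every stochastic stage derives its stream from it.
#' @return Invisibly, a list with the result objects and output paths.
#' @export
runPipeline <- function(config = simulationConfig(), dir = tempfile("study"),
                        B = 200, depth = floor(0.8 * config@librarySizeMean),
                        mveRepeats = 20, scfaEffect = 1, networkPerm = 100,
                        seed = config@seed) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(dir, f)

  ## generate
  me <- simulateCounts(config)
  me <- simulatePhenotype(me, config)
  truth <- S4Vectors::metadata(me)$phenotype
  producers <- truth$causalTaxa[truth$beta1 > 0]
  if (!length(producers)) producers <- utils::head(rownames(me), 1)
  scfa <- simulateScfa(me, producers, effect = scfaEffect,
                       seed = .subSeed(seed, 2))
  writeCountTable(me, path("counts.tsv"))
  writeScfaTable(scfa, path("scfa.tsv"))
  writeSimulationTruth(me, path("truth.json"))

  ## preprocess
  me <- rarefyCounts(me, depth = depth, seed = .subSeed(seed, 3))
  me <- toRelative(me)
  me <- filterTaxa(me)
  me <- residualizeWeight(me)
  writePhenotypeTable(me, path("phenotype.tsv"))
  jsonlite::write_json(S4Vectors::metadata(me)$filterReport,
                       path("filter_report.json"), auto_unbox = TRUE)

  ## two-part association scan
  assoc <- twoPartScan(me, B = B, seed = .subSeed(seed, 4))
  writeAssociationTable(assoc, path("association.tsv"))

  ## variance explained
  mve <- estimateVarianceExplained(me, nRepeats = mveRepeats,
                                   seed = .subSeed(seed, 5))
  utils::write.table(varianceTable(mve), path("variance_explained.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## co-abundance network on the associated taxa
  tab <- associationTable(assoc)
  netTaxa <- tab$taxon[!is.na(tab$qValue) & tab$qValue < 0.05]
  if (length(netTaxa) < 5) {
    ord <- order(tab$pPerm, tab$pFinal, tab$taxon)
    netTaxa <- utils::head(tab$taxon[ord], 20)
  }
  net <- coabundanceNetwork(me, subsetTaxa = netTaxa, nPerm = networkPerm,
                            seed = .subSeed(seed, 6))
  utils::write.table(edges(net), path("network_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  memb <- data.frame(taxon = names(cagLabels(net)),
                     cag = as.character(cagLabels(net)))
  utils::write.table(memb, path("cag_membership.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cagCorrelations(net), path("cag_correlations.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## high/low group contrasts
  design <- selectExtremes(me, nPerGroup = 5)
  utils::write.table(design, path("group_design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scfaTest <- ttestFdr(scfa, design)
  utils::write.table(scfaTest, path("scfa_ttest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  wil <- wilcoxonFdr(me, design)
  utils::write.table(wil, path("wilcoxon_high_low.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  assocTaxa <- intersect(netTaxa, rownames(me))
  spr <- spearmanFdr(t(fractions(me))[, assocTaxa, drop = FALSE], scfa)
  utils::write.table(spr, path("species_scfa_spearman.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  invisible(list(
    experiment = me, scfa = scfa, association = assoc,
    varianceExplained = mve, network = net, design = design,
    scfaTest = scfaTest, wilcoxon = wil, spearman = spr,
    files = list.files(dir, full.names = TRUE)))
}
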