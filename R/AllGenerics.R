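#' Accessors for gutTrait result objects
#'
#' `associationTable()` returns the per-taxon data.frame of a
#' [TwoPartResult-class]; `varianceTable()` the threshold table of a
#' [VarianceExplained-class]; `edges()`, `cagLabels()` and
#' `cagCorrelations()` the corresponding pieces of a
#' [CorrelationNetwork-class]; `fractions()` the relative-abundance assay of a
#' [MicrobiomeExperiment-class] (computing it on the fly when only counts are
#' stored).
#'
#' @param x a gutTrait result object.
#' @return The requested component (data.frame, matrix or factor).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("associationTable", function(x) standardGeneric("associationTable"))

#' @rdname accessors
#' @export
setGeneric("varianceTable", function(x) standardGeneric("varianceTable"))

#' @rdname accessors
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname accessors
#' @export
setGeneric("cagLabels", function(x) standardGeneric("cagLabels"))

#' @rdname accessors
#' @export
setGeneric("cagCorrelations", function(x) standardGeneric("cagCorrelations"))

#' @rdname accessors
#' @export
setGeneric("fractions", function(x) standardGeneric("fractions"))

#' @rdname accessors
#' @export
setMethod("associationTable", "TwoPartResult", function(x) x@results)

#' @rdname accessors
#' @export
setMethod("varianceTable", "VarianceExplained", function(x) x@table)

#' @rdname accessors
#' @export
setMethod("edges", "CorrelationNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setMethod("cagLabels", "CorrelationNetwork", function(x) x@cagLabels)

#' @rdname accessors
#' @export
setMethod("cagCorrelations", "CorrelationNetwork", function(x) x@cagCorrelations)

#' @rdname accessors
#' @export
setMethod("fractions", "MicrobiomeExperiment", function(x) {
  an <- SummarizedExperiment::assayNames(x)
  if ("fractions" %in% an) {
    return(SummarizedExperiment::assay(x, "fractions"))
  }
  cnt <- SummarizedExperiment::assay(x, "counts")
  cs <- colSums(cnt)
  if (any(cs == 0)) {
    stop("all-zero sample(s): ", paste(colnames(x)[cs == 0], collapse = ", "),
         call. = FALSE)
  }
  sweep(cnt, 2, cs, `/`)
})

#' @describeIn MicrobiomeExperiment-class the raw count assay (taxa x samples).
#' @param object a `MicrobiomeExperiment`.
#' @importMethodsFrom BiocGenerics counts
#' @export
setMethod("counts", "MicrobiomeExperiment", function(object) {
  SummarizedExperiment::assay(object, "counts")
})

setMethod("show", "MicrobiomeExperiment", function(object) {
  cat("MicrobiomeExperiment:", nrow(object), "taxa x", ncol(object), "samples\n")
  cat("  assays:", paste(SummarizedExperiment::assayNames(object), collapse = ", "), "\n")
  cd <- colnames(SummarizedExperiment::colData(object))
  if (length(cd)) cat("  colData:", paste(cd, collapse = ", "), "\n")
  md <- names(S4Vectors::metadata(object))
  if (length(md)) cat("  metadata:", paste(md, collapse = ", "), "\n")
})

setMethod("show", "TwoPartResult", function(object) {
  res <- object@results
  nsig <- sum(res$qValue < 0.05, na.rm = TRUE)
  cat("TwoPartResult:", nrow(res), "taxa,", object@nSamples, "samples, B =",
      object@B, "permutations\n")
  cat("  taxa with FDR q < 0.05:", nsig, "\n")
  top <- utils::head(res[order(res$pPerm, res$pFinal), ], 5)
  cat("  top taxa by permutation p:\n")
  print(top[, c("taxon", "beta1", "beta2", "pFinal", "pPerm", "qValue")],
        row.names = FALSE, digits = 3)
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat("CorrelationNetwork:", length(object@taxonIds), "taxa,",
      nrow(object@edges), "edges (|r| >", object@rThreshold, ", q <",
      object@qThreshold, ")\n")
  if (length(object@cagLabels)) {
    cat("  CAGs:", paste(sprintf("%s (n=%d)", levels(object@cagLabels),
                                 table(object@cagLabels)), collapse = ", "), "\n")
    cat("  PERMANOVA pseudo-F =", format(object@permanovaF, digits = 4),
        ", p =", format(object@permanovaP, digits = 4), "\n")
  }
  if (nrow(object@cagCorrelations)) {
    cat("  CAG-phenotype Spearman correlations:\n")
    print(object@cagCorrelations, row.names = FALSE, digits = 3)
  }
})

setMethod("show", "VarianceExplained", function(object) {
  cat("VarianceExplained:", object@nRepeats, "repeats,",
      sprintf("%.0f%%/%.0f%%", 100 * object@trainFraction,
              100 * (1 - object@trainFraction)),
      "discovery/validation split\n")
  print(object@table, row.names = FALSE, digits = 4)
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nSamples, "samples x", object@nTaxa, "taxa,",
      object@nCausalTaxa, "causal taxa, seed", object@seed, "\n")
  tv <- object@targetMicrobialVarianceFraction
  if (!is.na(tv)) cat("  target microbial variance fraction:", tv, "\n")
})
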