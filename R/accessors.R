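# Accessor generics and show methods for the core classes.

#' @rdname LipidFeatureSet-class
#' @param object,x a `LipidFeatureSet`
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("featureIds", "LipidFeatureSet", function(x) rownames(x))

#' @rdname LipidFeatureSet-class
#' @export
setGeneric("featureMz", function(x) standardGeneric("featureMz"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("featureMz", "LipidFeatureSet", function(x)
  setNames(SummarizedExperiment::rowData(x)$mz, rownames(x)))

#' @rdname LipidFeatureSet-class
#' @export
setGeneric("featureRt", function(x) standardGeneric("featureRt"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("featureRt", "LipidFeatureSet", function(x)
  setNames(SummarizedExperiment::rowData(x)$rt, rownames(x)))

#' @rdname LipidFeatureSet-class
#' @export
setGeneric("neutralMass", function(x) standardGeneric("neutralMass"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("neutralMass", "LipidFeatureSet", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!"neutral_mass" %in% colnames(rd)) return(NULL)
  setNames(rd$neutral_mass, rownames(x))
})

#' @rdname LipidFeatureSet-class
#' @export
setGeneric("isGrouped", function(x) standardGeneric("isGrouped"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("isGrouped", "LipidFeatureSet", function(x) x@grouped)

#' @rdname LipidFeatureSet-class
#' @export
setGeneric("ionPolarity", function(x) standardGeneric("ionPolarity"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("ionPolarity", "LipidFeatureSet", function(x) x@polarity)

#' @rdname LipidFeatureSet-class
#' @export
setGeneric("intensityMatrix", function(x) standardGeneric("intensityMatrix"))
#' @rdname LipidFeatureSet-class
#' @export
setMethod("intensityMatrix", "LipidFeatureSet", function(x)
  SummarizedExperiment::assay(x, "intensity"))

setMethod("show", "LipidFeatureSet", function(object) {
  cat("LipidFeatureSet:", nrow(object), "features x", ncol(object),
      "samples\n")
  cat("  polarity:", object@polarity,
      if (object@grouped) "(grouped analytes)" else "(ungrouped ions)", "\n")
  cat("  rt range:", paste(round(range(featureRt(object)), 1),
                           collapse = " - "), "s;  m/z range:",
      paste(round(range(featureMz(object)), 4), collapse = " - "), "\n")
  miss <- mean(is.na(intensityMatrix(object)))
  cat(sprintf("  missing intensities: %.1f%%\n", 100 * miss))
})

#' @rdname LipidDatabase-class
#' @param x,object a `LipidDatabase`
#' @export
setGeneric("dbEntries", function(x) standardGeneric("dbEntries"))
#' @rdname LipidDatabase-class
#' @export
setMethod("dbEntries", "LipidDatabase", function(x) x@entries)

#' @rdname LipidDatabase-class
#' @export
setGeneric("dbOntology", function(x) standardGeneric("dbOntology"))
#' @rdname LipidDatabase-class
#' @export
setMethod("dbOntology", "LipidDatabase", function(x) x@ontology)

setMethod("show", "LipidDatabase", function(object) {
  e <- object@entries
  cat("LipidDatabase:", nrow(e), "entries,",
      length(unique(e$subclass)), "subclasses,",
      length(unique(e$main_class)), "main classes\n")
  cat("  monoisotopic mass range:",
      paste(round(range(e$monoisotopic_mass), 4), collapse = " - "), "Da\n")
  cat("  logP available for", sum(!is.na(e$logp)), "entries\n")
})

#' @rdname PcorNetwork-class
#' @param x,object a `PcorNetwork`
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname PcorNetwork-class
#' @export
setMethod("networkNodes", "PcorNetwork", function(x) x@nodes)

#' @rdname PcorNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname PcorNetwork-class
#' @export
setMethod("networkEdges", "PcorNetwork", function(x) x@edges)

#' @rdname PcorNetwork-class
#' @export
setGeneric("shrinkageLambda", function(x) standardGeneric("shrinkageLambda"))
#' @rdname PcorNetwork-class
#' @export
setMethod("shrinkageLambda", "PcorNetwork", function(x) x@lambda)

setMethod("show", "PcorNetwork", function(object) {
  cat("PcorNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges\n")
  if (nrow(object@edges))
    cat("  |rho| range:",
        paste(signif(range(abs(object@edges$rho)), 3), collapse = " - "),
        "\n")
  cat("  n samples:", object@nSamples, "; shrinkage lambda:",
      signif(object@lambda, 4), "\n")
})
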