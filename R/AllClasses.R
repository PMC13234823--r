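#' @import methods
#' @importFrom stats approx density dist glm.fit median optimize p.adjust
#'   pbeta pnorm quantile rbinom rnorm runif sd setNames isoreg cmdscale
#'   binomial wilcox.test rexp uniroot
#' @importFrom utils read.delim write.table head
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData
#'   colData "rowData<-"
#' @importFrom S4Vectors DataFrame
#' @useDynLib lipidGGM, .registration = TRUE
NULL

#' Container for an untargeted LC-MS feature table
#'
#' `LipidFeatureSet` extends
#' [SummarizedExperiment::SummarizedExperiment] with the feature-level
#' columns required by network-based lipid class prediction. Rows are
#' detected MS1 features, columns are samples; the single assay
#' `"intensity"` holds raw (non-logged) feature intensities with `NA` for
#' missing (non-detected) cells. Row metadata carry the mass-to-charge
#' ratio (`mz`, Da/e), retention time (`rt`, seconds) and, for grouped
#' (analyte-deconvoluted) tables, the estimated neutral mass
#' (`neutral_mass`, Da).
#'
#' @slot grouped logical; `TRUE` when each row represents a neutral analyte
#'   with an estimated neutral mass rather than a single ion.
#' @slot polarity `"positive"` or `"negative"` ESI mode.
#'
#' @seealso [LipidFeatureSet()] for the constructor,
#'   [readFeatureTable()] for reading delimited text.
#' @export
setClass("LipidFeatureSet",
  contains = "SummarizedExperiment",
  slots = c(grouped = "logical", polarity = "character")
)

setValidity("LipidFeatureSet", function(object) {
  msg <- character()
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("mz", "rt") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain 'mz' and 'rt'")
  if (nrow(object) < 2L || ncol(object) < 2L)
    msg <- c(msg, "feature table needs >= 2 features and >= 2 samples")
  ids <- rownames(object)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "feature ids (rownames) must be present and unique")
  if ("mz" %in% colnames(rd) && any(!is.finite(rd$mz) | rd$mz <= 0))
    msg <- c(msg, "all mz must be finite and > 0")
  if ("rt" %in% colnames(rd) && any(!is.finite(rd$rt) | rd$rt < 0))
    msg <- c(msg, "all rt must be finite and >= 0 (seconds)")
  if (length(object@grouped) != 1L)
    msg <- c(msg, "'grouped' must be a single logical")
  if (isTRUE(object@grouped)) {
    if (!("neutral_mass" %in% colnames(rd)) || anyNA(rd$neutral_mass))
      msg <- c(msg, "grouped tables require a complete 'neutral_mass' column")
  }
  if (!object@polarity %in% c("positive", "negative"))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  a <- SummarizedExperiment::assay(object, "intensity")
  if (any(a < 0, na.rm = TRUE))
    msg <- c(msg, "intensities must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a LipidFeatureSet
#'
#' @param intensities numeric matrix, features x samples; `NA` marks missing
#'   cells (never silently imputed here).
#' @param mz numeric vector of feature m/z values (Da/e, > 0).
#' @param rt numeric vector of retention times (seconds, >= 0).
#' @param neutralMass optional numeric vector of estimated neutral masses
#'   (Da); required when `grouped = TRUE`.
#' @param grouped logical; whether rows are grouped analytes.
#' @param polarity `"positive"` or `"negative"`.
#' @param sampleData optional `data.frame` of per-sample metadata
#'   (phenotype, covariates), rownames matching sample names.
#'
#' @return A validated [LipidFeatureSet-class] object.
#' @examples
#' m <- matrix(rexp(12, 1 / 1e5), nrow = 3,
#'             dimnames = list(paste0("F", 1:3), paste0("S", 1:4)))
#' fs <- LipidFeatureSet(m, mz = c(500.1, 650.2, 799.3), rt = c(60, 120, 180))
#' fs
#' @export
LipidFeatureSet <- function(intensities, mz, rt, neutralMass = NULL,
                            grouped = FALSE, polarity = "positive",
                            sampleData = NULL) {
  intensities <- as.matrix(intensities)
  rd <- S4Vectors::DataFrame(mz = as.numeric(mz), rt = as.numeric(rt))
  if (!is.null(neutralMass)) rd$neutral_mass <- as.numeric(neutralMass)
  cd <- if (is.null(sampleData)) {
    S4Vectors::DataFrame(row.names = colnames(intensities))
  } else {
    S4Vectors::DataFrame(sampleData, row.names = rownames(sampleData))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensities), rowData = rd, colData = cd
  )
  new("LipidFeatureSet", se, grouped = as.logical(grouped),
      polarity = polarity)
}

#' In-memory lipid structure database
#'
#' Tabular equivalent of an LMSD-style structure database: one row per
#' entry with its monoisotopic mass and two-level class ontology
#' (subclass nested in main class), plus an optional logP used by the
#' retention-time consistency filter.
#'
#' @slot entries `data.frame` with columns `entry_id`, `name`, `formula`,
#'   `monoisotopic_mass` (Da), `subclass`, `main_class`, `logp` (may be NA).
#' @slot ontology named character vector mapping subclass -> main class.
#' @seealso [loadLipidDatabase()], [matchFeatures()]
#' @export
setClass("LipidDatabase",
  slots = c(entries = "data.frame", ontology = "character"))

setValidity("LipidDatabase", function(object) {
  e <- object@entries
  msg <- character()
  req <- c("entry_id", "name", "formula", "monoisotopic_mass",
           "subclass", "main_class")
  if (!all(req %in% colnames(e)))
    msg <- c(msg, paste("entries must have columns:",
                        paste(req, collapse = ", ")))
  else {
    if (anyDuplicated(e$entry_id))
      msg <- c(msg, "duplicate entry_id")
    if (any(!is.finite(e$monoisotopic_mass) | e$monoisotopic_mass <= 0))
      msg <- c(msg, "monoisotopic_mass must be finite and > 0")
    nmain <- tapply(e$main_class, e$subclass,
                    function(x) length(unique(x)))
    if (any(nmain > 1L))
      msg <- c(msg, paste("subclass mapped to >1 main class:",
                          paste(names(nmain)[nmain > 1L], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Partial-correlation (Gaussian graphical model) network
#'
#' Undirected weighted graph over features. Each edge carries the shrinkage
#' partial correlation rho surviving the edge-selection test; each edge is
#' stored once with `from < to` in node order.
#'
#' @slot nodes character vector of feature ids (network node set).
#' @slot edges `data.frame` with columns `from`, `to`, `rho`.
#' @slot nSamples integer, samples used in estimation.
#' @slot lambda numeric in `[0, 1]`, shrinkage intensity toward the
#'   identity correlation target.
#' @seealso [estimatePartialCorrelations()], [selectEdges()],
#'   [mainSubgraph()]
#' @export
setClass("PcorNetwork",
  slots = c(nodes = "character", edges = "data.frame",
            nSamples = "integer", lambda = "numeric"))

setValidity("PcorNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "rho") %in% colnames(e)))
    msg <- c(msg, "edges must have columns from, to, rho")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges are not allowed")
    if (any(abs(e$rho) > 1)) msg <- c(msg, "|rho| must be <= 1")
    if (!all(e$from %in% object@nodes) || !all(e$to %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    key <- paste(pmin(e$from, e$to), pmax(e$from, e$to))
    if (anyDuplicated(key)) msg <- c(msg, "each undirected edge stored once")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn PcorNetwork-class construct a network from an edge table.
#' @param nodes,edges,nSamples,lambda see slot documentation.
#' @export
PcorNetwork <- function(nodes, edges, nSamples = NA_integer_,
                        lambda = NA_real_) {
  edges <- as.data.frame(edges)
  new("PcorNetwork", nodes = as.character(nodes), edges = edges,
      nSamples = as.integer(nSamples), lambda = as.numeric(lambda))
}
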