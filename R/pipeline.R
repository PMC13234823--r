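# One-call prediction pipeline used by the command-line interface and
# the worked examples: GGM estimation, ion-type inference, database
# matching, optional rt-logP filtering, scoring and quality scores.

#' Run the full class-prediction workflow on a feature table
#'
#' Chains [estimateNetwork()], [inferIonTypes()] (ungrouped tables),
#' [matchFeatures()], optionally [rtLogpFilter()], [predictClasses()],
#' [embedNetwork()] and [qualityScores()].
#'
#' @param featureSet a [LipidFeatureSet-class].
#' @param db a [LipidDatabase-class].
#' @param tolerancePpm accurate-mass tolerance (default 5 ppm).
#' @param rtWindow,alphaSelf scoring parameters (50 s, 5).
#' @param edgeAlpha,edgeMethod edge-selection parameters.
#' @param inferAdducts data-derive enabled ion forms from co-eluting m/z
#'   differences (ungrouped tables; default TRUE).
#' @param applyRtLogpFilter prune matches violating the rt-logP monotone
#'   trend (default FALSE).
#' @param quality also compute the embedding and quality scores
#'   (default TRUE).
#' @param ... further arguments to [predictClasses()].
#' @return list with `predictions`, `scores`, `quality`, `network`,
#'   `matches`, `coverage` (main-subgraph fraction of features entering
#'   network estimation), `classifiedFraction` (classified / nodes).
#' @export
runClassPrediction <- function(featureSet, db, tolerancePpm = 5,
                               rtWindow = 50, alphaSelf = 5,
                               edgeAlpha = 0.05,
                               edgeMethod = c("localfdr", "bh"),
                               inferAdducts = TRUE,
                               applyRtLogpFilter = FALSE,
                               quality = TRUE, ...) {
  net <- estimateNetwork(featureSet, edgeAlpha = edgeAlpha,
                         method = edgeMethod)
  adducts <- if (!isGrouped(featureSet) && inferAdducts)
    suppressWarnings(inferIonTypes(featureSet)) else NULL
  matches <- matchFeatures(featureSet, db, tolerancePpm = tolerancePpm,
                           adducts = adducts)
  if (applyRtLogpFilter)
    matches <- rtLogpFilter(matches, featureSet, db)
  fit <- predictClasses(net$network, matches, featureSet,
                        ontology = dbOntology(db), rtWindow = rtWindow,
                        alphaSelf = alphaSelf, ...)
  qs <- NULL
  emb <- NULL
  if (quality) {
    if (length(networkNodes(net$network)) >= 10L) {
      emb <- embedNetwork(net$network)
      qs <- qualityScores(emb, fit$predictions, fit$scores)
    } else {
      warning("main subgraph has fewer than 10 nodes; quality scores ",
              "skipped")
    }
  }
  list(predictions = fit$predictions, scores = fit$scores, quality = qs,
       embedding = emb, network = net$network, matches = matches,
       coverage = net$coverage, classifiedFraction = fit$coverage)
}
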