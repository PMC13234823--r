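# Closest-m/z baseline: conventional accurate-mass search with randomized
# tie resolution, and repeated-seed metric aggregation.

# candidate subclass sets at minimal |ppm| per feature
.closestCandidates <- function(featureSet, db, tolerancePpm = 10,
                               adducts = NULL, tieEpsPpm = 1e-9) {
  if (is.null(adducts) && !isGrouped(featureSet))
    adducts <- defaultAdducts(ionPolarity(featureSet))
  m <- matchFeatures(featureSet, db, tolerancePpm = tolerancePpm,
                     adducts = adducts)
  cands <- setNames(vector("list", nrow(featureSet)),
                    featureIds(featureSet))
  if (nrow(m)) {
    for (grp in split(m, m$feature_id)) {
      best <- min(abs(grp$ppm_error))
      cands[[grp$feature_id[1]]] <-
        sort(unique(grp$subclass[abs(grp$ppm_error) <= best + tieEpsPpm]))
    }
  }
  cands
}

#' Closest-m/z baseline prediction
#'
#' Every database match within the ppm tolerance is found (grouped:
#' neutral mass against monoisotopic mass; ungrouped: all configured ion
#' forms of the assay polarity); the match(es) of minimal absolute ppm
#' error define the candidate subclass set. Ties — typically isomeric
#' structures sharing a molecular formula across classes — are resolved by
#' sampling one candidate uniformly under the given seed. Features with no
#' match stay unpredicted (`NA`).
#'
#' @param featureSet a [LipidFeatureSet-class].
#' @param db a [LipidDatabase-class].
#' @param tolerancePpm mass window (default 10 ppm).
#' @param adducts ion-form table for ungrouped data (default: full
#'   [defaultAdducts()] of the polarity).
#' @param seed RNG seed for tie resolution (default 0).
#' @return `data.frame` with `feature_id`, `subclass` (sampled),
#'   `main_class`, `tied`, `n_candidates`; the candidate sets are attached
#'   as the `"candidates"` attribute.
#' @export
closestMzPredict <- function(featureSet, db, tolerancePpm = 10,
                             adducts = NULL, seed = 0L) {
  cands <- .closestCandidates(featureSet, db, tolerancePpm, adducts)
  ont <- dbOntology(db)
  n <- vapply(cands, length, integer(1))
  sampled <- .withSeed(seed, vapply(cands, function(cs) {
    if (!length(cs)) NA_character_
    else if (length(cs) == 1L) cs
    else sample(cs, 1L)
  }, character(1)))
  out <- data.frame(feature_id = names(cands), subclass = unname(sampled),
                    main_class = unname(ont[sampled]),
                    tied = unname(n > 1L), n_candidates = unname(n),
                    stringsAsFactors = FALSE)
  attr(out, "candidates") <- cands
  out
}

#' Repeated-seed baseline metrics
#'
#' Re-resolves baseline ties under `nSeeds` seeds (`1:nSeeds`) and reports
#' the mean and standard error of the mean of accuracy, macro F1 and micro
#' F1 at the subclass and main-class level against the annotations.
#' Tie-free inputs give identical metrics every seed, hence SEM exactly 0.
#'
#' @inheritParams closestMzPredict
#' @param annotations annotation `data.frame` (feature_id, subclass,
#'   main_class), e.g. from [readAnnotations()].
#' @param nSeeds number of random seeds (default 1000).
#' @return `data.frame` with columns `level`, `metric`, `mean`, `sem`.
#' @export
repeatClosestMz <- function(featureSet, db, annotations, nSeeds = 1000,
                            tolerancePpm = 10, adducts = NULL) {
  if (nSeeds < 2L) {
    warning("SEM undefined for nSeeds < 2; reported as 0")
  }
  cands <- .closestCandidates(featureSet, db, tolerancePpm, adducts)
  ont <- dbOntology(db)
  ann <- annotations[annotations$feature_id %in% names(cands), ,
                     drop = FALSE]
  if (!nrow(ann)) stop("no annotated features in the feature table")
  levels <- c("subclass", "main_class")
  acc <- array(NA_real_, dim = c(nSeeds, 2L, 3L),
               dimnames = list(NULL, levels,
                               c("accuracy", "macro_f1", "micro_f1")))
  for (s in seq_len(nSeeds)) {
    sampled <- .withSeed(s, vapply(cands[ann$feature_id], function(cs) {
      if (!length(cs)) NA_character_
      else if (length(cs) == 1L) cs
      else sample(cs, 1L)
    }, character(1)))
    pred <- data.frame(feature_id = ann$feature_id,
                       subclass = unname(sampled),
                       main_class = unname(ont[sampled]),
                       stringsAsFactors = FALSE)
    for (lv in levels) {
      m <- classificationMetrics(pred, ann, level = lv)
      acc[s, lv, ] <- c(m$accuracy, m$macro_f1, m$micro_f1)
    }
  }
  out <- expand.grid(level = levels,
                     metric = c("accuracy", "macro_f1", "micro_f1"),
                     stringsAsFactors = FALSE)
  out$mean <- mapply(function(lv, mt) mean(acc[, lv, mt]),
                     out$level, out$metric)
  out$sem <- mapply(function(lv, mt) {
    if (nSeeds < 2L) 0 else sd(acc[, lv, mt]) / sqrt(nSeeds)
  }, out$level, out$metric)
  out
}
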