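# Evaluation machinery: classification metrics against ground truth,
# hierarchical confusion matrices, the permuted feature-to-node negative
# control, and the binomial 1-NN embedding clustering test.

#' Classification metrics against annotations
#'
#' Metrics are computed over annotated features only. Annotated features
#' without a prediction (NA) count as errors — they contribute a false
#' negative to their true class but no false positive. Macro F1 averages
#' the per-class F1 over the annotated (true) classes; micro F1 pools
#' counts over all classes appearing in truth or prediction.
#'
#' @param predictions `data.frame` with `feature_id` and the class column
#'   for `level` (`subclass` or `main_class`).
#' @param annotations `data.frame` with `feature_id` and the same class
#'   columns (truth).
#' @param level `"subclass"` (default) or `"main_class"`.
#' @return list with `accuracy`, `macro_f1`, `micro_f1`, `n`.
#' @export
classificationMetrics <- function(predictions, annotations,
                                  level = c("subclass", "main_class")) {
  level <- match.arg(level)
  i <- match(annotations$feature_id, predictions$feature_id)
  keep <- !is.na(i)
  truth <- annotations[[level]][keep]
  pred <- predictions[[level]][i[keep]]
  if (!length(truth)) stop("no annotated feature has a prediction row")
  acc <- mean(!is.na(pred) & pred == truth)
  trueClasses <- unique(truth)
  allClasses <- unique(c(trueClasses, pred[!is.na(pred)]))
  f1 <- tp <- fp <- fn <- setNames(numeric(length(allClasses)), allClasses)
  for (cc in allClasses) {
    tp[cc] <- sum(!is.na(pred) & pred == cc & truth == cc)
    fp[cc] <- sum(!is.na(pred) & pred == cc & truth != cc)
    fn[cc] <- sum(truth == cc & (is.na(pred) | pred != cc))
    denom <- 2 * tp[cc] + fp[cc] + fn[cc]
    f1[cc] <- if (denom == 0) 0 else 2 * tp[cc] / denom
  }
  microDenom <- 2 * sum(tp) + sum(fp) + sum(fn)
  list(accuracy = acc,
       macro_f1 = mean(f1[trueClasses]),
       micro_f1 = if (microDenom == 0) 0 else 2 * sum(tp) / microDenom,
       n = length(truth))
}

#' Hierarchical confusion matrix
#'
#' Rows are the annotated subclasses (grouped by main class); columns are
#' the same subclasses plus `"Other: correct main class"` and
#' `"Other: incorrect main class"`, which absorb predictions whose
#' subclass is absent from the annotated set, split by whether the
#' predicted main class agrees with the truth. Unpredicted annotated
#' features fall into an `"Unclassified"` column. Row sums equal the
#' per-subclass annotation counts.
#'
#' @param predictions prediction `data.frame` (subclass-level).
#' @param annotations truth `data.frame` with `subclass`, `main_class`.
#' @param ontology named character subclass -> main class; must cover all
#'   predicted subclasses.
#' @return integer matrix of counts.
#' @export
hierarchicalConfusion <- function(predictions, annotations, ontology) {
  i <- match(annotations$feature_id, predictions$feature_id)
  pred <- predictions$subclass[i]
  predKnown <- pred[!is.na(pred)]
  if (length(setdiff(predKnown, names(ontology))))
    stop("predicted subclass absent from ontology: ",
         paste(setdiff(predKnown, names(ontology)), collapse = ", "))
  ord <- order(annotations$main_class, annotations$subclass)
  rowClasses <- unique(annotations$subclass[ord])
  cols <- c(rowClasses, "Other: correct main class",
            "Other: incorrect main class", "Unclassified")
  cm <- matrix(0L, length(rowClasses), length(cols),
               dimnames = list(rowClasses, cols))
  for (k in seq_len(nrow(annotations))) {
    tr <- annotations$subclass[k]
    pk <- pred[k]
    col <- if (is.na(pk)) "Unclassified"
    else if (pk %in% rowClasses) pk
    else if (identical(unname(ontology[pk]), annotations$main_class[k]))
      "Other: correct main class"
    else "Other: incorrect main class"
    cm[tr, col] <- cm[tr, col] + 1L
  }
  cm
}

#' Permuted feature-to-node negative control
#'
#' Randomises the mapping between network nodes and feature attributes
#' (retention time and database matches) with a seeded permutation, then
#' runs the class scoring unchanged. Destroying the correspondence between
#' network structure and chemistry collapses performance, quantifying how
#' much the predictions rely on the network.
#'
#' @inheritParams predictClasses
#' @param seed permutation seed.
#' @param permutation optional explicit permutation (integer vector over
#'   the network nodes); identity returns the unpermuted predictions.
#' @return as [predictClasses()].
#' @export
permutedNodeBaseline <- function(network, matches, featureSet, ontology,
                                 seed = 1L, permutation = NULL, ...) {
  nodes <- networkNodes(network)
  if (is.null(permutation))
    permutation <- .withSeed(seed, sample(length(nodes)))
  stopifnot(length(permutation) == length(nodes))
  # node k takes the attributes (rt, matches) of nodes[permutation[k]]
  relabel <- setNames(nodes, nodes[permutation])
  m <- matches[matches$feature_id %in% nodes, , drop = FALSE]
  m$feature_id <- unname(relabel[m$feature_id])
  m <- m[!is.na(m$feature_id), , drop = FALSE]
  rt <- featureRt(featureSet)
  rtPerm <- rt
  rtPerm[nodes] <- rt[nodes[permutation]]
  fsPerm <- featureSet
  SummarizedExperiment::rowData(fsPerm)$rt[
    match(names(rtPerm), featureIds(featureSet))] <- unname(rtPerm)
  predictClasses(network, m, fsPerm, ontology, ...)
}

#' Binomial 1-NN clustering test in the embedding
#'
#' For every class with at least `minClassSize` labelled features: under
#' the null that class labels are arranged at random, the probability that
#' a member's nearest labelled neighbour shares its class is the overall
#' class share `mu0`. The observed share `mu` is compared through
#' `z = (mu - mu0) / sigma` with `sigma = sqrt(mu0 (1 - mu0) / n)`, a
#' one-tailed upper Z-test, and Benjamini-Hochberg adjustment across
#' tested classes.
#'
#' @param embedding a `"NetworkEmbedding"` from [embedNetwork()].
#' @param labels named character vector feature_id -> class (NA ignored).
#' @param minClassSize smallest tested class (default 5).
#' @return `data.frame` with `class`, `n`, `mu0`, `mu`, `sigma`, `z`, `p`,
#'   `p_adj`.
#' @export
nnClusteringTest <- function(embedding, labels, minClassSize = 5) {
  labels <- labels[!is.na(labels)]
  ids <- intersect(rownames(embedding$coords), names(labels))
  if (length(unique(labels[ids])) < 2L)
    stop("need >= 2 labelled classes in the embedding")
  coords <- embedding$coords[ids, , drop = FALSE]
  lab <- labels[ids]
  nn <- .knnIndices(coords, 1L)
  nnLab <- lab[nn[, 1]]
  tab <- table(lab)
  classes <- names(tab)[tab >= max(2L, minClassSize)]
  if (!length(classes)) stop("no class reaches minClassSize")
  res <- do.call(rbind, lapply(classes, function(cc) {
    n <- sum(lab == cc)
    mu0 <- n / length(lab)
    mu <- mean(nnLab[lab == cc] == cc)
    sigma <- sqrt(mu0 * (1 - mu0) / n)
    z <- (mu - mu0) / sigma
    data.frame(class = cc, n = n, mu0 = mu0, mu = mu, sigma = sigma,
               z = z, p = pnorm(z, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  res$p_adj <- p.adjust(res$p, method = "BH")
  res
}
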