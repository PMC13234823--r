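# Prediction quality scores: local Simpson's index of the k nearest
# embedded neighbours, top-K score-margin (PCOR) quality, and their
# quantile-transformed product.

#' Low-dimensional embedding of the network
#'
#' Embeds the min-max scaled absolute weighted adjacency matrix of the
#' network into two dimensions by classical multidimensional scaling of
#' pairwise cosine distances between node profiles. The neighbour count of
#' the configured manifold embedding, `max(2, round(nNeighborsFrac * n))`
#' (2% of the features by default), is recorded in the returned
#' parameters. The embedding is deterministic; `seed` is recorded for
#' provenance.
#'
#' @param network [PcorNetwork-class] with at least 10 nodes.
#' @param nNeighborsFrac neighbour fraction bookkeeping (default 0.02).
#' @param minDist minimum-distance parameter recorded with the embedding
#'   (default 1).
#' @param seed integer recorded with the embedding (default 42).
#' @return object of class `"NetworkEmbedding"`: list with `coords`
#'   (n x 2 matrix, rownames = nodes) and `params`.
#' @export
embedNetwork <- function(network, nNeighborsFrac = 0.02, minDist = 1,
                         seed = 42L) {
  nodes <- networkNodes(network)
  n <- length(nodes)
  if (n < 10L) stop("embedding requires >= 10 nodes")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- networkEdges(network)
  if (nrow(e)) {
    A[cbind(e$from, e$to)] <- abs(e$rho)
    A[cbind(e$to, e$from)] <- abs(e$rho)
  }
  rng <- range(A)
  if (diff(rng) > 0) A <- (A - rng[1]) / diff(rng)
  # cosine distance between adjacency rows (self-similarity column kept;
  # zero rows mapped to distance 1 from everything)
  nrm <- sqrt(rowSums(A^2))
  nrm[nrm == 0] <- 1
  S <- (A / nrm) %*% t(A / nrm)
  D <- 1 - pmin(pmax(S, -1), 1)
  diag(D) <- 0
  coords <- cmdscale(stats::as.dist(D), k = 2)
  if (ncol(coords) < 2L)
    coords <- cbind(coords, 0)[, 1:2, drop = FALSE]
  rownames(coords) <- nodes
  structure(list(coords = coords,
                 params = list(n_components = 2L, metric = "cosine",
                               min_dist = minDist,
                               n_neighbors = max(2L,
                                 as.integer(round(nNeighborsFrac * n))),
                               seed = as.integer(seed))),
            class = "NetworkEmbedding")
}

# indices (n x k matrix) of the k nearest other points, Euclidean
.knnIndices <- function(coords, k) {
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  idx <- apply(d, 1, function(row) order(row)[seq_len(k)])
  if (k == 1L) matrix(idx, ncol = 1L) else t(idx)
}

#' Local Simpson's index of prediction homogeneity
#'
#' For each feature, its `k` nearest neighbours in the embedding are
#' collected; `L(f)` is the sum of squared subclass proportions among the
#' classified neighbours (1 = perfectly homogeneous neighbourhood).
#' Unclassified neighbours are dropped from the proportions; when all `k`
#' neighbours are unclassified, `L(f)` is undefined (`NA`). Raw values are
#' min-max scaled to `[0, 1]` across features.
#'
#' @param embedding a `"NetworkEmbedding"` from [embedNetwork()].
#' @param predictions prediction `data.frame` from [predictClasses()].
#' @param k neighbours (default 5).
#' @return `data.frame` with `feature_id`, `lsi_raw`, `lsi_scaled`.
#' @export
localSimpsonIndex <- function(embedding, predictions, k = 5) {
  coords <- embedding$coords
  ids <- rownames(coords)
  lab <- setNames(predictions$subclass, predictions$feature_id)[ids]
  nn <- .knnIndices(coords, min(k, nrow(coords) - 1L))
  L <- vapply(seq_along(ids), function(i) {
    cls <- lab[nn[i, ]]
    cls <- cls[!is.na(cls)]
    if (!length(cls)) return(NA_real_)
    p <- table(cls) / length(cls)
    sum(p^2)
  }, numeric(1))
  rng <- range(L, na.rm = TRUE)
  scaled <- if (diff(rng) == 0) {
    warning("all local Simpson indices equal; scaled LSI set to 1")
    ifelse(is.na(L), NA_real_, 1)
  } else (L - rng[1]) / diff(rng)
  data.frame(feature_id = ids, lsi_raw = L, lsi_scaled = scaled,
             stringsAsFactors = FALSE)
}

#' Score-margin (PCOR) quality
#'
#' `Q(f)` is the top subclass score divided by the sum of the `K` highest
#' subclass scores of that feature (all available when fewer than `K` are
#' nonzero); values are then mapped through the uniform quantile transform
#' across features. Unclassified features get `NA`.
#'
#' @param scores long score `data.frame` from [predictClasses()].
#' @param predictions matching prediction `data.frame`.
#' @param K top scores entering the normalisation (default 10).
#' @return `data.frame` with `feature_id`, `pcor_raw`, `pcor_transformed`.
#' @export
pcorQuality <- function(scores, predictions, K = 10) {
  q <- setNames(rep(NA_real_, nrow(predictions)), predictions$feature_id)
  byF <- split(scores$S, scores$feature_id)
  for (f in names(byF)) {
    s <- sort(byF[[f]], decreasing = TRUE)
    if (!length(s) || s[1] <= 0) next
    topK <- s[seq_len(min(K, length(s)))]
    q[f] <- s[1] / sum(topK)
  }
  q[is.na(predictions$subclass)] <- NA_real_
  data.frame(feature_id = predictions$feature_id, pcor_raw = unname(q),
             pcor_transformed = unname(quantileTransform(q)),
             stringsAsFactors = FALSE)
}

#' Product quality score
#'
#' Elementwise product of the scaled LSI and transformed PCOR scores,
#' passed through the uniform quantile transform across the data set.
#' Undefined inputs propagate to `NA`.
#'
#' @param lsiScaled,pcorTransformed numeric vectors aligned on features.
#' @return list with `product_raw` and `product` (transformed).
#' @export
productQuality <- function(lsiScaled, pcorTransformed) {
  raw <- lsiScaled * pcorTransformed
  list(product_raw = raw, product = quantileTransform(raw))
}

#' All quality scores in one table
#'
#' @inheritParams localSimpsonIndex
#' @inheritParams pcorQuality
#' @param useTransformed combine the post-processing variants
#'   (scaled LSI x transformed PCOR, default) rather than raw x raw.
#' @return `data.frame` with `feature_id`, `lsi_raw`, `lsi_scaled`,
#'   `pcor_raw`, `pcor_transformed`, `product`.
#' @export
qualityScores <- function(embedding, predictions, scores, k = 5, K = 10,
                          useTransformed = TRUE) {
  lsi <- localSimpsonIndex(embedding, predictions, k)
  pc <- pcorQuality(scores, predictions, K)
  stopifnot(identical(lsi$feature_id, pc$feature_id))
  prod <- if (useTransformed)
    productQuality(lsi$lsi_scaled, pc$pcor_transformed)
  else productQuality(lsi$lsi_raw, pc$pcor_raw)
  cbind(lsi, pc[, c("pcor_raw", "pcor_transformed")],
        product = prod$product)
}
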