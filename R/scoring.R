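# Guilt-by-association lipid subclass scoring on the partial-correlation
# network: 1-hop, 2-hop (max-product path weight) and self-match
# components, combined into S = S1 + S2 + Sself.

# adjacency list: node -> named numeric |rho| over neighbours
.adjacency <- function(network) {
  nodes <- networkNodes(network)
  adj <- setNames(vector("list", length(nodes)), nodes)
  e <- networkEdges(network)
  if (nrow(e)) {
    for (i in seq_len(nrow(e))) {
      adj[[e$from[i]]][e$to[i]] <- abs(e$rho[i])
      adj[[e$to[i]]][e$from[i]] <- abs(e$rho[i])
    }
  }
  adj
}

.sumByClass <- function(weights, matchList) {
  # weights: named numeric over features; accumulate into matched subclasses
  out <- numeric(0)
  for (j in names(weights)) {
    cls <- matchList[[j]]
    if (is.null(cls)) next
    for (cc in cls) out[cc] <- (if (is.na(out[cc])) 0 else out[cc]) +
        weights[[j]]
  }
  out[!is.na(out)]
}

#' One-hop subclass score
#'
#' `S1(c, f)` sums the absolute partial correlations of `f`'s direct
#' neighbours that elute within the retention-time window and carry a
#' tentative database match to subclass `c`; a neighbour matching several
#' subclasses contributes its full weight to each.
#'
#' @param f feature id (must be a network node).
#' @param network [PcorNetwork-class] (main subgraph).
#' @param matchList list feature_id -> character vector of matched
#'   subclasses (see [matchFeatures()]; internally derived via
#'   `split`/`unique`).
#' @param rt named numeric retention times (seconds), e.g. [featureRt()].
#' @param rtWindow half-width of the co-elution window in seconds
#'   (default 50).
#' @param adj optional precomputed adjacency (internal reuse).
#' @return named numeric vector subclass -> S1 (possibly empty).
#' @export
oneHopScore <- function(f, network, matchList, rt, rtWindow = 50,
                        adj = NULL) {
  if (is.null(adj)) adj <- .adjacency(network)
  nb <- adj[[f]]
  if (is.null(nb) || !length(nb)) return(numeric(0))
  nb <- nb[abs(rt[names(nb)] - rt[f]) <= rtWindow]
  .sumByClass(nb, matchList)
}

#' Two-hop path weights
#'
#' For every node `j != f` reachable by a two-step path `f - i - j`, the
#' weight is the maximum over intermediates `i` of
#' `|rho(f,i)| * |rho(i,j)|`. Endpoints `j` are retention-time filtered;
#' intermediates are not (configurable). Nodes that are also direct
#' neighbours stay in the two-hop set when reachable by a two-step path
#' (configurable via `includeOneHop`).
#'
#' @inheritParams oneHopScore
#' @param includeOneHop keep two-step-reachable nodes that are also 1-hop
#'   neighbours (default TRUE).
#' @param rtFilterIntermediates also restrict intermediates `i` to the rt
#'   window (default FALSE).
#' @return named numeric vector j -> w (possibly empty).
#' @export
twoHopWeights <- function(f, network, rt, rtWindow = 50,
                          includeOneHop = TRUE,
                          rtFilterIntermediates = FALSE, adj = NULL) {
  if (is.null(adj)) adj <- .adjacency(network)
  nb <- adj[[f]]
  if (is.null(nb) || !length(nb)) return(numeric(0))
  if (rtFilterIntermediates)
    nb <- nb[abs(rt[names(nb)] - rt[f]) <= rtWindow]
  w <- numeric(0)
  for (i in names(nb)) {
    nb2 <- adj[[i]]
    if (is.null(nb2) || !length(nb2)) next
    cand <- nb2 * nb[[i]]
    for (j in names(cand)) {
      if (j == f) next
      if (!includeOneHop && !is.na(nb[j])) next
      if (is.na(w[j]) || cand[[j]] > w[j]) w[j] <- cand[[j]]
    }
  }
  w <- w[!is.na(w)]
  if (!length(w)) return(numeric(0))
  w[abs(rt[names(w)] - rt[f]) <= rtWindow]
}

#' Two-hop subclass score
#'
#' `S2(c, f)` sums the two-hop path weights of nodes matching subclass `c`.
#' @inheritParams twoHopWeights
#' @param matchList as in [oneHopScore()].
#' @return named numeric vector subclass -> S2.
#' @export
twoHopScore <- function(f, network, matchList, rt, rtWindow = 50,
                        includeOneHop = TRUE,
                        rtFilterIntermediates = FALSE, adj = NULL) {
  w <- twoHopWeights(f, network, rt, rtWindow, includeOneHop,
                     rtFilterIntermediates, adj)
  if (!length(w)) return(numeric(0))
  .sumByClass(w, matchList)
}

#' Self-match subclass score
#'
#' A feature has no partial correlation with itself, so its own database
#' match is weighted by the strongest co-eluting neighbour supporting the
#' same subclass: `Sself(c, f) = alphaSelf * max |rho(f, i)|` over 1-hop
#' neighbours `i` matching `c` (0 when no neighbour supports `c`), and only
#' for subclasses `c` that `f` itself matches.
#'
#' @inheritParams oneHopScore
#' @param alphaSelf self-importance multiplier (default 5).
#' @return named numeric vector subclass -> Sself.
#' @export
selfWeightScore <- function(f, network, matchList, rt, rtWindow = 50,
                            alphaSelf = 5, adj = NULL) {
  own <- matchList[[f]]
  if (is.null(own) || !length(own)) return(numeric(0))
  if (is.null(adj)) adj <- .adjacency(network)
  nb <- adj[[f]]
  if (!is.null(nb) && length(nb))
    nb <- nb[abs(rt[names(nb)] - rt[f]) <= rtWindow]
  out <- setNames(numeric(length(own)), own)
  for (cc in own) {
    m <- 0
    if (!is.null(nb) && length(nb)) {
      sup <- vapply(names(nb), function(i) cc %in% matchList[[i]],
                    logical(1))
      if (any(sup)) m <- max(nb[sup])
    }
    out[cc] <- alphaSelf * m
  }
  out
}

#' Predict lipid subclasses for all network features
#'
#' Computes `S(c, f) = S1 + S2 + Sself` for every feature in the network
#' and emits the top-ranking subclass (main class from the ontology).
#' Features whose scores are all zero (or that have no scored subclass)
#' are reported unclassified. Exact score ties are flagged; with
#' `tiePolicy = "lexicographic"` they are additionally broken toward the
#' alphabetically first subclass.
#'
#' @param network [PcorNetwork-class], typically the main subgraph.
#' @param matches match-set `data.frame` from [matchFeatures()].
#' @param featureSet the [LipidFeatureSet-class] (source of retention
#'   times).
#' @param ontology named character subclass -> main class.
#' @param rtWindow,alphaSelf scoring parameters (defaults 50 s and 5).
#' @param tiePolicy `"report"` (default) or `"lexicographic"`.
#' @param includeOneHop,rtFilterIntermediates two-hop set toggles, see
#'   [twoHopWeights()].
#' @return list with `predictions` (`data.frame`: feature_id, subclass,
#'   main_class, score, tied), `scores` (long `data.frame`: feature_id,
#'   subclass, S1, S2, Sself, S) and `coverage` (classified / nodes).
#' @export
predictClasses <- function(network, matches, featureSet, ontology,
                           rtWindow = 50, alphaSelf = 5,
                           tiePolicy = c("report", "lexicographic"),
                           includeOneHop = TRUE,
                           rtFilterIntermediates = FALSE) {
  tiePolicy <- match.arg(tiePolicy)
  stopifnot(rtWindow > 0, alphaSelf >= 0)
  nodes <- networkNodes(network)
  rt <- featureRt(featureSet)
  absent <- setdiff(nodes, names(rt))
  if (length(absent))
    stop("network node(s) missing from feature table: ",
         paste(head(absent, 5), collapse = ", "))
  adj <- .adjacency(network)
  ml <- .matchList(matches)
  scoreRows <- vector("list", length(nodes))
  pred <- data.frame(feature_id = nodes, subclass = NA_character_,
                     main_class = NA_character_, score = 0,
                     tied = FALSE, stringsAsFactors = FALSE)
  for (k in seq_along(nodes)) {
    f <- nodes[k]
    s1 <- oneHopScore(f, network, ml, rt, rtWindow, adj = adj)
    s2 <- twoHopScore(f, network, ml, rt, rtWindow, includeOneHop,
                      rtFilterIntermediates, adj = adj)
    ss <- selfWeightScore(f, network, ml, rt, rtWindow, alphaSelf,
                          adj = adj)
    cls <- unique(c(names(s1), names(s2), names(ss)))
    if (!length(cls)) next
    S1 <- setNames(rep(0, length(cls)), cls); S1[names(s1)] <- s1
    S2 <- setNames(rep(0, length(cls)), cls); S2[names(s2)] <- s2
    SS <- setNames(rep(0, length(cls)), cls); SS[names(ss)] <- ss
    S <- S1 + S2 + SS
    scoreRows[[k]] <- data.frame(feature_id = f, subclass = cls,
                                 S1 = unname(S1), S2 = unname(S2),
                                 Sself = unname(SS), S = unname(S),
                                 stringsAsFactors = FALSE)
    if (all(S == 0)) next
    top <- which(S == max(S))
    tied <- length(top) > 1L
    pick <- if (tied && tiePolicy == "lexicographic")
      top[order(cls[top])][1] else top[1]
    pred$subclass[k] <- cls[pick]
    pred$main_class[k] <- unname(ontology[cls[pick]])
    pred$score[k] <- S[[pick]]
    pred$tied[k] <- tied
  }
  scores <- do.call(rbind, scoreRows)
  if (is.null(scores))
    scores <- data.frame(feature_id = character(), subclass = character(),
                         S1 = numeric(), S2 = numeric(), Sself = numeric(),
                         S = numeric())
  list(predictions = pred, scores = scores,
       coverage = mean(!is.na(pred$subclass)))
}
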