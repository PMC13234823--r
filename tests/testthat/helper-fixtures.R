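# Shared fixtures: all built in code at test time.

# tiny 3-feature x 4-sample table with one missing cell
toyFeatureSet <- function() {
  m <- matrix(c(1e5, 2e5, 3e5, 4e5,
                5e5, NA, 7e5, 8e5,
                2e4, 3e4, 4e4, 5e4), nrow = 3, byrow = TRUE,
              dimnames = list(c("f1", "f2", "f3"), paste0("S", 1:4)))
  LipidFeatureSet(m, mz = c(701.007276, 722.989220, 750.5), rt = c(60, 61, 300))
}

# small database: 4 subclasses in 2 main classes, known masses
toyDb <- function() {
  entries <- data.frame(
    entry_id = paste0("E", 1:6),
    name = paste("lipid", 1:6),
    formula = rep("C40H80NO8P", 6),
    monoisotopic_mass = c(700.0, 721.981944, 760.5851, 760.5851, 500.0,
                          820.2),
    subclass = c("TG", "PC", "PC", "SM", "CER", "TG"),
    main_class = c("GL", "GP", "GP", "SP", "SP", "GL"),
    logp = c(12, 8, 9, 9, 5, 14),
    stringsAsFactors = FALSE)
  new("LipidDatabase", entries = entries,
      ontology = c(TG = "GL", PC = "GP", SM = "SP", CER = "SP"))
}

# network from an explicit edge list (nodes inferred unless given)
edgeNetwork <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$from, edges$to)))
  PcorNetwork(nodes, edges, nSamples = 100L, lambda = 0.1)
}

# feature set whose only purpose is carrying rt values for scoring
rtFeatureSet <- function(rt) {
  n <- length(rt)
  m <- matrix(seq_len(2 * n) * 1.0, nrow = n,
              dimnames = list(names(rt), c("S1", "S2")))
  LipidFeatureSet(m, mz = rep(500, n), rt = unname(rt))
}

# brute-force oracle for two-hop max-product path weights
bruteTwoHop <- function(f, edges, rt, rtWindow = Inf) {
  absrho <- function(a, b) {
    hit <- (edges$from == a & edges$to == b) |
      (edges$from == b & edges$to == a)
    if (any(hit)) abs(edges$rho[which(hit)[1]]) else NA_real_
  }
  nodes <- sort(unique(c(edges$from, edges$to)))
  w <- numeric(0)
  for (i in nodes) {
    ri <- absrho(f, i)
    if (is.na(ri)) next
    for (j in nodes) {
      if (j == f) next
      rj <- absrho(i, j)
      if (is.na(rj)) next
      cand <- ri * rj
      if (is.na(w[j]) || cand > w[j]) w[j] <- cand
    }
  }
  w <- w[!is.na(w)]
  if (length(w)) w <- w[abs(rt[names(w)] - rt[f]) <= rtWindow]
  w[sort(names(w))]
}

# random undirected weighted graph for property tests
randomGraph <- function(nNodes, pEdge = 0.2) {
  nodes <- sprintf("n%02d", seq_len(nNodes))
  pairs <- which(upper.tri(matrix(0, nNodes, nNodes)), arr.ind = TRUE)
  keep <- runif(nrow(pairs)) < pEdge
  edges <- data.frame(from = nodes[pairs[keep, 1]],
                      to = nodes[pairs[keep, 2]],
                      rho = runif(sum(keep), -0.9, 0.9),
                      stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges)
}

tmpWrite <- function(df, sep = "\t") {
  path <- tempfile(fileext = ".tsv")
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE,
              na = "NA")
  path
}
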