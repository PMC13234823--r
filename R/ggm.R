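# Gaussian graphical model estimation: missingness filtering, log
# transform, KNN imputation, shrinkage partial correlations, edge
# selection under an empirical null, and main-subgraph extraction.

#' Prepare intensities for network estimation
#'
#' Zeros are treated as missing (non-detects) before the missingness
#' filter. Features missing in more than `maxMissingFrac` of samples are
#' excluded, intensities are natural-log transformed, and remaining
#' missing values are imputed by k-nearest-neighbour imputation over
#' samples (Euclidean distance on co-observed entries rescaled for
#' missingness, uniform weights over the `imputeK` nearest samples with an
#' observed value).
#'
#' @param featureSet a [LipidFeatureSet-class].
#' @param maxMissingFrac maximum tolerated per-feature missing fraction
#'   (default 0.10; strictly greater is excluded).
#' @param imputeK neighbours for imputation (default 5).
#' @return list with `matrix` (samples x features, log scale, complete)
#'   and `retained` (feature ids kept).
#' @export
preprocessIntensities <- function(featureSet, maxMissingFrac = 0.10,
                                  imputeK = 5) {
  x <- t(intensityMatrix(featureSet))  # samples x features
  if (nrow(x) < 2L) stop("need >= 2 samples")
  x[!is.na(x) & x == 0] <- NA
  missFrac <- colMeans(is.na(x))
  keep <- missFrac <= maxMissingFrac
  dropAll <- colMeans(is.na(x)) == 1
  if (any(keep & dropAll)) {
    warning("dropping all-missing feature(s): ",
            paste(colnames(x)[keep & dropAll], collapse = ", "))
    keep <- keep & !dropAll
  }
  x <- log(x[, keep, drop = FALSE])
  if (ncol(x) < 3L)
    stop("fewer than 3 features retained after missingness filtering")
  if (anyNA(x)) x <- .knnImputeSamples(x, k = imputeK)
  list(matrix = x, retained = colnames(x))
}

# KNN imputation across samples (rows). Distances: nan-Euclidean with
# rescaling sqrt(p_total / p_co-observed); neighbours must observe the
# missing entry; uniform mean over the k nearest.
.knnImputeSamples <- function(x, k = 5) {
  n <- nrow(x); p <- ncol(x)
  obs <- !is.na(x)
  xz <- x; xz[!obs] <- 0
  sq <- xz^2
  # pairwise sums of squared differences over co-observed entries
  co <- obs %*% t(obs)                               # co-observed counts
  cross <- xz %*% t(xz)
  s1 <- sq %*% t(obs)
  ss <- s1 + t(s1) - 2 * cross
  d <- sqrt(pmax(ss, 0) * ifelse(co > 0, p / co, Inf))
  diag(d) <- Inf
  for (j in which(colSums(!obs) > 0)) {
    miss <- which(!obs[, j])
    for (i in miss) {
      cand <- which(obs[, j])
      if (!length(cand)) next
      dd <- d[i, cand]
      ok <- is.finite(dd)
      cand <- cand[ok]; dd <- dd[ok]
      if (!length(cand)) cand <- which(obs[, j])
      take <- cand[order(dd)][seq_len(min(k, length(cand)))]
      x[i, j] <- mean(x[take, j])
    }
  }
  if (anyNA(x)) {
    cm <- colMeans(x, na.rm = TRUE)
    idx <- which(is.na(x), arr.ind = TRUE)
    x[idx] <- cm[idx[, 2]]
  }
  x
}

#' Shrinkage partial correlations
#'
#' Estimates the correlation matrix with analytic-optimal linear shrinkage
#' toward the identity (the ratio of the summed sampling variances of the
#' empirical correlations to their summed squares, clamped to `[0, 1]`) and
#' derives partial correlations from the standardized inverse:
#' `pcor[i,j] = -omega[i,j] / sqrt(omega[i,i] * omega[j,j])`.
#'
#' @param x numeric matrix, samples x features (log scale, complete).
#' @return list with `pcor` (symmetric, unit diagonal), `lambda`
#'   (shrinkage intensity) and `n` (samples).
#' @export
estimatePartialCorrelations <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) stop("need >= 3 samples")
  if (p < 3L) stop("need >= 3 features")
  sds <- apply(x, 2, sd)
  if (any(sds == 0 | !is.finite(sds)))
    stop("constant (zero-variance) feature(s): ",
         paste(colnames(x)[sds == 0 | !is.finite(sds)], collapse = ", "))
  xs <- scale(x)                                   # centred, unit sd (n-1)
  r <- crossprod(xs) / (n - 1)
  # sampling variance of each r_ij from the empirical variance of the
  # per-sample products w_kij = xs_ki * xs_kj
  wbar <- crossprod(xs) / n
  w2 <- crossprod(xs^2) / n
  varR <- n / (n - 1)^3 * (w2 - wbar^2) * n
  offdiag <- upper.tri(r)
  lambda <- sum(varR[offdiag]) / sum(r[offdiag]^2)
  lambda <- min(1, max(0, lambda))
  rShrunk <- (1 - lambda) * r
  diag(rShrunk) <- 1
  omega <- solve(rShrunk)
  pc <- -omega / sqrt(diag(omega) %o% diag(omega))
  diag(pc) <- 1
  pc <- (pc + t(pc)) / 2
  dimnames(pc) <- list(colnames(x), colnames(x))
  list(pcor = pc, lambda = lambda, n = n)
}

# Null density of partial correlations: r^2 ~ Beta(1/2, (kappa-1)/2),
# f0(r; kappa) \propto (1 - r^2)^{(kappa-3)/2}. Fit kappa to the
# null-dominated bulk: robust scale start (MAD), then maximum likelihood
# truncated to |r| <= 4 * scale so the signal tail cannot widen the null.
.fitKappa <- function(r) {
  r <- r[abs(r) < 1 - 1e-12]
  if (!length(r)) return(NA_real_)
  trunc <- Inf
  if (length(r) >= 200L) {
    s0 <- 1.4826 * median(abs(r - median(r)))
    if (s0 > 0) trunc <- 4 * s0
  }
  rt <- r[abs(r) <= trunc]
  if (length(rt) < 3L) rt <- r
  nll <- function(kappa) {
    ll <- sum((kappa - 3) / 2 * log1p(-rt^2)) +
      length(rt) * (lgamma(kappa / 2) - lgamma((kappa - 1) / 2) -
                      0.5 * log(pi))
    if (is.finite(trunc))
      ll <- ll - length(rt) *
        log(pbeta(trunc^2, 0.5, (kappa - 1) / 2))
    -ll
  }
  opt <- tryCatch(optimize(nll, c(2.001, 1e7)), error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$minimum)) NA_real_ else opt$minimum
}

.dnull <- function(r, kappa) {
  exp((kappa - 3) / 2 * log1p(-pmin(r^2, 1 - 1e-15)) +
        lgamma(kappa / 2) - lgamma((kappa - 1) / 2) - 0.5 * log(pi))
}

.pnull <- function(r, kappa) pbeta(r^2, 0.5, (kappa - 1) / 2,
                                   lower.tail = FALSE)

#' Select significant network edges
#'
#' Each off-diagonal partial correlation is assessed against the null
#' density of shrinkage partial correlations, with the effective degree of
#' freedom `kappa` fitted by maximum likelihood to the empirical pcor
#' distribution. Edges are kept where the empirical-Bayes local false
#' discovery rate is at most `edgeAlpha` (`method = "localfdr"`), or where
#' the Benjamini-Hochberg adjusted two-sided p-value is at most
#' `edgeAlpha` (`method = "bh"`). A degenerate null fit falls back to BH
#' with a warning.
#'
#' @param pcorFit result of [estimatePartialCorrelations()], or a plain
#'   pcor matrix (then supply `nSamples`).
#' @param edgeAlpha significance / local-fdr threshold (default 0.05).
#' @param method `"localfdr"` (default) or `"bh"`.
#' @param nSamples samples used, when `pcorFit` is a bare matrix.
#' @return a [PcorNetwork-class] whose nodes are all features and whose
#'   edges carry the retained rho values.
#' @export
selectEdges <- function(pcorFit, edgeAlpha = 0.05,
                        method = c("localfdr", "bh"), nSamples = NULL) {
  method <- match.arg(method)
  stopifnot(edgeAlpha > 0, edgeAlpha < 1)
  if (is.matrix(pcorFit))
    pcorFit <- list(pcor = pcorFit, lambda = NA_real_, n = nSamples)
  pc <- pcorFit$pcor
  nodes <- colnames(pc)
  ut <- which(upper.tri(pc), arr.ind = TRUE)
  r <- pc[upper.tri(pc)]
  kappa <- .fitKappa(r)
  degenerate <- is.na(kappa) || kappa <= 2.01
  keep <- NULL
  if (method == "localfdr" && !degenerate) {
    p <- .pnull(r, kappa)
    eta0 <- min(1, 2 * mean(p > 0.5))
    dfit <- tryCatch(density(r, n = 1024), error = function(e) NULL)
    if (is.null(dfit) || any(!is.finite(dfit$y))) {
      degenerate <- TRUE
    } else {
      fhat <- approx(dfit$x, dfit$y, xout = r, rule = 2)$y
      fhat <- pmax(fhat, 1e-300)
      fdr <- pmin(1, eta0 * .dnull(r, kappa) / fhat)
      # enforce monotonicity: fdr must not rise as |r| grows
      o <- order(abs(r))
      fdr[o] <- cummin(fdr[o])
      keep <- fdr <= edgeAlpha
    }
  }
  if (method == "bh" || degenerate) {
    if (degenerate && method == "localfdr")
      warning("degenerate null fit; falling back to BH edge selection")
    if (is.na(kappa)) {
      padj <- rep(1, length(r))
    } else {
      padj <- p.adjust(.pnull(r, kappa), method = "BH")
    }
    keep <- padj <= edgeAlpha
  }
  edges <- data.frame(from = nodes[ut[keep, 1]], to = nodes[ut[keep, 2]],
                      rho = r[keep], stringsAsFactors = FALSE)
  PcorNetwork(nodes, edges, nSamples = pcorFit$n %||% NA_integer_,
              lambda = pcorFit$lambda)
}

#' Largest connected component of the network
#'
#' Downstream class scoring operates on the main subgraph only. Component
#' size ties are broken toward the component containing the
#' lexicographically smallest feature id.
#'
#' @param network a [PcorNetwork-class].
#' @return list with `network` (restricted to the main subgraph) and
#'   `coverage` (component size / node count).
#' @export
mainSubgraph <- function(network) {
  nodes <- networkNodes(network)
  if (!length(nodes)) stop("empty network")
  g <- igraph::graph_from_data_frame(
    networkEdges(network)[, c("from", "to")], directed = FALSE,
    vertices = data.frame(name = nodes))
  comp <- igraph::components(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    champions <- vapply(best, function(b)
      min(nodes[comp$membership == b]), character(1))
    best <- best[order(champions)][1]
  }
  keep <- nodes[comp$membership == best]
  e <- networkEdges(network)
  e <- e[e$from %in% keep & e$to %in% keep, , drop = FALSE]
  list(network = PcorNetwork(keep, e, nSamples = network@nSamples,
                             lambda = network@lambda),
       coverage = length(keep) / length(nodes))
}

#' Export / import a network as an edge-list text file
#'
#' Plain three-column delimited text (`from`, `to`, `rho`); node set,
#' sample count and shrinkage lambda are stored in `#`-prefixed header
#' comments so round-trips preserve isolated nodes.
#' @param network a [PcorNetwork-class].
#' @param path file path.
#' @return `writeNetwork`: the path invisibly; `readNetwork`: a
#'   [PcorNetwork-class].
#' @export
writeNetwork <- function(network, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# nodes: ", paste(networkNodes(network), collapse = ",")),
    paste0("# n_samples: ", network@nSamples),
    paste0("# lambda: ", format(network@lambda, digits = 17))), con)
  write.table(networkEdges(network), con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  nodes <- strsplit(sub("^# nodes: ", "", hdr[1]), ",")[[1]]
  n <- as.integer(sub("^# n_samples: ", "", hdr[2]))
  lambda <- as.numeric(sub("^# lambda: ", "", hdr[3]))
  body <- lines[!grepl("^#", lines)]
  e <- read.delim(text = paste(body, collapse = "\n"), sep = "\t",
                  stringsAsFactors = FALSE)
  PcorNetwork(nodes, e, nSamples = n, lambda = lambda)
}

#' Estimate the GGM from a feature table in one call
#'
#' Convenience wrapper: [preprocessIntensities()] then
#' [estimatePartialCorrelations()] then [selectEdges()] then
#' [mainSubgraph()].
#'
#' @inheritParams preprocessIntensities
#' @inheritParams selectEdges
#' @return list with `network` (main subgraph), `fullNetwork`, `coverage`,
#'   `lambda`, and `retained` feature ids.
#' @export
estimateNetwork <- function(featureSet, maxMissingFrac = 0.10, imputeK = 5,
                            edgeAlpha = 0.05,
                            method = c("localfdr", "bh")) {
  prep <- preprocessIntensities(featureSet, maxMissingFrac, imputeK)
  fit <- estimatePartialCorrelations(prep$matrix)
  net <- selectEdges(fit, edgeAlpha = edgeAlpha, method = method)
  ms <- mainSubgraph(net)
  list(network = ms$network, fullNetwork = net, coverage = ms$coverage,
       lambda = fit$lambda, retained = prep$retained)
}
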