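# Lipid class-level enrichment: per-feature logistic regression,
# empirical Fisher's method under phenotype permutation, log2 fold-change
# summaries and rolling-Jaccard ranking concordance.

#' Per-feature phenotype association p-values
#'
#' Fits, per feature, a logistic regression of the binary phenotype on the
#' (log-scale) feature intensity plus covariates, and extracts the Wald
#' p-value of the feature coefficient. Constant features and non-converged
#' fits report p = 1 and are flagged; (quasi-)separated fits are refit
#' with a small ridge penalty and flagged.
#'
#' @param x numeric matrix, samples x features, log-scale intensities
#'   (complete; see [preprocessIntensities()]).
#' @param phenotype binary vector (two levels; coerced to 0/1).
#' @param covariates optional numeric matrix / data.frame of per-sample
#'   covariates (e.g. age, sex).
#' @param engine `"cpp"` (default, compiled IRLS) or `"glm"` (reference R
#'   fit via [stats::glm.fit()]); the two agree to numerical precision on
#'   regular fits.
#' @return `data.frame` with `feature`, `p`, `flag`.
#' @export
featurePvalues <- function(x, phenotype, covariates = NULL,
                           engine = c("cpp", "glm")) {
  engine <- match.arg(engine)
  x <- as.matrix(x)
  y <- .binPhenotype(phenotype)
  C <- .covMatrix(covariates, nrow(x))
  flags <- rep("", ncol(x))
  constant <- apply(x, 2, function(v) sd(v) < 1e-12)
  flags[constant] <- "constant"
  if (engine == "cpp") {
    p <- as.vector(cpp_logistic_pvals(x, y, C,
                                      matrix(0, nrow(x), 0))[, 1])
  } else {
    p <- vapply(seq_len(ncol(x)), function(j) {
      if (constant[j]) return(1)
      .glmWaldP(x[, j], y, C)
    }, numeric(1))
  }
  p[constant] <- 1
  data.frame(feature = colnames(x) %||% as.character(seq_len(ncol(x))),
             p = p, flag = flags, stringsAsFactors = FALSE)
}

.binPhenotype <- function(phenotype) {
  u <- sort(unique(phenotype))
  if (length(u) != 2L) stop("phenotype must have exactly two levels")
  as.numeric(phenotype == u[2])
}

.covMatrix <- function(covariates, n) {
  if (is.null(covariates)) return(matrix(0, n, 0))
  C <- as.matrix(as.data.frame(lapply(as.data.frame(covariates),
                                      as.numeric)))
  stopifnot(nrow(C) == n)
  C
}

# reference single-feature logistic Wald p through glm.fit
.glmWaldP <- function(xj, y, C) {
  X <- cbind(1, xj, C)
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  if (!fit$converged) return(1)
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(w))
  cov <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(cov)) return(1)
  se <- sqrt(cov[2, 2])
  if (!is.finite(se) || se <= 0) return(1)
  2 * pnorm(-abs(fit$coefficients[2] / se))
}

#' Fisher's combination statistic
#'
#' `T = -2 * sum(log(p))`. p-values of exactly zero are clamped to the
#' smallest positive double with a warning.
#'
#' @param p numeric vector of p-values in `(0, 1]`.
#' @return the statistic T (>= 0).
#' @examples
#' fisherStatistic(c(0.05, 0.01))  # 15.202
#' @export
fisherStatistic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  if (any(p == 0)) {
    warning("p-value(s) of 0 clamped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  -2 * sum(log(p))
}

#' Empirical Fisher's method for class-level enrichment
#'
#' For every subclass with at least `minSize` assigned features, the
#' observed statistic `T_obs = -2 sum(log p_i)` is compared against a null
#' distribution built by permuting phenotype labels `B` times (covariates
#' stay attached to their samples) and refitting every feature's logistic
#' regression per permutation. The same permutations are shared across
#' classes, preserving the correlation structure of the null statistics.
#' The empirical p-value uses the add-one estimator
#' `p_c = (1 + #\{T_b >= T_obs\}) / (1 + B)`, so it is never below
#' `1 / (B + 1)`; Benjamini-Hochberg q-values are computed across tested
#' classes.
#'
#' @inheritParams featurePvalues
#' @param classAssignment named character vector feature -> subclass
#'   (NA / missing features are ignored); typically the top predictions or
#'   annotation membership.
#' @param B number of phenotype permutations (default 10000).
#' @param minSize smallest tested class (default 15; use 3 for sparse
#'   ground-truth annotations).
#' @param seed permutation seed.
#' @return `data.frame` with `subclass`, `n_features`, `T_obs`, `p`, `q`,
#'   ordered by `p` ascending, `T_obs` descending, then name.
#' @export
empiricalFisher <- function(x, phenotype, classAssignment,
                            covariates = NULL, B = 10000, minSize = 15,
                            seed = 1L) {
  if (B < 100) warning("B < 100 gives a very coarse empirical p resolution")
  x <- as.matrix(x)
  y <- .binPhenotype(phenotype)
  C <- .covMatrix(covariates, nrow(x))
  cls <- classAssignment[!is.na(classAssignment)]
  cls <- cls[names(cls) %in% colnames(x)]
  tab <- table(cls)
  tested <- names(tab)[tab >= minSize]
  if (!length(tested)) stop("no subclass reaches minSize")
  feats <- names(cls)[cls %in% tested]
  xm <- x[, feats, drop = FALSE]
  perms <- .withSeed(seed,
    vapply(seq_len(B), function(b) y[sample(length(y))], numeric(length(y))))
  pm <- cpp_logistic_pvals(xm, y, C, perms)   # F x (1+B)
  pm[pm <= 0] <- .Machine$double.xmin
  logp <- log(pm)
  res <- do.call(rbind, lapply(tested, function(cc) {
    rows <- which(cls[feats] == cc)
    Tall <- -2 * colSums(logp[rows, , drop = FALSE])
    Tobs <- Tall[1]
    pc <- (1 + sum(Tall[-1] >= Tobs)) / (1 + B)
    data.frame(subclass = cc, n_features = length(rows), T_obs = Tobs,
               p = pc, stringsAsFactors = FALSE)
  }))
  res$q <- p.adjust(res$p, method = "BH")
  res[order(res$p, -res$T_obs, res$subclass), ]
}

#' Log2 fold change of median abundance, grouped by main class
#'
#' Per feature, `log2(median intensity in group 1 / median in group 2)`
#' on the raw intensity scale (missing cells removed), reported grouped by
#' the predicted main class and ordered by ascending retention time within
#' class. A zero or missing denominator median yields `NA`.
#'
#' @param featureSet a [LipidFeatureSet-class].
#' @param groups binary per-sample grouping (two levels); the second
#'   sorted level is the denominator group.
#' @param predictions prediction `data.frame` (source of `main_class`).
#' @return `data.frame` with `feature_id`, `main_class`, `rt`, `log2fc`.
#' @export
log2fcByClass <- function(featureSet, groups, predictions) {
  u <- sort(unique(groups))
  if (length(u) != 2L) stop("groups must have exactly two levels")
  m <- intensityMatrix(featureSet)
  med1 <- apply(m[, groups == u[1], drop = FALSE], 1, median, na.rm = TRUE)
  med2 <- apply(m[, groups == u[2], drop = FALSE], 1, median, na.rm = TRUE)
  fc <- ifelse(is.na(med2) | med2 == 0 | is.na(med1) | med1 == 0,
               NA_real_, log2(med1 / med2))
  out <- data.frame(feature_id = featureIds(featureSet),
                    main_class = predictions$main_class[
                      match(featureIds(featureSet),
                            predictions$feature_id)],
                    rt = unname(featureRt(featureSet)), log2fc = fc,
                    stringsAsFactors = FALSE)
  out[order(out$main_class, out$rt), ]
}

#' Cumulative rolling Jaccard similarity of two ranked lists
#'
#' `J_k` is the Jaccard similarity of the two top-k prefixes,
#' `k = 1..n`. Both lists are first restricted to the elements present in
#' both rankings (order preserved).
#'
#' @param r1,r2 character vectors (ranked, most significant first).
#' @return numeric vector `J_1..J_n`.
#' @export
rollingJaccard <- function(r1, r2) {
  common <- intersect(r1, r2)
  r1 <- r1[r1 %in% common]
  r2 <- r2[r2 %in% common]
  n <- length(r1)
  if (n < 2L) stop("need >= 2 common elements")
  vapply(seq_len(n), function(k) {
    a <- r1[seq_len(k)]; b <- r2[seq_len(k)]
    length(intersect(a, b)) / length(union(a, b))
  }, numeric(1))
}

#' Normalised area under the rolling Jaccard curve
#'
#' Trapezoidal rule over the curve, divided by the maximal possible area:
#' `AUC = sum_{k=1}^{n-1} (J_k + J_{k+1}) / (2 (n - 1))`; 1 iff the
#' rankings agree at every prefix.
#'
#' @param J numeric Jaccard curve from [rollingJaccard()].
#' @return `AUC_norm` in `[0, 1]`.
#' @export
jaccardAuc <- function(J) {
  n <- length(J)
  if (n < 2L) stop("need >= 2 curve points")
  sum((J[-n] + J[-1]) / 2) / (n - 1)
}

#' Permutation p-value for ranking concordance
#'
#' Null AUC distribution from `B` random reorderings of the second list;
#' add-one empirical p-value `(1 + #\{AUC_b >= AUC_obs\}) / (1 + B)`.
#'
#' @inheritParams rollingJaccard
#' @param B permutations (default 1000).
#' @param seed RNG seed.
#' @return list with `auc`, `p`, `B`.
#' @export
jaccardPermutationP <- function(r1, r2, B = 1000, seed = 1L) {
  common <- intersect(r1, r2)
  r1 <- r1[r1 %in% common]
  r2 <- r2[r2 %in% common]
  obs <- jaccardAuc(rollingJaccard(r1, r2))
  null <- .withSeed(seed, vapply(seq_len(B), function(b)
    jaccardAuc(rollingJaccard(r1, sample(r2))), numeric(1)))
  list(auc = obs, p = (1 + sum(null >= obs)) / (1 + B), B = B)
}
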