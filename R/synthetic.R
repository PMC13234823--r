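# Synthetic study generator: toy lipid database plus a feature table with
# block-correlated class structure, class-specific retention windows,
# adduct multiplicity, mass collisions, missingness and an optional
# phenotype effect. Everything downstream of raw LC-MS preprocessing can
# be exercised without external data.

#' Configuration of the synthetic study
#'
#' Defaults define the standard simulated study: 6 lipid subclasses of 40
#' analytes each, 200 samples, within-class dependence calibrated so
#' adjacent analytes have partial correlation 0.4, a 15% cross-class
#' isomer (identical-mass) rate, two ion forms per analyte, 5%
#' missingness and ~1 ppm mass error.
#'
#' Within a class, analytes are ordered (as by acyl chain length) and
#' follow a two-banded correlation structure — strong co-regulation with
#' the two nearest class neighbours — whose bands are calibrated
#' numerically so the population partial correlation between adjacent
#' analytes equals `withinPcor`. Band entries crossing a class boundary
#' are scaled by `interBlockPcor / withinPcor`, giving weak inter-class
#' coupling that keeps the network one connected main subgraph, as in
#' real lipidomic GGMs.
#'
#' @param nClasses number of lipid subclasses.
#' @param featuresPerClass analytes (database entries) per subclass.
#' @param nSamples samples (>= 10).
#' @param withinPcor target partial correlation between adjacent
#'   within-class analytes.
#' @param interBlockPcor coupling of class-boundary neighbours on the
#'   same scale as `withinPcor` (0 disconnects the classes).
#' @param nUnrelated additional feature rows with no database analyte.
#' @param adductMultiplicity ion rows emitted per analyte (1 = primary
#'   adduct only).
#' @param rtCenters per-class retention-time centres in seconds (default
#'   evenly spaced over 100-700 s).
#' @param rtSpread half-width of each class retention window (seconds).
#' @param collisionRate fraction of entries given an identical-mass
#'   partner in another class.
#' @param missingFrac completely-at-random missingness fraction.
#' @param ppmNoiseSd mass error standard deviation (ppm).
#' @param ionNoiseSd per-ion log-intensity noise sd.
#' @param effectClasses subclass names whose features respond to
#'   phenotype.
#' @param effectSize log-scale mean shift added to effect-class features
#'   in phenotype group 1.
#' @param grouped emit one neutral-mass row per analyte instead of ion
#'   rows.
#' @param polarity ESI mode of the simulated assay.
#' @param seed RNG seed; the whole study is a deterministic function of
#'   the configuration.
#' @return validated list of class `"SyntheticConfig"`.
#' @export
syntheticConfig <- function(nClasses = 6, featuresPerClass = 40,
                            nSamples = 200, withinPcor = 0.4,
                            interBlockPcor = 0.3, nUnrelated = 0,
                            adductMultiplicity = 2, rtCenters = NULL,
                            rtSpread = 20, collisionRate = 0.15,
                            missingFrac = 0.05, ppmNoiseSd = 1,
                            ionNoiseSd = 0.15, effectClasses = character(),
                            effectSize = 0, grouped = FALSE,
                            polarity = "positive", seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$rtCenters))
    cfg$rtCenters <- seq(100, 700, length.out = nClasses)
  stopifnot(nSamples >= 10,
            collisionRate >= 0, collisionRate <= 1,
            missingFrac >= 0, missingFrac <= 1,
            abs(withinPcor) < 0.5, abs(interBlockPcor) < 0.5,
            adductMultiplicity >= 1,
            length(cfg$rtCenters) == nClasses)
  if (collisionRate > 0 && nClasses < 2)
    stop("mass collisions need >= 2 classes")
  structure(cfg, class = "SyntheticConfig")
}

.subclassNames <- function(n) sprintf("Subclass%02d", seq_len(n))

# Two-banded within-class correlation structure: analytes ordered by acyl
# chain length co-vary strongly with their two nearest class neighbours
# (corr r1 at lag 1, r2 = bandRatio * r1 at lag 2). Calibrate r1 so the
# population partial correlation between adjacent analytes equals the
# configured target.
.calibrateBands <- function(withinPcor, m = 40, bandRatio = 0.55) {
  if (m < 3L || withinPcor == 0) return(c(r1 = withinPcor, r2 = 0))
  pcorAdj <- function(r1) {
    S <- diag(m)
    for (j in seq_len(m - 1L)) S[j, j + 1L] <- S[j + 1L, j] <- r1
    if (m > 2L)
      for (j in seq_len(m - 2L))
        S[j, j + 2L] <- S[j + 2L, j] <- bandRatio * r1
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < 1e-6)
      return(NA_real_)
    O <- solve(S)
    mid <- max(1L, m %/% 2L)
    -O[mid, mid + 1L] / sqrt(O[mid, mid] * O[mid + 1L, mid + 1L])
  }
  # pcorAdj is not monotone near the positive-definiteness boundary:
  # take the smallest band value reaching the target on a fine grid
  grid <- seq(0.002, 0.68, by = 0.002)
  vals <- vapply(grid, pcorAdj, numeric(1))
  ok <- which(!is.na(vals) & vals >= withinPcor)
  if (length(ok)) {
    i <- ok[1]
    r1 <- if (i == 1L) grid[1] else {
      # linear interpolation to the crossing point
      g0 <- grid[i - 1L]; v0 <- vals[i - 1L]
      if (is.na(v0)) grid[i] else
        g0 + (withinPcor - v0) / (vals[i] - v0) * (grid[i] - g0)
    }
  } else {
    best <- which.max(vals)
    warning("withinPcor target ", withinPcor, " unattainable for block ",
            "size ", m, "; using closest attainable ",
            round(vals[best], 3))
    r1 <- grid[best]
  }
  c(r1 = r1, r2 = bandRatio * r1)
}

# Global analyte-level correlation matrix: banded within classes, with
# band entries crossing a class boundary scaled down so inter-class
# coupling is weak but the network stays connected. Positive definite by
# convex interpolation between the full banded Toeplitz form and its
# block-diagonal restriction.
.syntheticSigma <- function(config) {
  M <- config$nClasses * config$featuresPerClass
  cls <- rep(seq_len(config$nClasses), each = config$featuresPerClass)
  bands <- .calibrateBands(config$withinPcor,
                           m = min(config$featuresPerClass, 40L))
  tCross <- if (config$withinPcor == 0) 0 else
    min(1, abs(config$interBlockPcor) / abs(config$withinPcor))
  S <- diag(M)
  for (lag in 1:2) {
    r <- bands[lag]
    if (M <= lag || r == 0) next
    for (j in seq_len(M - lag)) {
      v <- if (cls[j] == cls[j + lag]) r else r * tCross
      S[j, j + lag] <- S[j + lag, j] <- v
    }
  }
  S
}

#' Generate the synthetic lipid structure database
#'
#' `nClasses` subclasses (two subclasses per main class) with
#' `featuresPerClass` entries each. Masses are distinct draws from
#' 400-1000 Da with a guaranteed minimum separation; logP follows a
#' monotone trend in the class retention-time centre. A fraction
#' `collisionRate` of entries receives an identical-mass isomer partner
#' in a different class, emulating formula-sharing lipids.
#'
#' @param config a [syntheticConfig()].
#' @return a [LipidDatabase-class].
#' @export
generateDatabase <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  .withSeed(config$seed, {
    n <- config$nClasses * config$featuresPerClass
    subclasses <- rep(.subclassNames(config$nClasses),
                      each = config$featuresPerClass)
    mains <- sprintf("MainClass%02d",
                     (match(subclasses, .subclassNames(config$nClasses)) +
                        1L) %/% 2L)
    base <- seq(400, 1000, length.out = n)
    masses <- sample(base) + runif(n, -0.3, 0.3)
    rtc <- config$rtCenters[match(subclasses,
                                  .subclassNames(config$nClasses))]
    logp <- 1 + 0.015 * rtc + runif(n, -0.2, 0.2)
    entries <- data.frame(
      entry_id = sprintf("LM%04d", seq_len(n)),
      name = sprintf("Lipid %04d", seq_len(n)),
      formula = sprintf("C%dH%dO%d", 40 + seq_len(n) %% 20,
                        70 + seq_len(n) %% 30, 4 + seq_len(n) %% 6),
      monoisotopic_mass = masses,
      subclass = subclasses, main_class = mains, logp = logp,
      stringsAsFactors = FALSE)
    nColl <- round(config$collisionRate * n)
    if (nColl > 0) {
      a <- sample(n, nColl)
      for (k in a) {
        other <- which(entries$subclass != entries$subclass[k])
        b <- sample(other, 1L)
        entries$monoisotopic_mass[b] <- entries$monoisotopic_mass[k]
      }
    }
    new("LipidDatabase", entries = entries,
        ontology = .ontologyFromEntries(entries))
  })
}

#' Generate the full synthetic study
#'
#' Draws log-scale analyte intensities from a multivariate normal whose
#' precision matrix chains consecutive within-class analytes at the
#' target partial correlation (with one weak inter-class link keeping the
#' network connected), assigns class-specific retention times, emits
#' `adductMultiplicity` ion rows per analyte with correct adduct m/z and
#' ~`ppmNoiseSd` ppm mass error, applies completely-at-random
#' missingness, and attaches a binary phenotype that shifts effect-class
#' features on the log scale, plus age/sex covariates.
#'
#' @param config a [syntheticConfig()].
#' @param db optional pre-generated database (defaults to
#'   [generateDatabase()] of the same config).
#' @return list of class `"SyntheticLipidDataset"` with elements
#'   `featureSet`, `db`, `annotations` (full truth), `metadata`, `config`.
#' @export
generateDataset <- function(config, db = NULL) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (is.null(db)) db <- generateDatabase(config)
  e <- dbEntries(db)
  M <- nrow(e)
  .withSeed(config$seed + 1L, {
    cls <- e$subclass
    sigma <- .syntheticSigma(config)
    z <- matrix(rnorm(config$nSamples * M), config$nSamples, M) %*%
      chol(sigma)
    mu <- rnorm(M, 15, 1)
    L <- sweep(z, 2, mu, "+")
    phenotype <- rbinom(config$nSamples, 1, 0.5)
    if (length(config$effectClasses) && config$effectSize != 0) {
      idx <- which(cls %in% config$effectClasses)
      L[, idx] <- L[, idx] + config$effectSize * phenotype
    }
    rtc <- config$rtCenters[match(cls, .subclassNames(config$nClasses))]
    analyteRt <- rtc + runif(M, -config$rtSpread, config$rtSpread)
    adducts <- defaultAdducts(config$polarity)
    adducts <- adducts[order(-adducts$primary), , drop = FALSE]
    nAdd <- if (config$grouped) 1L else config$adductMultiplicity
    stopifnot(nAdd <= nrow(adducts))
    ionFactors <- c(1, 0.35, 0.15, 0.08, 0.05)[seq_len(nAdd)]
    rows <- list(); k <- 0L
    for (j in seq_len(M)) {
      for (a in seq_len(nAdd)) {
        k <- k + 1L
        mzTheo <- adductMz(e$monoisotopic_mass[j], adducts$mass_shift[a],
                           adducts$charge[a])
        rows[[k]] <- data.frame(
          analyte = j,
          adduct = adducts$name[a],
          mz = mzTheo * (1 + rnorm(1, 0, config$ppmNoiseSd) * 1e-6),
          rt = analyteRt[j] + if (a == 1L) 0 else rnorm(1, 0, 0.2),
          logFactor = log(ionFactors[a]),
          stringsAsFactors = FALSE)
      }
    }
    ions <- do.call(rbind, rows)
    ions$feature_id <- sprintf("F%04d_%s", ions$analyte,
                               gsub("[^A-Za-z0-9]", "", ions$adduct))
    intens <- exp(t(L[, ions$analyte, drop = FALSE]) + ions$logFactor +
                    matrix(rnorm(nrow(ions) * config$nSamples, 0,
                                 config$ionNoiseSd),
                           nrow(ions), config$nSamples))
    if (config$nUnrelated > 0) {
      extra <- matrix(exp(rnorm(config$nUnrelated * config$nSamples,
                                15, 1)),
                      config$nUnrelated, config$nSamples)
      intens <- rbind(intens, extra)
      ions <- rbind(ions, data.frame(
        analyte = NA_integer_, adduct = "[?]",
        mz = runif(config$nUnrelated, 400, 1000) + 0.5,
        rt = runif(config$nUnrelated, 50, 750), logFactor = 0,
        feature_id = sprintf("U%04d", seq_len(config$nUnrelated)),
        stringsAsFactors = FALSE))
    }
    rownames(intens) <- ions$feature_id
    colnames(intens) <- sprintf("S%03d", seq_len(config$nSamples))
    if (config$missingFrac > 0) {
      mask <- matrix(runif(length(intens)) < config$missingFrac,
                     nrow(intens), ncol(intens))
      intens[mask] <- NA
    }
    nm <- if (config$grouped)
      e$monoisotopic_mass[ions$analyte] *
        (1 + rnorm(nrow(ions), 0, config$ppmNoiseSd) * 1e-6) else NULL
    metadata <- data.frame(sample_id = colnames(intens),
                           phenotype = phenotype,
                           age = round(rnorm(config$nSamples, 65, 8)),
                           sex = rbinom(config$nSamples, 1, 0.5),
                           stringsAsFactors = FALSE)
    rownames(metadata) <- metadata$sample_id
    fs <- LipidFeatureSet(intens, mz = ions$mz, rt = ions$rt,
                          neutralMass = nm, grouped = config$grouped,
                          polarity = config$polarity,
                          sampleData = metadata)
    ann <- data.frame(
      feature_id = ions$feature_id,
      subclass = ifelse(is.na(ions$analyte), NA, cls[ions$analyte]),
      stringsAsFactors = FALSE)
    ann$main_class <- unname(dbOntology(db)[ann$subclass])
    structure(list(featureSet = fs, db = db, annotations = ann,
                   metadata = metadata, config = config),
              class = "SyntheticLipidDataset")
  })
}

#' @export
print.SyntheticLipidDataset <- function(x, ...) {
  cat("SyntheticLipidDataset:", nrow(x$featureSet), "features,",
      ncol(x$featureSet), "samples,", x$config$nClasses, "subclasses\n")
  invisible(x)
}

#' Accuracy of predictions against the generated truth
#'
#' Exact comparison over every truth-bearing feature of the dataset;
#' features that are unclassified or absent from the prediction table
#' count as errors. Main-class accuracy is always at least the subclass
#' accuracy (ontology coarsening).
#'
#' @param dataset a `"SyntheticLipidDataset"`.
#' @param predictions prediction `data.frame` with `feature_id`,
#'   `subclass`, `main_class`.
#' @return list with `subclass_accuracy`, `main_class_accuracy`, `n`.
#' @export
truthReport <- function(dataset, predictions) {
  truth <- dataset$annotations
  truth <- truth[!is.na(truth$subclass), , drop = FALSE]
  i <- match(truth$feature_id, predictions$feature_id)
  ps <- predictions$subclass[i]
  pm <- predictions$main_class[i]
  list(subclass_accuracy = mean(!is.na(ps) & ps == truth$subclass),
       main_class_accuracy = mean(!is.na(pm) & pm == truth$main_class),
       n = nrow(truth))
}

#' Write the synthetic study to a directory of delimited text files
#'
#' Emits `features.tsv`, `database.tsv`, `annotations.tsv`,
#' `metadata.tsv` in the formats read by [readFeatureTable()],
#' [loadLipidDatabase()], [readAnnotations()] and [readSampleMetadata()].
#'
#' @param dataset a `"SyntheticLipidDataset"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
writeSyntheticDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeFeatureTable(dataset$featureSet, file.path(dir, "features.tsv"))
  writeLipidDatabase(dataset$db, file.path(dir, "database.tsv"))
  .writeDelim(dataset$annotations[, c("feature_id", "subclass")],
              file.path(dir, "annotations.tsv"))
  .writeDelim(dataset$metadata, file.path(dir, "metadata.tsv"))
  invisible(dir)
}
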