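# Lipid structure database parsing, adduct arithmetic, accurate-mass
# matching, kernel-density ion-type inference and the rt-logP consistency
# filter.

#' Proton mass (Da) used in adduct arithmetic
#' @export
PROTON_MASS <- 1.00727646677

#' Built-in adduct (ion form) table
#'
#' Standard electrospray ion forms with their m/z shifts relative to the
#' neutral monoisotopic mass M: `mz = (M + mass_shift) / |charge|`. The
#' first row of each polarity is the primary adduct (`[M+H]+` / `[M-H]-`),
#' which matching always considers; further ion forms can be enabled
#' explicitly or via [inferIonTypes()]. The table is plain data and can be
#' replaced or extended by the user ([readAdducts()]).
#'
#' @param polarity optional `"positive"`/`"negative"` filter.
#' @return `data.frame` with columns `name`, `mass_shift` (Da), `charge`,
#'   `polarity`, `primary`.
#' @export
defaultAdducts <- function(polarity = NULL) {
  tab <- data.frame(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+", "[M+H-H2O]+",
             "[M-H]-", "[M+Cl]-", "[M+HCOO]-", "[M-H-H2O]-"),
    mass_shift = c(1.00727646677, 21.98194425, 38.96315842, 18.03382555,
                   -17.00328823, -1.00727646677, 34.96885271, 44.99820285,
                   -19.01784116),
    charge = c(1L, 1L, 1L, 1L, 1L, -1L, -1L, -1L, -1L),
    polarity = rep(c("positive", "negative"), c(5L, 4L)),
    primary = c(TRUE, FALSE, FALSE, FALSE, FALSE,
                TRUE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
  if (!is.null(polarity)) tab <- tab[tab$polarity == polarity, ]
  tab
}

#' Read an adduct configuration table
#'
#' @param path delimited text with columns `name`, `mass_shift`, `charge`,
#'   `polarity` and optionally `primary`.
#' @return adduct `data.frame` as in [defaultAdducts()].
#' @export
readAdducts <- function(path) {
  df <- .readDelim(path)
  req <- c("name", "mass_shift", "charge", "polarity")
  if (!all(req %in% colnames(df)))
    stop("schema error: adduct table needs columns ",
         paste(req, collapse = ", "))
  if (any(df$charge == 0)) stop("validation error: adduct charge must be != 0")
  if (!"primary" %in% colnames(df)) df$primary <- FALSE
  df
}

#' Theoretical m/z of an adduct of a neutral molecule
#'
#' `mz = (M + mass_shift) / |charge|`.
#'
#' @param neutralMass neutral monoisotopic mass M (Da, > 0).
#' @param massShift adduct mass shift (Da).
#' @param charge adduct charge (non-zero integer).
#' @return theoretical m/z.
#' @examples
#' adductMz(700, massShift = 1.007276, charge = 1L)   # 701.007276
#' @export
adductMz <- function(neutralMass, massShift, charge = 1L) {
  stopifnot(all(neutralMass > 0), all(charge != 0))
  (neutralMass + massShift) / abs(charge)
}

#' Invert [adductMz()]: neutral mass from an observed m/z
#' @param mz observed m/z.
#' @inheritParams adductMz
#' @return neutral mass (Da).
#' @export
neutralMassFromMz <- function(mz, massShift, charge = 1L) {
  stopifnot(all(charge != 0))
  mz * abs(charge) - massShift
}

#' Load a lipid structure database from delimited text
#'
#' @param path delimited text with header columns `entry_id`, `name`,
#'   `formula`, `monoisotopic_mass`, `subclass`, `main_class` and
#'   optionally `logp`.
#' @return a validated [LipidDatabase-class]; the subclass -> main class
#'   ontology is extracted from the entries.
#' @export
loadLipidDatabase <- function(path) {
  df <- .readDelim(path)
  req <- c("entry_id", "name", "formula", "monoisotopic_mass", "subclass",
           "main_class")
  missing_cols <- setdiff(req, colnames(df))
  if (length(missing_cols))
    stop("schema error: missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"logp" %in% colnames(df)) df$logp <- NA_real_
  df$entry_id <- as.character(df$entry_id)
  df$monoisotopic_mass <- as.numeric(df$monoisotopic_mass)
  ont <- .ontologyFromEntries(df)
  new("LipidDatabase", entries = df[, c(req, "logp")], ontology = ont)
}

.ontologyFromEntries <- function(entries) {
  u <- unique(entries[, c("subclass", "main_class")])
  setNames(as.character(u$main_class), u$subclass)
}

#' Write a lipid database to delimited text
#' @param db a [LipidDatabase-class].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeLipidDatabase <- function(db, path) {
  .writeDelim(dbEntries(db), path)
  invisible(path)
}

# Match an observed mass vector against theoretical masses within a closed
# ppm interval; denominator is the theoretical mass. Returns a data.frame
# (obs_index, theo_index, ppm_error) with signed errors.
.ppmMatch <- function(obs, theo, tolerancePpm) {
  o <- order(theo)
  ts <- theo[o]
  lo <- findInterval(obs * (1 - tolerancePpm * 1e-6) - 1e-12, ts) + 1L
  hi <- findInterval(obs * (1 + tolerancePpm * 1e-6) + 1e-12, ts)
  n <- pmax(hi - lo + 1L, 0L)
  if (sum(n) == 0L)
    return(data.frame(obs_index = integer(), theo_index = integer(),
                      ppm_error = numeric()))
  oi <- rep.int(seq_along(obs), n)
  ti <- o[unlist(Map(function(a, b) if (a <= b) a:b else integer(), lo, hi),
                 use.names = FALSE)]
  ppm <- 1e6 * (obs[oi] - theo[ti]) / theo[ti]
  keep <- abs(ppm) <= tolerancePpm + 1e-9
  data.frame(obs_index = oi[keep], theo_index = ti[keep],
             ppm_error = ppm[keep])
}

#' Tentatively match features to database structures by accurate mass
#'
#' Grouped tables compare the feature's estimated neutral mass to entry
#' monoisotopic masses. Ungrouped tables convert each entry mass to a
#' theoretical m/z under every enabled adduct of the assay polarity and
#' compare it to the observed feature m/z. Matches are retained when the
#' signed relative error `1e6 * (obs - theo) / theo` lies in the closed
#' interval `[-tolerancePpm, +tolerancePpm]`.
#'
#' @param featureSet a [LipidFeatureSet-class].
#' @param db a [LipidDatabase-class].
#' @param tolerancePpm mass tolerance in ppm (default 5).
#' @param adducts adduct table (ungrouped mode); defaults to the primary
#'   adduct of the assay polarity only.
#' @return a match-set `data.frame` with columns `feature_id`, `entry_id`,
#'   `subclass`, `main_class`, `adduct`, `ppm_error`.
#' @seealso [inferIonTypes()] to data-derive the enabled adducts,
#'   [rtLogpFilter()] to prune chromatographically inconsistent matches.
#' @export
matchFeatures <- function(featureSet, db, tolerancePpm = 5,
                          adducts = NULL) {
  stopifnot(tolerancePpm > 0)
  e <- dbEntries(db)
  empty <- data.frame(feature_id = character(), entry_id = character(),
                      subclass = character(), main_class = character(),
                      adduct = character(), ppm_error = numeric(),
                      stringsAsFactors = FALSE)
  if (isGrouped(featureSet)) {
    nm <- neutralMass(featureSet)
    if (is.null(nm)) stop("grouped matching requires neutral_mass")
    hits <- .ppmMatch(unname(nm), e$monoisotopic_mass, tolerancePpm)
    if (!nrow(hits)) return(empty)
    out <- data.frame(
      feature_id = featureIds(featureSet)[hits$obs_index],
      entry_id = e$entry_id[hits$theo_index],
      subclass = e$subclass[hits$theo_index],
      main_class = e$main_class[hits$theo_index],
      adduct = "[M]", ppm_error = hits$ppm_error,
      stringsAsFactors = FALSE)
    return(out[order(out$feature_id, abs(out$ppm_error)), ])
  }
  if (is.null(adducts)) {
    adducts <- defaultAdducts(ionPolarity(featureSet))
    adducts <- adducts[adducts$primary, , drop = FALSE]
  } else {
    adducts <- adducts[adducts$polarity == ionPolarity(featureSet), ,
                       drop = FALSE]
  }
  if (!nrow(adducts)) stop("no adducts enabled for polarity ",
                           ionPolarity(featureSet))
  mz <- unname(featureMz(featureSet))
  res <- lapply(seq_len(nrow(adducts)), function(a) {
    theo <- adductMz(e$monoisotopic_mass, adducts$mass_shift[a],
                     adducts$charge[a])
    hits <- .ppmMatch(mz, theo, tolerancePpm)
    if (!nrow(hits)) return(NULL)
    data.frame(feature_id = featureIds(featureSet)[hits$obs_index],
               entry_id = e$entry_id[hits$theo_index],
               subclass = e$subclass[hits$theo_index],
               main_class = e$main_class[hits$theo_index],
               adduct = adducts$name[a], ppm_error = hits$ppm_error,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) return(empty)
  out[order(out$feature_id, abs(out$ppm_error)), ]
}

#' Infer plausible ion types from co-eluting m/z differences
#'
#' Computes all pairwise m/z differences among features co-eluting within
#' `rtPairWindow` seconds, estimates a Gaussian kernel density over the
#' differences (restricted to `(0, maxDiff]` Da) and enables an ion form
#' when its characteristic m/z difference from the primary adduct lies
#' within `tolerance` Da of a local density maximum whose density exceeds
#' `densityFactor` times the reference density (the median of the density
#' curve, floored at 1.5x the uniform density `1/maxDiff` so isolated
#' stray differences cannot qualify). The primary adduct of the polarity is
#' always enabled. Adduct-difference spectra are mixtures of narrow
#' spikes, so the default kernel bandwidth equals the mass tolerance
#' rather than a global scale rule; both are configurable.
#'
#' @param featureSet ungrouped [LipidFeatureSet-class].
#' @param adducts candidate adduct table (default [defaultAdducts()] of the
#'   assay polarity).
#' @param rtPairWindow co-elution window in seconds (default 1).
#' @param tolerance Da window around a density peak (default 0.01).
#' @param densityFactor peak prominence multiplier over the reference
#'   density (default 3).
#' @param maxDiff largest m/z difference considered (default 60 Da).
#' @param bw kernel bandwidth in Da (default `tolerance`).
#' @return subset of `adducts` (enabled ion forms, primary included).
#' @export
inferIonTypes <- function(featureSet, adducts = NULL, rtPairWindow = 1,
                          tolerance = 0.01, densityFactor = 3,
                          maxDiff = 60, bw = NULL) {
  if (isGrouped(featureSet))
    stop("ion-type inference applies to ungrouped feature tables")
  if (is.null(adducts)) adducts <- defaultAdducts(ionPolarity(featureSet))
  adducts <- adducts[adducts$polarity == ionPolarity(featureSet), ,
                     drop = FALSE]
  primary <- adducts[adducts$primary, , drop = FALSE]
  others <- adducts[!adducts$primary, , drop = FALSE]
  if (!nrow(primary)) stop("adduct table lacks a primary adduct for ",
                           ionPolarity(featureSet))
  rt <- unname(featureRt(featureSet))
  mz <- unname(featureMz(featureSet))
  o <- order(rt)
  rt <- rt[o]; mz <- mz[o]
  diffs <- numeric(0)
  j <- 1L
  for (i in seq_along(rt)) {
    while (rt[i] - rt[j] > rtPairWindow) j <- j + 1L
    if (j < i) diffs <- c(diffs, abs(mz[i] - mz[j:(i - 1L)]))
  }
  diffs <- diffs[diffs > 0 & diffs <= maxDiff]
  if (length(diffs) < 2L) {
    warning("fewer than 2 co-eluting feature pairs; enabling primary ",
            "adduct only")
    return(primary)
  }
  if (is.null(bw)) bw <- tolerance
  d <- density(diffs, bw = bw, from = 0, to = maxDiff, n = 32768)
  y <- d$y
  # reference level: median of the density curve, floored above the
  # uniform level so a single stray difference cannot mimic a peak
  ref <- max(median(y), 1.5 / maxDiff)
  peak <- which(y > c(-Inf, y[-length(y)]) & y >= c(y[-1], -Inf))
  peak <- peak[y[peak] > densityFactor * ref]
  peakX <- d$x[peak]
  # characteristic observed m/z difference of each ion form vs the primary
  charDiff <- abs(adductMz(500, others$mass_shift, others$charge) -
                  adductMz(500, primary$mass_shift[1], primary$charge[1]))
  enabled <- vapply(charDiff, function(cd)
    length(peakX) > 0 && any(abs(peakX - cd) <= tolerance), logical(1))
  rbind(primary, others[enabled, , drop = FALSE])
}

#' Filter matches inconsistent with the retention-time/logP trend
#'
#' In reversed-phase chromatography, lipid hydrophobicity (logP) increases
#' monotonically with retention time. A monotone non-decreasing (isotonic,
#' pool-adjacent-violators) regression of entry logP on feature rt is
#' fitted on calibration features carrying exactly one match with a known
#' logP; matches whose |logP residual| exceeds the central
#' `residualQuantile` band of the calibration residuals are removed.
#' Entries without logP always pass; a feature's last remaining match is
#' kept unless `strict = TRUE`. With fewer than 10 calibration points the
#' filter is disabled with a warning.
#'
#' @param matches match-set `data.frame` from [matchFeatures()].
#' @param featureSet the matched [LipidFeatureSet-class].
#' @param db the [LipidDatabase-class] (source of logP).
#' @param residualQuantile central quantile of absolute calibration
#'   residuals retained (default 0.95).
#' @param strict allow removal of a feature's last match (default FALSE).
#' @return filtered match-set (always a subset of the input).
#' @export
rtLogpFilter <- function(matches, featureSet, db, residualQuantile = 0.95,
                         strict = FALSE) {
  e <- dbEntries(db)
  logp <- setNames(e$logp, e$entry_id)[matches$entry_id]
  rt <- featureRt(featureSet)[matches$feature_id]
  nmatch <- table(matches$feature_id)
  calib <- names(nmatch)[nmatch == 1L]
  ci <- which(matches$feature_id %in% calib & !is.na(logp))
  if (length(ci) < 10L) {
    warning("rt-logP filter disabled: fewer than 10 unique-match ",
            "calibration points with logP")
    return(matches)
  }
  ord <- order(rt[ci])
  fit <- isoreg(rt[ci][ord], logp[ci][ord])
  # step-wise prediction at arbitrary rt (constant extrapolation)
  predIso <- function(x) approx(fit$x, fit$yf, xout = x, method = "constant",
                                rule = 2, ties = mean)$y
  res <- abs(logp[ci] - predIso(rt[ci]))
  band <- quantile(res, residualQuantile, names = FALSE)
  out_res <- abs(logp - predIso(rt))
  drop <- !is.na(logp) & out_res > band
  if (!strict) {
    # never remove a feature's last surviving match
    for (f in unique(matches$feature_id[drop])) {
      idx <- which(matches$feature_id == f)
      if (all(drop[idx])) drop[idx[which.min(out_res[idx])]] <- FALSE
    }
  }
  matches[!drop, , drop = FALSE]
}

# match-set as list feature_id -> unique character vector of subclasses
.matchList <- function(matches) {
  if (!nrow(matches)) return(list())
  lapply(split(matches$subclass, matches$feature_id), unique)
}
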