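test_that("the synthetic database honours counts, collisions, and the seed", {
  cfg <- syntheticConfig(collisionRate = 0, seed = 2L)
  db <- generateDatabase(cfg)
  e <- dbEntries(db)
  expect_equal(nrow(e), 240L)
  expect_equal(length(unique(e$monoisotopic_mass)), 240L)
  expect_equal(length(unique(e$subclass)), 6L)
  expect_equal(length(unique(e$main_class)), 3L)

  cfgC <- syntheticConfig(collisionRate = 0.1, seed = 2L)
  eC <- dbEntries(generateDatabase(cfgC))
  dupMass <- eC$monoisotopic_mass[duplicated(eC$monoisotopic_mass)]
  crossPairs <- sum(vapply(unique(dupMass), function(m) {
    sub <- eC$subclass[eC$monoisotopic_mass == m]
    length(unique(sub)) > 1
  }, logical(1)))
  expect_gt(crossPairs, 24 * 0.6)
  expect_lt(length(dupMass), 24 * 1.5 + 1)

  expect_identical(dbEntries(generateDatabase(cfgC)), eC)  # deterministic
  expect_error(syntheticConfig(nClasses = 1, collisionRate = 1),
               ">= 2 classes")
})

test_that("the generated dataset reproduces its own configuration", {
  cfg <- syntheticConfig(nClasses = 3, featuresPerClass = 10,
                         nSamples = 40, adductMultiplicity = 2,
                         missingFrac = 0.08, seed = 5L)
  ds <- generateDataset(cfg)
  fs <- ds$featureSet
  expect_equal(nrow(fs), 2L * 30L)                 # multiplicity x analytes
  expect_equal(ncol(fs), 40L)
  expect_equal(mean(is.na(intensityMatrix(fs))), 0.08, tolerance = 0.25)
  expect_false(isGrouped(fs))
  # every ion's m/z sits within ~5 ppm of its planted adduct arithmetic
  e <- dbEntries(ds$db)
  an <- as.integer(sub("F(\\d+)_.*", "\\1", featureIds(fs)))
  isH <- grepl("MH", featureIds(fs))
  theo <- ifelse(isH, e$monoisotopic_mass[an] + 1.00727646677,
                 e$monoisotopic_mass[an] + 21.98194425)
  expect_lt(max(abs(1e6 * (unname(featureMz(fs)) - theo) / theo)), 5)
  # class retention windows respected
  rtc <- cfg$rtCenters[match(ds$annotations$subclass,
                             sprintf("Subclass%02d", 1:3))]
  expect_lt(max(abs(unname(featureRt(fs)) - rtc)), cfg$rtSpread + 2)
  # determinism
  ds2 <- generateDataset(cfg)
  expect_equal(intensityMatrix(ds2$featureSet), intensityMatrix(fs))
})

test_that("adjacent-analyte partial correlation recovers the configured target", {
  # population-level: the calibrated structure hits the target exactly
  cfg <- syntheticConfig(nClasses = 2, featuresPerClass = 40,
                         nSamples = 500, adductMultiplicity = 1,
                         missingFrac = 0, seed = 8L)
  S <- lipidGGM:::.syntheticSigma(cfg)
  O <- solve(S)
  pc <- -O / sqrt(diag(O) %o% diag(O))
  adj <- mapply(function(j) pc[j, j + 1], 10:30)
  expect_lt(abs(mean(adj) - 0.4), 0.02)
  # sample-level: shrinkage estimate on generated data lands near the target
  ds <- generateDataset(cfg)
  prep <- preprocessIntensities(ds$featureSet)
  fit <- estimatePartialCorrelations(prep$matrix)
  ids <- colnames(fit$pcor)
  an <- as.integer(sub("F(\\d+)_.*", "\\1", ids))
  cls <- dbEntries(ds$db)$subclass[an]
  est <- mapply(function(i) {
    j <- which(an == an[i] + 1L)
    if (length(j) && cls[i] == cls[j]) fit$pcor[i, j] else NA_real_
  }, seq_along(an))
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.4), 0.1)
})

test_that("a null phenotype leaves features unassociated", {
  cfg <- syntheticConfig(nClasses = 2, featuresPerClass = 15,
                         nSamples = 120, adductMultiplicity = 1,
                         missingFrac = 0, effectSize = 0, seed = 3L)
  ds <- generateDataset(cfg)
  prep <- preprocessIntensities(ds$featureSet)
  p <- featurePvalues(prep$matrix, ds$metadata$phenotype)$p
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
  # with an effect, the shifted class dominates the smallest p-values
  cfgE <- syntheticConfig(nClasses = 2, featuresPerClass = 15,
                          nSamples = 120, adductMultiplicity = 1,
                          missingFrac = 0, effectSize = 1.5,
                          effectClasses = "Subclass01", seed = 3L)
  dsE <- generateDataset(cfgE)
  prepE <- preprocessIntensities(dsE$featureSet)
  pE <- featurePvalues(prepE$matrix, dsE$metadata$phenotype)$p
  top <- order(pE)[1:5]
  cls <- dsE$annotations$subclass[match(colnames(prepE$matrix),
                                        dsE$annotations$feature_id)]
  expect_gte(mean(cls[top] == "Subclass01"), 0.8)
})

test_that("truth reports are exact and respect ontology coarsening", {
  cfg <- syntheticConfig(nClasses = 2, featuresPerClass = 5,
                         nSamples = 12, adductMultiplicity = 1,
                         missingFrac = 0, seed = 6L)
  ds <- generateDataset(cfg)
  truth <- ds$annotations
  perfect <- truth
  tr <- truthReport(ds, perfect)
  expect_equal(tr$subclass_accuracy, 1)
  expect_equal(tr$main_class_accuracy, 1)
  none <- transform(truth, subclass = NA_character_,
                    main_class = NA_character_)
  tr0 <- truthReport(ds, none)
  expect_equal(tr0$subclass_accuracy, 0)
  # corrupting subclasses within the same main class: main stays ahead
  mixed <- truth
  flip <- seq(1, nrow(mixed), by = 2)
  mixed$subclass[flip] <- ifelse(mixed$subclass[flip] == "Subclass01",
                                 "Subclass02", "Subclass01")
  trM <- truthReport(ds, mixed)
  expect_lte(trM$subclass_accuracy, trM$main_class_accuracy)
})

test_that("the study round-trips through a directory of text files", {
  cfg <- syntheticConfig(nClasses = 2, featuresPerClass = 4,
                         nSamples = 10, adductMultiplicity = 1,
                         missingFrac = 0, seed = 7L)
  ds <- generateDataset(cfg)
  dir <- file.path(tempdir(), "synthstudy")
  writeSyntheticDataset(ds, dir)
  fs <- readFeatureTable(file.path(dir, "features.tsv"))
  db <- loadLipidDatabase(file.path(dir, "database.tsv"))
  ann <- readAnnotations(file.path(dir, "annotations.tsv"),
                         dbOntology(db), featureSet = fs)
  md <- readSampleMetadata(file.path(dir, "metadata.tsv"), featureSet = fs)
  expect_equal(dim(fs), dim(ds$featureSet))
  expect_equal(nrow(dbEntries(db)), 8L)
  expect_equal(ann$subclass, ds$annotations$subclass)
  expect_equal(md$phenotype, ds$metadata$phenotype)
})
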