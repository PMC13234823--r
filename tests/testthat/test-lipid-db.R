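test_that("adduct arithmetic matches its definition and inverts", {
  expect_equal(adductMz(700, 1.007276, 1L), 701.007276)
  expect_equal(adductMz(700, -1.007276, -1L), 698.992724)
  ad <- defaultAdducts()
  for (i in seq_len(nrow(ad))) {
    mz <- adductMz(700, ad$mass_shift[i], ad$charge[i])
    expect_equal(neutralMassFromMz(mz, ad$mass_shift[i], ad$charge[i]),
                 700, tolerance = 1e-9)
  }
})

test_that("database loading validates entries and extracts the ontology", {
  db <- toyDb()
  path <- tempfile(fileext = ".tsv")
  writeLipidDatabase(db, path)
  db2 <- loadLipidDatabase(path)
  expect_equal(nrow(dbEntries(db2)), 6L)
  expect_equal(sort(names(dbOntology(db2))), c("CER", "PC", "SM", "TG"))
  expect_equal(dbOntology(db2)[["PC"]], "GP")

  bad <- dbEntries(db); bad$monoisotopic_mass[1] <- -5
  expect_error(new("LipidDatabase", entries = bad,
                   ontology = dbOntology(db)), "> 0")
  dup <- dbEntries(db); dup$entry_id[2] <- "E1"
  expect_error(new("LipidDatabase", entries = dup,
                   ontology = dbOntology(db)), "duplicate")
  twomain <- dbEntries(db); twomain$main_class[3] <- "SP"  # PC under 2 mains
  expect_error(new("LipidDatabase", entries = twomain,
                   ontology = dbOntology(db)), "main class")
})

test_that("ppm matching uses a closed signed window on the theoretical mass", {
  # grouped: neutral 760.5850 against entry 760.5851 -> ppm ~ -0.13
  m <- matrix(1:4 * 1e4, nrow = 2,
              dimnames = list(c("g1", "g2"), c("S1", "S2")))
  fs <- LipidFeatureSet(m, mz = c(761.6, 500.1), rt = c(10, 20),
                        neutralMass = c(760.5850, 499.9), grouped = TRUE)
  hits <- matchFeatures(fs, toyDb(), tolerancePpm = 5)
  g1 <- hits[hits$feature_id == "g1", ]
  expect_setequal(g1$subclass, c("PC", "SM"))
  expect_equal(unique(g1$ppm_error), 1e6 * (760.5850 - 760.5851) / 760.5851)
  expect_equal(unique(round(g1$ppm_error, 2)), -0.13)
  # g2 has no entry within 5 ppm
  expect_false("g2" %in% hits$feature_id)

  # an observation exactly at the +5 ppm boundary is retained
  fsB <- LipidFeatureSet(m, mz = c(761.6, 500.1), rt = c(10, 20),
                         neutralMass = c(700 * (1 + 5e-6), 499.9),
                         grouped = TRUE)
  hb <- matchFeatures(fsB, toyDb(), tolerancePpm = 5)
  expect_true(any(hb$feature_id == "g1" & hb$entry_id == "E1"))
})

test_that("growing the adduct set never removes matches", {
  fs <- toyFeatureSet()  # ungrouped positive; f1 = E1 + H, f2 = E2 + H
  primary <- defaultAdducts("positive")[1, ]
  all_pos <- defaultAdducts("positive")
  h1 <- matchFeatures(fs, toyDb(), tolerancePpm = 5, adducts = primary)
  h2 <- matchFeatures(fs, toyDb(), tolerancePpm = 5, adducts = all_pos)
  key <- function(h) paste(h$feature_id, h$entry_id, h$adduct)
  expect_true(all(key(h1) %in% key(h2)))
  expect_true(any(h1$feature_id == "f1" & h1$entry_id == "E1"))
})

test_that("ion-type inference recovers a planted sodium adduct", {
  set.seed(42)
  nA <- 60
  M <- runif(nA, 400, 900)
  rt <- runif(nA, 100, 600)
  dH <- 1.00727646677; dNa <- 21.98194425
  mz <- c(M + dH, M + dNa)
  rts <- c(rt, rt + rnorm(nA, 0, 0.1))
  m <- matrix(rexp(4 * 2 * nA, 1e-5), ncol = 4,
              dimnames = list(sprintf("i%03d", seq_len(2 * nA)), NULL))
  colnames(m) <- paste0("S", 1:4)
  fs <- LipidFeatureSet(m, mz = mz, rt = rts)
  enabled <- inferIonTypes(fs)
  expect_true("[M+H]+" %in% enabled$name)
  expect_true("[M+Na]+" %in% enabled$name)
  expect_false("[M+K]+" %in% enabled$name)
})

test_that("isolated features or structureless differences enable only the primary adduct", {
  m <- matrix(1:8 * 1e3, nrow = 4,
              dimnames = list(paste0("x", 1:4), c("S1", "S2")))
  lonely <- LipidFeatureSet(m, mz = c(500, 600, 700, 800),
                            rt = c(0, 100, 200, 300))
  expect_warning(en <- inferIonTypes(lonely), "co-eluting")
  expect_equal(en$name, "[M+H]+")

  # co-eluting but uniformly random differences: no density peak support
  set.seed(7)
  n <- 40
  mz2 <- runif(n, 400, 460)
  fs2 <- LipidFeatureSet(matrix(rexp(2 * n, 1e-4), ncol = 2,
                                dimnames = list(paste0("y", seq_len(n)),
                                                c("S1", "S2"))),
                         mz = mz2, rt = rep(100, n))
  en2 <- inferIonTypes(fs2)
  expect_equal(en2$name, "[M+H]+")
})

test_that("rt-logP filter removes planted outliers but preserves structure", {
  set.seed(1)
  n <- 40
  rt <- sort(runif(n, 50, 600))
  logp <- 2 + 0.02 * rt + rnorm(n, 0, 0.1)  # monotone trend + noise
  entries <- data.frame(
    entry_id = sprintf("E%03d", seq_len(n + 1)),
    name = "x", formula = "x",
    monoisotopic_mass = seq(500, 900, length.out = n + 1),
    subclass = rep(c("A", "B"), length.out = n + 1),
    main_class = rep(c("MA", "MB"), length.out = n + 1),
    logp = c(logp, logp[20] + 10),  # E041: logP 10 units off the trend
    stringsAsFactors = FALSE)
  db <- new("LipidDatabase", entries = entries,
            ontology = c(A = "MA", B = "MB"))
  ids <- sprintf("f%03d", seq_len(n))
  fs <- rtFeatureSet(setNames(rt, ids))
  matches <- data.frame(
    feature_id = c(ids, "f020"),
    entry_id = c(entries$entry_id[seq_len(n)], "E041"),
    subclass = "A", main_class = "MA", adduct = "[M+H]+", ppm_error = 0,
    stringsAsFactors = FALSE)
  filt <- rtLogpFilter(matches, fs, db)
  expect_false("E041" %in% filt$entry_id)       # outlier removed
  expect_true(all(paste(filt$feature_id, filt$entry_id) %in%
                    paste(matches$feature_id, matches$entry_id)))
  # clean monotone matches survive unchanged
  clean <- matches[matches$entry_id != "E041", ]
  expect_equal(rtLogpFilter(clean, fs, db), clean)
  # all-NA logp disables the filter with a warning
  entries2 <- entries; entries2$logp <- NA_real_
  db2 <- new("LipidDatabase", entries = entries2,
             ontology = c(A = "MA", B = "MB"))
  expect_warning(out <- rtLogpFilter(matches, fs, db2), "disabled")
  expect_equal(out, matches)
})
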