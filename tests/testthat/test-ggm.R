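test_that("preprocessing filters by missingness, logs, and KNN-imputes", {
  set.seed(3)
  n <- 100
  m <- matrix(rexp(n * 4, 1e-4) + 1, nrow = 4,
              dimnames = list(paste0("f", 1:4), sprintf("S%03d", 1:n)))
  m[1, 1:11] <- NA                         # 11% missing -> dropped
  m[2, 1:10] <- NA                         # 10% missing -> kept
  out <- preprocessIntensities(LipidFeatureSet(m, mz = 1:4 + 500,
                                               rt = 1:4))
  expect_false("f1" %in% out$retained)
  expect_true("f2" %in% out$retained)
  expect_false(anyNA(out$matrix))

  # no missing values: output is exactly the elementwise natural log
  m2 <- m[3:4 + 0, ]; m2 <- rbind(m2, f5 = rexp(n, 1e-4) + 1)
  out2 <- preprocessIntensities(LipidFeatureSet(m2, mz = 1:3 + 500,
                                                rt = 1:3))
  expect_equal(out2$matrix, t(log(m2)))

  # zeros are treated as missing before the filter
  m3 <- rbind(m2, f6 = rexp(n, 1e-4) + 1)
  m3[1, 1:15] <- 0
  out3 <- preprocessIntensities(LipidFeatureSet(m3, mz = 1:4 + 500,
                                                rt = 1:4),
                                maxMissingFrac = 0.10)
  expect_false(rownames(m3)[1] %in% out3$retained)
})

test_that("a missing cell surrounded by identical neighbours imputes to that value", {
  # sample 1 is identical to samples 2..6 except the missing cell; all
  # nearest neighbours carry value v there
  base <- matrix(rep(c(10, 20, 30, 40), each = 8), nrow = 8)
  base <- base + matrix(rnorm(32, 0, 1e-3), 8)  # tiny jitter, distinct rows
  v <- 7
  x <- cbind(base, c(NA, rep(v, 7)))
  imp <- lipidGGM:::.knnImputeSamples(x, k = 5)
  expect_equal(imp[1, 5], v, tolerance = 1e-12)
})

test_that("shrinkage partial correlations remove indirect associations", {
  set.seed(11)
  n <- 5000
  x <- rnorm(n); y <- 0.8 * x + rnorm(n, 0, 0.6); z <- 0.8 * y + rnorm(n, 0, 0.6)
  fit <- estimatePartialCorrelations(cbind(X = x, Y = y, Z = z))
  expect_lt(abs(fit$pcor["X", "Z"]), 0.05)   # cond. independent given Y
  expect_gt(fit$pcor["X", "Y"], 0.3)
  expect_true(isSymmetric(fit$pcor, tol = 1e-12))
  expect_gte(fit$lambda, 0); expect_lte(fit$lambda, 1)

  ind <- matrix(rnorm(3 * n), ncol = 3,
                dimnames = list(NULL, c("a", "b", "c")))
  fit2 <- estimatePartialCorrelations(ind)
  expect_lt(max(abs(fit2$pcor[upper.tri(fit2$pcor)])), 3 / sqrt(n))

  const <- cbind(a = rnorm(10), b = rnorm(10), c = rep(1, 10))
  expect_error(estimatePartialCorrelations(const), "c")
})

test_that("edge selection finds planted blocks and controls false edges", {
  set.seed(21)
  n <- 500
  blockSigma <- function(m, r1 = 0.5, r2 = 0.3) {
    S <- diag(m)
    for (j in seq_len(m - 1)) S[j, j + 1] <- S[j + 1, j] <- r1
    for (j in seq_len(m - 2)) S[j, j + 2] <- S[j + 2, j] <- r2
    S
  }
  m <- 20
  S <- Matrix::bdiag(blockSigma(m), blockSigma(m))
  x <- matrix(rnorm(n * 2 * m), n) %*% chol(as.matrix(S))
  colnames(x) <- sprintf("v%02d", seq_len(2 * m))
  fit <- estimatePartialCorrelations(x)
  net <- selectEdges(fit, method = "bh")
  e <- networkEdges(net)
  expect_gt(nrow(e), 10)
  blockOf <- function(v) (as.integer(sub("v", "", v)) - 1L) %/% m
  within <- blockOf(e$from) == blockOf(e$to)
  expect_gte(mean(within), 0.9)

  # i.i.d. noise: BH keeps at most ~5% of pairs
  noise <- matrix(rnorm(200 * 200), 200,
                  dimnames = list(NULL, sprintf("n%03d", 1:200)))
  netN <- selectEdges(estimatePartialCorrelations(noise), method = "bh")
  expect_lte(nrow(networkEdges(netN)), 0.05 * choose(200, 2))

  # edge set shrinks monotonically as alpha decreases, empty in the limit
  a1 <- selectEdges(fit, edgeAlpha = 0.05, method = "bh")
  a2 <- selectEdges(fit, edgeAlpha = 0.005, method = "bh")
  a3 <- selectEdges(fit, edgeAlpha = 1e-12, method = "bh")
  key <- function(net) paste(networkEdges(net)$from, networkEdges(net)$to)
  expect_true(all(key(a2) %in% key(a1)))
  expect_lte(nrow(networkEdges(a3)), nrow(networkEdges(a2)))
})

test_that("edge selection is deterministic", {
  set.seed(5)
  x <- matrix(rnorm(100 * 12), 100,
              dimnames = list(NULL, letters[1:12]))
  f1 <- estimatePartialCorrelations(x)
  f2 <- estimatePartialCorrelations(x)
  expect_identical(f1, f2)
  expect_identical(suppressWarnings(selectEdges(f1)),
                   suppressWarnings(selectEdges(f2)))
})

test_that("main subgraph keeps the largest component with deterministic ties", {
  conn <- edgeNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                                 rho = c(0.5, 0.4)))
  ms <- mainSubgraph(conn)
  expect_equal(ms$coverage, 1.0)
  expect_setequal(networkNodes(ms$network), c("a", "b", "c"))

  nodes <- c(sprintf("x%02d", 1:9), "y1")
  e <- data.frame(from = sprintf("x%02d", 1:8), to = sprintf("x%02d", 2:9),
                  rho = 0.3)
  split9 <- PcorNetwork(nodes, e)
  ms2 <- mainSubgraph(split9)
  expect_equal(ms2$coverage, 0.9)
  expect_false("y1" %in% networkNodes(ms2$network))

  # size tie: keep the component with the lexicographically smallest node
  tied <- PcorNetwork(c("b1", "b2", "a1", "a2"),
                      data.frame(from = c("b1", "a1"), to = c("b2", "a2"),
                                 rho = 0.5))
  ms3 <- mainSubgraph(tied)
  expect_setequal(networkNodes(ms3$network), c("a1", "a2"))

  expect_error(mainSubgraph(PcorNetwork(character(),
                                        data.frame(from = character(),
                                                   to = character(),
                                                   rho = numeric()))),
               "empty")
})

test_that("networks round-trip through edge-list text", {
  net <- edgeNetwork(data.frame(from = c("a", "b"), to = c("b", "c"),
                                rho = c(0.512345678901, -0.25)),
                     nodes = c("a", "b", "c", "isolated"))
  path <- tempfile(fileext = ".txt")
  writeNetwork(net, path)
  back <- readNetwork(path)
  expect_equal(networkNodes(back), networkNodes(net))
  expect_equal(networkEdges(back)$rho, networkEdges(net)$rho)
  expect_equal(back@nSamples, net@nSamples)
})
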