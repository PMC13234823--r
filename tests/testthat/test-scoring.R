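# rt values that keep every node inside the default +/- 50 s window
flatRt <- function(nodes) setNames(rep(100, length(nodes)), nodes)

test_that("one-hop score sums |rho| of matched co-eluting neighbours", {
  net <- edgeNetwork(data.frame(from = c("f", "f", "f"),
                                to = c("n1", "n2", "n3"),
                                rho = c(0.3, -0.2, 0.5)))
  rt <- flatRt(networkNodes(net))
  ml <- list(n1 = "A", n2 = "A", n3 = "B")
  s1 <- oneHopScore("f", net, ml, rt)
  expect_equal(s1[["A"]], 0.5)
  expect_equal(s1[["B"]], 0.5)

  # all neighbours outside the rt window
  rt2 <- rt; rt2[c("n1", "n2", "n3")] <- 200
  expect_length(oneHopScore("f", net, ml, rt2), 0L)
  # neighbour without a database match contributes nothing
  expect_length(oneHopScore("f", net, list(), rt), 0L)
})

test_that("two-hop weights take the maximum product path", {
  net <- edgeNetwork(data.frame(from = c("f", "f", "i1", "i2"),
                                to = c("i1", "i2", "j", "j"),
                                rho = c(0.4, 0.6, 0.5, 0.3)))
  rt <- flatRt(networkNodes(net))
  w <- twoHopWeights("f", net, rt)
  expect_equal(w[["j"]], 0.20)   # max(0.4*0.5, 0.6*0.3)

  single <- edgeNetwork(data.frame(from = c("f", "i"), to = c("i", "j"),
                                   rho = c(0.5, 0.5)))
  expect_equal(twoHopWeights("f", single, flatRt(networkNodes(single)))[["j"]],
               0.25)

  lone <- edgeNetwork(data.frame(from = "f", to = "i", rho = 0.5))
  w3 <- twoHopWeights("f", lone, flatRt(networkNodes(lone)))
  expect_length(w3[setdiff(names(w3), "i")], 0L)
})

test_that("two-hop weights equal brute-force path enumeration on random graphs", {
  set.seed(2024)
  for (rep in 1:8) {
    g <- randomGraph(sample(5:30, 1))
    if (!nrow(g$edges)) next
    net <- PcorNetwork(g$nodes, g$edges)
    rt <- flatRt(g$nodes)
    f <- sample(g$nodes, 1)
    w <- twoHopWeights(f, net, rt)
    brute <- bruteTwoHop(f, g$edges, rt)
    expect_equal(w[sort(names(w))], brute, tolerance = 1e-15)
  }
})

test_that("two-hop score accumulates weights by matched subclass", {
  net <- edgeNetwork(data.frame(from = c("f", "f", "i1", "i2"),
                                to = c("i1", "i2", "j1", "j2"),
                                rho = c(0.5, 0.5, 0.4, 0.2)))
  rt <- flatRt(networkNodes(net))
  s2 <- twoHopScore("f", net, list(j1 = "A", j2 = "A"), rt)
  expect_equal(s2[["A"]], 0.5 * 0.4 + 0.5 * 0.2)
  expect_length(twoHopScore("f", net, list(), rt), 0L)
})

test_that("self-weight uses alpha times the best same-class neighbour", {
  net <- edgeNetwork(data.frame(from = c("f", "f"), to = c("n1", "n2"),
                                rho = c(0.3, 0.45)))
  rt <- flatRt(networkNodes(net))
  ml <- list(f = "A", n1 = "A", n2 = "A")
  expect_equal(selfWeightScore("f", net, ml, rt, alphaSelf = 5)[["A"]],
               2.25)
  # no supporting neighbour: the empty max is 0
  ml2 <- list(f = "A", n1 = "B")
  expect_equal(selfWeightScore("f", net, ml2, rt)[["A"]], 0)
  # no own match: no self-weight entries at all
  expect_length(selfWeightScore("f", net, list(n1 = "A"), rt), 0L)
})

test_that("hand-built 6-node graph reproduces hand-derived scores", {
  # f - a (0.30, matches A), f - b (0.20, matches A and B),
  # f - c (0.50, matches B); a - d (0.60, d matches A);
  # c - e (0.40, e matches B); f itself matches A.
  net <- edgeNetwork(data.frame(
    from = c("f", "f", "f", "a", "c"),
    to = c("a", "b", "c", "d", "e"),
    rho = c(0.30, 0.20, 0.50, 0.60, 0.40)))
  rt <- flatRt(networkNodes(net))
  ml <- list(f = "A", a = "A", b = c("A", "B"), c = "B", d = "A", e = "B")
  s1 <- oneHopScore("f", net, ml, rt)
  expect_equal(s1[["A"]], 0.30 + 0.20)
  expect_equal(s1[["B"]], 0.20 + 0.50)
  w <- twoHopWeights("f", net, rt)
  expect_equal(w[["d"]], 0.30 * 0.60)
  expect_equal(w[["e"]], 0.50 * 0.40)
  s2 <- twoHopScore("f", net, ml, rt)
  expect_equal(s2[["A"]], 0.18)
  expect_equal(s2[["B"]], 0.20)
  ss <- selfWeightScore("f", net, ml, rt, alphaSelf = 5)
  expect_equal(ss[["A"]], 5 * 0.30)   # strongest A-matching neighbour
  fs <- rtFeatureSet(rt)
  matches <- data.frame(
    feature_id = c("f", "a", "b", "b", "c", "d", "e"),
    entry_id = "E", subclass = c("A", "A", "A", "B", "B", "A", "B"),
    main_class = "M", adduct = "[M+H]+", ppm_error = 0)
  fit <- predictClasses(net, matches, fs, ontology = c(A = "M", B = "M"))
  sf <- fit$scores[fit$scores$feature_id == "f", ]
  expect_equal(sf$S[sf$subclass == "A"], 0.50 + 0.18 + 1.50)
  expect_equal(sf$S[sf$subclass == "B"], 0.70 + 0.20)
  pf <- fit$predictions[fit$predictions$feature_id == "f", ]
  expect_equal(pf$subclass, "A")
  expect_false(pf$tied)
})

test_that("prediction handles unclassified features and exact ties", {
  net <- edgeNetwork(data.frame(from = c("f", "g"), to = c("g", "h"),
                                rho = c(0.3, 0.3)))
  fs <- rtFeatureSet(flatRt(networkNodes(net)))
  fit <- predictClasses(net, data.frame(feature_id = character(),
                                        entry_id = character(),
                                        subclass = character(),
                                        main_class = character(),
                                        adduct = character(),
                                        ppm_error = numeric()),
                        fs, ontology = c(A = "M"))
  expect_true(all(is.na(fit$predictions$subclass)))
  expect_equal(fit$coverage, 0)

  # two subclasses with exactly equal S -> tied
  net2 <- edgeNetwork(data.frame(from = c("f", "f"), to = c("p", "q"),
                                 rho = c(0.4, 0.4)))
  fs2 <- rtFeatureSet(flatRt(networkNodes(net2)))
  m2 <- data.frame(feature_id = c("p", "q"), entry_id = "E",
                   subclass = c("A", "B"), main_class = "M",
                   adduct = "[M+H]+", ppm_error = 0)
  fit2 <- predictClasses(net2, m2, fs2, ontology = c(A = "M", B = "M"))
  pf <- fit2$predictions[fit2$predictions$feature_id == "f", ]
  expect_true(pf$tied)
  fit3 <- predictClasses(net2, m2, fs2, ontology = c(A = "M", B = "M"),
                         tiePolicy = "lexicographic")
  expect_equal(fit3$predictions$subclass[
    fit3$predictions$feature_id == "f"], "A")
})

test_that("scores are monotone in alpha, rt window, and match availability", {
  set.seed(9)
  g <- randomGraph(15, 0.3)
  net <- PcorNetwork(g$nodes, g$edges)
  rt <- setNames(runif(15, 80, 160), g$nodes)
  fs <- rtFeatureSet(rt)
  matches <- data.frame(feature_id = g$nodes, entry_id = "E",
                        subclass = rep(c("A", "B", "C"), 5),
                        main_class = "M", adduct = "[M+H]+", ppm_error = 0)
  ont <- c(A = "M", B = "M", C = "M")
  base <- predictClasses(net, matches, fs, ont, rtWindow = 30)
  wide <- predictClasses(net, matches, fs, ont, rtWindow = 100)
  moreAlpha <- predictClasses(net, matches, fs, ont, rtWindow = 30,
                              alphaSelf = 10)
  fewer <- predictClasses(net, matches[-c(1, 5), ], fs, ont, rtWindow = 30)
  join <- function(a, b) merge(a, b, by = c("feature_id", "subclass"))
  jw <- join(base$scores, wide$scores)
  expect_true(all(jw$S.y >= jw$S.x - 1e-12))
  ja <- join(base$scores, moreAlpha$scores)
  expect_true(all(ja$S.y >= ja$S.x - 1e-12))
  jf <- join(base$scores, fewer$scores)
  expect_true(all(jf$S.y <= jf$S.x + 1e-12))
})
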