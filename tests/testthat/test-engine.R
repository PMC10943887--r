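# Engine: cluster-tree construction, forward pass under both algebras,
# optimal and stochastic traceback, precomputation.

coloringCT <- function() {
  net <- coloringModel()
  td <- makeGentle(minFillDecompose(dependencyGraph(net), seed = 1))
  list(net = net, ct = buildClusterTree(net, td))
}

test_that("algebras are consistent triples", {
  mx <- maxAlgebra(); sm <- sumAlgebra()
  expect_equal(sm@lift(-Inf), sm@excluded)      # exp(-Inf) = 0
  expect_equal(mx@lift(-Inf), mx@excluded)
  expect_equal(mx@combine(3, mx@neutralCombine), 3)
  expect_equal(sm@combine(3, sm@neutralCombine), 3)
  expect_equal(mx@choose(2, mx@neutralChoose), 2)
  expect_equal(sm@choose(2, sm@neutralChoose), 2)
})

test_that("placement is total, unique, and at a covering bag", {
  cc <- coloringCT()
  net <- cc$net; ct <- cc$ct
  # every constraint and function placed exactly once
  expect_length(ct@constraintNode, length(net@constraints))
  expect_equal(nrow(ct@functionTable),
               sum(vapply(net@features, function(f) length(f@functions), 0L)))
  # scopes contained in the assigned bag
  for (i in seq_along(net@constraints))
    expect_true(all(net@constraints[[i]]@scope %in%
                      ct@td@bags[[ct@constraintNode[i]]]))
  for (r in seq_len(nrow(ct@functionTable))) {
    f <- net@features[[ct@functionTable$feature[r]]]@functions[[
      ct@functionTable$index[r]]]
    expect_true(all(f@scope %in% ct@td@bags[[ct@functionTable$node[r]]]))
  }
  # a unary function sits at the node introducing its variable
  One <- defineFunctionType("OneT", function(v) as.numeric(v))
  net1 <- addFunctions(addVariables(featureNetwork(), 3, 0:1), "f",
                       lapply(1:3, One))
  td1 <- makeGentle(minFillDecompose(dependencyGraph(net1), seed = 1))
  ct1 <- buildClusterTree(net1, td1)
  dif <- tdSeparators(td1)$diff
  for (r in seq_len(3))
    expect_identical(dif[[ct1@functionTable$node[r]]],
                     net1@features$f@functions[[r]]@scope)
  # an uncovering decomposition is rejected
  badTd <- makeGentle(new("TreeDecomposition",
                          bags = list(1L, 2L, 3L),
                          parent = c(NA, 1L, 1L), root = 1L, nVariables = 3L))
  net2 <- addConstraint(addVariables(featureNetwork(), 3, 1:2),
                        defineConstraintType("NE2", function(v) v[1] != v[2])(c(1, 3)))
  expect_error(buildClusterTree(net2, badTd), class = "treefeat_td_error")
})

test_that("forward root values match exhaustive enumeration (both algebras)", {
  for (s in 1:40) {
    net <- randomFeatureNetwork(s + 1000)
    fn <- featureNames(net)
    w <- if (length(fn)) setNames(seq_along(fn) - 1.5, fn) else NULL
    bf <- enumNet(net, w)
    ct <- buildClusterTree(net, makeGentle(
      minFillDecompose(dependencyGraph(net), seed = s)))
    fmax <- forwardPass(ct, w, "max")
    expect_equal(fmax@rootValue, bruteMax(bf))
    fsum <- forwardPass(ct, w, "sum")
    expect_equal(fsum@rootValue, bruteZ(bf), tolerance = 1e-9)
    if (fmax@rootValue > -Inf) {
      x <- optimalTraceback(fmax)
      expect_true(isValid(net, x))
      expect_equal(evaluateAssignment(net, x, w), fmax@rootValue,
                   tolerance = 1e-9)
    } else {
      expect_error(optimalTraceback(fmax), class = "treefeat_infeasible")
      expect_equal(fsum@rootValue, 0)
    }
  }
})

test_that("the root value combines the 0-ary messages of the root children", {
  cc <- coloringCT()
  kids <- tdChildren(cc$ct@td)[[cc$ct@td@root]]
  fmax <- forwardPass(cc$ct, c(card = -1), "max")
  expect_equal(fmax@rootValue,
               sum(vapply(kids, function(u) fmax@messages[[u]][1], 0)))
  fsum <- forwardPass(cc$ct, c(card = -1), "sum")
  expect_equal(fsum@rootValue,
               prod(vapply(kids, function(u) fsum@messages[[u]][1], 0)))
})

test_that("message tables are bounded by the separator domain product", {
  cc <- coloringCT()
  fw <- forwardPass(cc$ct, NULL, "sum")
  sd <- tdSeparators(cc$ct@td)
  w <- tdWidth(cc$ct@td)
  for (u in seq_along(cc$ct@td@bags)) {
    if (u == cc$ct@td@root) next
    expect_lte(length(fw@messages[[u]]),
               prod(lengths(variableDomains(cc$net)[sd$sep[[u]]])))
    expect_lte(length(sd$sep[[u]]), w)
  }
})

test_that("optimization agrees with brute force on the coloring fixture", {
  cc <- coloringCT()
  bf <- enumNet(cc$net, c(card = -1))
  fw <- forwardPass(cc$ct, c(card = -1), "max")
  expect_equal(fw@rootValue, bruteMax(bf))
  # the worked coloring (total cardinality 11) is improved by recoloring v3
  x <- optimalTraceback(fw)
  expect_equal(-fw@rootValue, 10)
  xcol <- c(1, 2, 3, 3, 4, 2, 1, 3, 1)
  recol <- replace(xcol, 3, 4)
  expect_equal(evaluateAssignment(cc$net, recol), -fw@rootValue)
})

test_that("two equally weighted assignments are sampled 50/50", {
  # one variable, two values, constant evaluation: pure symmetry
  net <- addFunctions(addVariables(featureNetwork(), 1, 1:2), "f",
                      defineFunctionType("ConstT", function(v) 1)(1))
  draws <- sampleNetwork(net, NULL, n = 10000, seed = 101)
  p <- mean(draws[, 1] == 1)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("stochastic traceback follows the Boltzmann distribution", {
  cc <- coloringCT()
  bf <- enumNet(cc$net, c(card = -1))
  probs <- exp(bf$E) * bf$valid
  probs <- probs / sum(probs)
  S <- sampleNetwork(cc$net, c(card = -1), n = 20000, seed = 7)
  cells <- bf$encodeRows(S)
  obs <- tabulate(cells, nbins = bf$total)
  expect_equal(sum(obs[bf$valid]), 20000)   # samples are always valid
  p <- chisqPooledP(obs[probs > 0], probs[probs > 0])
  expect_gt(p, 0.001)
})

test_that("the maximizing assignment also has maximal sampling probability", {
  for (s in c(3, 11, 19)) {
    net <- randomFeatureNetwork(s, maxVars = 5, maxItems = 6)
    bf <- enumNet(net)
    if (!any(bf$valid)) next
    ct <- buildClusterTree(net, makeGentle(
      minFillDecompose(dependencyGraph(net), seed = 1)))
    fw <- forwardPass(ct, NULL, "max")
    x <- optimalTraceback(fw)
    # P(x) proportional to exp(E): the argmax attains the maximal probability
    expect_equal(evaluateAssignment(net, x), max(bf$E[bf$valid]))
  }
})

test_that("tabulated and on-the-fly evaluation agree to the last bit", {
  cc <- coloringCT()
  for (alg in c("max", "sum")) {
    a <- forwardPass(cc$ct, c(card = -0.7), alg, tabulate = TRUE)
    b <- forwardPass(cc$ct, c(card = -0.7), alg, tabulate = FALSE)
    expect_identical(a@rootValue, b@rootValue)
    expect_identical(a@messages, b@messages)
  }
})

test_that("precomputed tables have d^k entries and a space accounting", {
  net <- addConstraint(addVariables(featureNetwork(), 2, 1:4),
                       defineConstraintType("NE2", function(v) v[1] != v[2])(c(1, 2)))
  ct <- buildClusterTree(net, makeGentle(
    minFillDecompose(dependencyGraph(net), seed = 1)))
  tabs <- precomputeTables(ct)
  expect_length(tabs$constraints[[1]]$values, 16)   # 4^2
  expect_equal(attr(tabs, "entries"), 16)
  # the cap triggers the documented fallback
  expect_message(small <- precomputeTables(ct, maxEntries = 8), "cap")
  expect_null(small$constraints[[1]])
  fw1 <- forwardPass(ct, NULL, "sum", tables = small)
  fw2 <- forwardPass(ct, NULL, "sum", tables = tabs)
  expect_identical(fw1@rootValue, fw2@rootValue)
})

test_that("infeasible networks yield the excluded value under both algebras", {
  inst <- coloringInstance()
  inst$k <- 1L
  net <- coloringModel(inst)
  ct <- buildClusterTree(net, makeGentle(
    minFillDecompose(dependencyGraph(net), seed = 1)))
  expect_equal(forwardPass(ct, NULL, "max")@rootValue, -Inf)
  expect_equal(forwardPass(ct, NULL, "sum")@rootValue, 0)
  expect_error(stochasticTraceback(forwardPass(ct, NULL, "sum")),
               class = "treefeat_infeasible")
})

test_that("algebra mismatches in tracebacks are rejected", {
  cc <- coloringCT()
  expect_error(optimalTraceback(forwardPass(cc$ct, NULL, "sum")),
               class = "treefeat_algebra_error")
  expect_error(stochasticTraceback(forwardPass(cc$ct, NULL, "max")),
               class = "treefeat_algebra_error")
})
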