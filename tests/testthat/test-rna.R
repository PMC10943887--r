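# RNA design models and DFA-based motif control.

test_that("dot-bracket parsing handles layers, errors, and triplets", {
  expect_equal(parseDotBracket("((..))")@pairs,
               matrix(c(1L, 2L, 6L, 5L), ncol = 2))
  s <- parseDotBracket("([)]")
  expect_equal(s@pairs, matrix(c(1L, 2L, 3L, 4L), ncol = 2))
  expect_true(isCrossing(s))
  expect_equal(nrow(parseDotBracket("....")@pairs), 0)
  expect_false(isCrossing(parseDotBracket("(.(..).)")))
  expect_error(parseDotBracket("(()"), class = "treefeat_parse_error")
  expect_error(parseDotBracket("())"), class = "treefeat_parse_error")
  expect_error(parseDotBracket("(x)"), class = "treefeat_parse_error")
  # doubly paired position via explicit constructor
  expect_error(secondaryStructure(4, rbind(c(1, 3), c(3, 4))))
})

test_that("gcCount and bpEnergy follow their definitions", {
  expect_equal(gcCount("GCGC"), 4)
  expect_equal(gcCount("AAAA"), 0)
  expect_equal(gcCount("AUGC"), 2)
  expect_error(gcCount("AXU"), class = "treefeat_alphabet_error")
  tab <- bpEnergyTable(GC = -3.5)
  expect_equal(bpEnergy("GAAC", "(..)", tab), -3.5)
  expect_equal(bpEnergy("AAAA", "....", tab), 0)
  expect_equal(bpEnergy("GAAG", "(..)", tab), Inf)   # GG is not canonical
  # random noncrossing structure: equals the per-pair manual sum
  withr::with_seed(3, {
    for (rep in 1:10) {
      st <- randomStructures(10, 1, seed = rep)[[1]]
      seq <- randomRna(10)
      manual <- 0
      for (r in seq_len(nrow(st@pairs))) {
        pt <- paste0(substr(seq, st@pairs[r, 1], st@pairs[r, 1]),
                     substr(seq, st@pairs[r, 2], st@pairs[r, 2]))
        manual <- manual + if (pt %in% names(tab)) tab[[pt]] else Inf
      }
      expect_equal(bpEnergy(seq, st, tab), manual)
    }
  })
})

test_that("design models count and sample exactly", {
  # valid sequence count = 6^pairs * 4^unpaired on a noncrossing structure
  for (db in c("((..))", "(.(..).)", "().....")) {
    net <- designModel(db)
    p <- nrow(parseDotBracket(db)@pairs)
    u <- nchar(db) - 2 * p
    w0 <- setNames(c(0, 0), c("gc", "E1"))
    expect_equal(partitionFunction(net, w0), 6^p * 4^u)
  }
  # every sampled sequence is canonical at every target pair
  net <- designModel("((...))")
  st <- parseDotBracket("((...))")
  S <- sampleNetwork(net, c(gc = 0, E1 = 0), n = 60, seed = 5)
  for (r in seq_len(nrow(S)))
    expect_true(all(isCanonicalPair(S[r, st@pairs[, 1]], S[r, st@pairs[, 2]])))
  # crossing targets are rejected in strict mode, allowed behind the flag
  expect_error(designModel("([)]"), class = "treefeat_parse_error")
  expect_equal(partitionFunction(designModel("([)]", allowCrossing = TRUE),
                                 c(gc = 0, E1 = 0)),
               sum(sapply(0:255, function(i) {
                 s <- c(i %% 4, i %/% 4 %% 4, i %/% 16 %% 4, i %/% 64) + 1
                 isCanonicalPair(s[1], s[3]) && isCanonicalPair(s[2], s[4])
               })))
  expect_error(designModel(list("(..)", "(.)")),
               class = "treefeat_parse_error")
})

test_that("design sampling follows the product Boltzmann law", {
  tab <- bpEnergyTable()
  net <- designModel("((..))", table = tab)
  w <- c(gc = 0.4, E1 = -0.6)
  bf <- enumNet(net, w)
  probs <- exp(bf$E) * bf$valid
  probs <- probs / sum(probs)
  S <- sampleNetwork(net, w, n = 20000, seed = 6)
  obs <- tabulate(bf$encodeRows(S), nbins = bf$total)
  expect_gt(chisqPooledP(obs[probs > 0], probs[probs > 0]), 0.001)
  # P(s) factorizes as exp(a_gc #GC) * exp(a_1 E1): check against direct
  # per-sequence computation for a few sampled sequences
  for (r in c(1, 7, 42)) {
    s <- codesToRna(S[r, ])
    expect_equal(bf$E[bf$encodeRows(S[r, , drop = FALSE])],
                 0.4 * gcCount(s) - 0.6 * bpEnergy(s, "((..))", tab))
  }
})

test_that("the stop-codon automaton has 5 states and the right language", {
  dfa <- ahoCorasickDfa(c("UGA", "UUA", "UUG"))
  expect_equal(dfa@nStates, 5L)
  expect_true(dfaAccepts(dfa, "UGA"))
  expect_false(dfaAccepts(dfa, "AAA"))
  expect_false(dfaAccepts(dfa, ""))      # q0 not accepting
  words3 <- apply(expand.grid(RNA_ALPHABET, RNA_ALPHABET, RNA_ALPHABET), 1,
                  paste, collapse = "")
  accepted <- words3[vapply(words3, function(w) dfaAccepts(dfa, w), TRUE)]
  expect_setequal(accepted, c("UGA", "UUA", "UUG"))
  expect_error(ahoCorasickDfa(c("UGA", "")), class = "treefeat_parse_error")
  expect_error(ahoCorasickDfa("UXA"), class = "treefeat_alphabet_error")
})

test_that("forbid mode matches a direct substring scan", {
  motifs <- c("GGA", "AU")
  dfa <- ahoCorasickDfa(motifs, mode = "forbid")
  withr::with_seed(8, {
    for (rep in 1:300) {
      w <- randomRna(sample(0:12, 1))
      hasMotif <- any(vapply(motifs, function(m)
        grepl(m, w, fixed = TRUE), TRUE))
      expect_identical(dfaAccepts(dfa, w), !hasMotif)
    }
  })
})

test_that("DFA model counts equal direct enumeration of accepted words", {
  for (mode in c("accept", "forbid")) {
    dfa <- ahoCorasickDfa(c("GGG", "UA"), mode = mode)
    for (n in c(2, 4, 5)) {
      words <- apply(expand.grid(rep(list(RNA_ALPHABET), n)), 1,
                     paste, collapse = "")
      direct <- sum(vapply(words, function(w) dfaAccepts(dfa, w), TRUE))
      expect_equal(partitionFunction(dfaModel(dfa, n)), direct)
    }
  }
  expect_error(dfaModel(new("DFA", nStates = 1L, alphabet = "A",
                            transition = matrix(1L, 1, 1), initial = 1L,
                            accepting = integer(0)), 2),
               class = "treefeat_domain_error")
})

test_that("merging motif control into a design model composes correctly", {
  st <- parseDotBracket("((..))..")
  net <- designModel(st)
  dfaF <- ahoCorasickDfa("GGG", mode = "forbid")
  merged <- dfaModel(dfaF, 8, into = net)
  S <- sampleNetwork(merged, c(gc = 0, E1 = 0), n = 50, seed = 9)
  seqs <- apply(S[, 1:8, drop = FALSE], 1, codesToRna)
  expect_true(all(vapply(seqs, function(w) dfaAccepts(dfaF, w), TRUE)))
  expect_true(all(apply(S, 1, function(x)
    all(isCanonicalPair(x[st@pairs[, 1]], x[st@pairs[, 2]])))))
  # merged count equals the direct filter of the design-only language
  only <- sampleNetwork(net, c(gc = 0, E1 = 0), n = 0, seed = 1)  # build check
  bf <- enumNet(net, c(gc = 0, E1 = 0))
  keep <- which(bf$valid)
  direct <- sum(vapply(keep, function(r)
    dfaAccepts(dfaF, codesToRna(bf$decodeRow(r))), TRUE))
  expect_equal(partitionFunction(merged, c(gc = 0, E1 = 0)), direct)
})
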