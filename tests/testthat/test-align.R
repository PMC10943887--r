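# Alignment models: worked example, encoding bijection, direct scoring,
# independent DP oracles, affine gaps, structure alignment, banding.

# second sequence as spelled in the worked alignment (three matches,
# three insertions, three deletions, score 6 - 3 - 3 = 0)
WA <- "AAACUGG"
WB <- "ACGAGGC"
WENC <- c(0, 0, 1, 4, 5, 5, 5, 6, 8)

test_that("the worked alignment encoding evaluates to 0 and decodes exactly", {
  net <- linearAlignModel(WA, WB, alignScheme(match = 2, mismatch = 0,
                                              gamma = -1))
  expect_true(isValid(net, WENC))
  expect_equal(evaluateAssignment(net, WENC), 0)
  cols <- decodeAlignment(WENC, WA, WB)
  expect_equal(nrow(cols), 10)
  expect_equal(sum(cols$type == "deletion"), 3)
  expect_equal(sum(cols$type == "insertion"), 3)
  expect_equal(sum(cols$type == "match"), 3)
  expect_equal(sum(cols$type == "mismatch"), 1)
  expect_equal(paste(cols$a, collapse = ""), "AA--ACUGG-")
  expect_equal(paste(cols$b, collapse = ""), "-ACGAG--GC")
  expect_equal(scoreColumns(cols, alignScheme(match = 2, gamma = -1)), 0)
})

test_that("identity alignment is optimal for identical sequences", {
  a <- "GAUUACA"
  sch <- alignScheme(match = 1, mismatch = 0, gamma = -1)
  res <- optimizeNetwork(linearAlignModel(a, a, sch))
  expect_equal(res$value, nchar(a))
  expect_equal(res$assignment[seq_len(nchar(a) + 2)], 0:(nchar(a) + 1))
})

test_that("encode and decode are mutually inverse on random alignments", {
  withr::with_seed(14, {
    for (rep in 1:60) {
      n <- sample(2:6, 1); m <- sample(2:6, 1)
      a <- randomRna(n); b <- randomRna(m)
      encs <- allAlignEncodings(n, m)
      x <- encs[sample(nrow(encs), 1), ]
      cols <- decodeAlignment(x, a, b)
      expect_identical(encodeAlignment(cols, n, m), as.integer(x))
      # well-formedness: stripping gaps recovers a and b
      expect_equal(paste(cols$a[cols$a != "-"], collapse = ""), a)
      expect_equal(paste(cols$b[cols$b != "-"], collapse = ""), b)
    }
  })
  expect_error(decodeAlignment(c(0, 2, 1, 4), "AC", "ACG"),
               class = "treefeat_invalid_assignment")
})

test_that("model evaluation equals direct column scoring (linear, exact)", {
  sch <- alignScheme(match = 3, mismatch = -1, gamma = -2)
  withr::with_seed(15, {
    for (rep in 1:25) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      a <- randomRna(n); b <- randomRna(m)
      net <- linearAlignModel(a, b, sch)
      encs <- allAlignEncodings(n, m)
      for (r in sample(nrow(encs), 5)) {
        x <- encs[r, ]
        expect_identical(evaluateAssignment(net, x),
                         scoreColumns(decodeAlignment(x, a, b), sch))
      }
    }
  })
})

test_that("linear optima equal the Needleman-Wunsch oracle", {
  withr::with_seed(16, {
    for (rep in 1:20) {
      a <- randomRna(sample(2:8, 1)); b <- randomRna(sample(2:8, 1))
      sch <- alignScheme(match = sample(1:3, 1), mismatch = sample(-1:0, 1),
                         gamma = -sample(1:2, 1))
      expect_identical(optimizeNetwork(linearAlignModel(a, b, sch))$value,
                       nwOracle(a, b, sch))
    }
  })
})

test_that("affine gap runs are charged beta once per run", {
  sch <- alignScheme(match = 2, mismatch = 0, gamma = -1, beta = -2)
  # single insertion run of length 3 vs three isolated insertions
  one <- data.frame(a = c("A", "-", "-", "-", "A"),
                    b = c("A", "C", "C", "C", "A"),
                    type = c("match", rep("insertion", 3), "match"))
  three <- data.frame(a = c("A", "-", "A", "-", "A", "-", "A"),
                      b = c("A", "C", "A", "C", "A", "C", "A"),
                      type = c("match", "insertion", "match", "insertion",
                               "match", "insertion", "match"))
  expect_equal(scoreColumns(one, sch), 2 * 2 + (-2 + 3 * -1))
  expect_equal(scoreColumns(three, sch), 4 * 2 + 3 * (-2 + -1))
  # model agreement: affine evaluation = affine column score on encodings
  withr::with_seed(17, {
    for (rep in 1:10) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      a <- randomRna(n); b <- randomRna(m)
      net <- affineAlignModel(a, b, sch)
      encs <- allAlignEncodings(n, m)
      x <- encs[sample(nrow(encs), 1), ]
      y <- as.integer(diff(x[seq_len(n + 1)]) > 0)
      expect_equal(evaluateAssignment(net, c(x, y)),
                   scoreColumns(decodeAlignment(x, a, b), sch))
    }
  })
})

test_that("affine optima equal the Gotoh oracle; beta = 0 degenerates", {
  withr::with_seed(18, {
    for (rep in 1:20) {
      a <- randomRna(sample(2:8, 1)); b <- randomRna(sample(2:8, 1))
      sch <- alignScheme(match = 3, mismatch = -1, gamma = -2, beta = -3)
      expect_identical(optimizeNetwork(affineAlignModel(a, b, sch))$value,
                       gotohOracle(a, b, sch))
    }
    for (rep in 1:10) {
      a <- randomRna(sample(2:7, 1)); b <- randomRna(sample(2:7, 1))
      sch0 <- alignScheme(match = 2, mismatch = 0, gamma = -1, beta = 0)
      lin <- alignScheme(match = 2, mismatch = 0, gamma = -1)
      expect_identical(optimizeNetwork(affineAlignModel(a, b, sch0))$value,
                       optimizeNetwork(linearAlignModel(a, b, lin))$value)
    }
  })
  expect_error(affineAlignModel("AC", "AC", alignScheme()),
               class = "treefeat_domain_error")
})

test_that("structure alignment awards tau exactly for matched canonical arcs", {
  sch <- alignScheme(match = 1, mismatch = 0, gamma = -1, tau = 5)
  lin <- alignScheme(match = 1, mismatch = 0, gamma = -1)
  # tau = 0 reduces to the sequence model
  sch0 <- alignScheme(match = 1, mismatch = 0, gamma = -1, tau = 0)
  withr::with_seed(19, {
    for (rep in 1:8) {
      n <- sample(3:6, 1); m <- sample(3:6, 1)
      a <- randomRna(n); b <- randomRna(m)
      S <- randomStructures(n, 1, seed = rep + 30)[[1]]
      expect_identical(
        optimizeNetwork(structureAlignModel(a, S, b, sch0))$value,
        optimizeNetwork(linearAlignModel(a, b, lin))$value)
    }
  })
  # brute force over all alignments with the arc bonus
  withr::with_seed(20, {
    for (rep in 1:8) {
      n <- sample(3:5, 1); m <- sample(3:6, 1)
      a <- randomRna(n); b <- randomRna(m)
      S <- randomStructures(n, 1, crossing = TRUE, seed = rep + 60,
                            pairProb = 0.6)[[1]]
      encs <- allAlignEncodings(n, m)
      brute <- max(apply(encs, 1, directStructureScore, a = a, b = b,
                         scheme = sch, pairs = S@pairs))
      expect_equal(optimizeNetwork(structureAlignModel(a, S, b, sch))$value,
                   brute)
    }
  })
})

test_that("a deleted arc endpoint never earns the arc bonus", {
  # arc (1,4) on a; force deletion of position 1 by a huge bonus bait:
  # b = GC, a = GAAC; if (1,4) matched to (1,2) = (G,C) it is canonical,
  # but deleting 1 and 4 must yield no tau even though b[x] values repeat
  sch <- alignScheme(match = 0, mismatch = 0, gamma = 0, tau = 7)
  net <- structureAlignModel("GAAC", "(..)", "GC", sch)
  # encoding deleting position 1: x = (0,0,1,2,2?,...) choose all deleted
  x <- c(0, 0, 0, 0, 0, 3)           # every position deleted
  y <- c(0, 0, 0, 0)
  expect_equal(evaluateAssignment(net, c(x, y)), 0)
  # matched endpoints (1 -> 1, 4 -> 2) do earn it
  x2 <- c(0, 1, 1, 1, 2, 3); y2 <- c(1, 0, 0, 1)
  expect_equal(evaluateAssignment(net, c(x2, y2)), 7)
})

test_that("banding restricts domains but keeps wide-band optima", {
  a <- randomRna(6); b <- randomRna(6)
  sch <- alignScheme(match = 2, mismatch = 0, gamma = -1)
  full <- optimizeNetwork(linearAlignModel(a, b, sch))$value
  wide <- optimizeNetwork(linearAlignModel(a, b, sch, band = 6))$value
  expect_identical(wide, full)
  banded <- linearAlignModel(a, b, sch, band = 1)
  doms <- variableDomains(banded)
  expect_lte(max(lengths(doms[2:7])), 3)
})
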