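# Built-in fixtures: the running graph-coloring example and seeded random
# generators for every model family (download-free test inputs).

#' The running graph-coloring instance
#'
#' A 9-vertex graph with 4 colors whose edge set is the union of the scored
#' 4-cycles (ordered so that the two worked-example colorings are proper)
#' plus connector edges `1-2` and `4-5` for the remaining vertices.  The
#' cardinality feature scores the three 4-cycles `(2,3,5,6)`, `(2,5,7,8)`
#' and `(5,6,7,8)`.
#'
#' @return list with `nVertices`, `edges` (2-column matrix), `k` (colors)
#'   and `cycles` (list of ordered vertex quadruples)
#' @export
coloringInstance <- function() {
  edges <- rbind(
    c(2, 3), c(3, 6), c(5, 6), c(2, 5),   # cycle through {2,3,5,6}
    c(5, 7), c(7, 8), c(2, 8),            # cycle through {2,5,7,8} (2-5 above)
    c(6, 7), c(5, 8),                     # cycle through {5,6,7,8}
    c(6, 8), c(8, 9), c(5, 9),            # fourth drawn cycle {5,6,8,9}
    c(1, 2), c(4, 5))                     # connectors
  list(nVertices = 9L, edges = edges, k = 4L,
       cycles = list(c(2L, 3L, 5L, 6L), c(2L, 5L, 7L, 8L), c(5L, 6L, 7L, 8L)))
}

.NotEquals <- defineConstraintType("NotEquals", function(v) v[1] != v[2])
.Card <- defineFunctionType("Card", function(v) length(unique(v)))

#' Graph-coloring feature network
#'
#' One variable per vertex with domain `1..k`, a `NotEquals` constraint per
#' edge, and one 4-ary `Card` function (number of distinct colors) per
#' listed 4-cycle, grouped into the feature `card`.  At all weights 1 the
#' two worked colorings `(1,2,3,3,4,2,1,3,1)` and `(1,2,4,3,4,2,1,3,1)`
#' evaluate to 11 and 10.
#'
#' @param instance as returned by [coloringInstance()]
#' @return a [FeatureNetwork-class]
#' @export
coloringModel <- function(instance = coloringInstance()) {
  for (cy in instance$cycles)
    if (length(cy) != 4L)
      .tfStop("scored cycles must have length 4", "treefeat_domain_error")
  net <- addVariables(featureNetwork(), instance$nVertices,
                      seq_len(instance$k))
  for (r in seq_len(nrow(instance$edges)))
    net <- addConstraint(net, .NotEquals(instance$edges[r, ]))
  addFunctions(net, "card", lapply(instance$cycles, .Card))
}

#' Random partial k-tree (treewidth <= k by construction)
#'
#' Builds a k-tree (start from a (k+1)-clique, attach each new vertex to a
#' random existing k-clique) and then keeps each edge independently with
#' probability `keepProb`; the construction order certifies treewidth at
#' most `k`.
#'
#' @param n number of vertices (> k)
#' @param k clique parameter (>= 1)
#' @param keepProb edge retention probability
#' @param seed RNG seed (deterministic output; caller RNG untouched)
#' @return a [DependencyHypergraph-class] with binary edges
#' @export
randomPartialKtree <- function(n, k, keepProb = 1, seed = 1L) {
  stopifnot(n > k, k >= 1L)
  .withSeed(seed, {
    edges <- list()
    cliques <- utils::combn(k + 1L, k, simplify = FALSE)  # k-cliques so far
    for (i in seq_len(k + 1L)) for (j in .seq2(i + 1L, k + 1L))
      edges[[length(edges) + 1L]] <- c(i, j)
    for (v in .seq2(k + 2L, n)) {
      base <- cliques[[sample.int(length(cliques), 1L)]]
      for (u in base) edges[[length(edges) + 1L]] <- c(u, v)
      for (u in base)
        cliques[[length(cliques) + 1L]] <- sort(c(setdiff(base, u), v))
    }
    keep <- runif(length(edges)) <= keepProb
    hypergraph(n, edges[keep])
  })
}

#' Random secondary structures
#'
#' Draws the number of pairs as `Binomial(floor(n/2), pairProb)` (so the
#' expected pair density, paired positions over n, is about `pairProb`),
#' places the paired positions uniformly, and matches them either by a
#' uniformly random noncrossing matching or, with `crossing = TRUE`, by a
#' uniformly random (generally crossing) matching; both are triplet-free by
#' construction.
#'
#' @param n structure length
#' @param count number of structures
#' @param crossing allow crossing pairs
#' @param pairProb target pair density
#' @param seed RNG seed
#' @return list of [SecondaryStructure-class]
#' @export
randomStructures <- function(n, count, crossing = FALSE, pairProb = 0.3,
                             seed = 1L) {
  ncMatch <- function(pts) {
    if (length(pts) == 0L) return(matrix(integer(0), 0, 2))
    # match pts[1] to a partner leaving even-size gaps; recurse both sides
    h <- length(pts) / 2L
    partner <- 2L * sample.int(h, 1L)
    rbind(c(pts[1L], pts[partner]),
          ncMatch(pts[.seq2(2L, partner - 1L)]),
          ncMatch(pts[.seq2(partner + 1L, length(pts))]))
  }
  .withSeed(seed, lapply(seq_len(count), function(dummy) {
    p <- rbinom(1L, floor(n / 2), pairProb)
    if (p == 0L) return(secondaryStructure(n))
    pts <- sort(sample.int(n, 2L * p))
    pairs <- if (crossing) {
      perm <- matrix(sample(pts), ncol = 2L)
      t(apply(perm, 1L, sort))
    } else ncMatch(pts)
    secondaryStructure(n, pairs)
  }))
}

#' Random binary phylogenetic network
#'
#' Grows a random rooted binary tree on `nLeaves` leaves, then creates each
#' reticulation by subdividing two tree edges and adding a new edge between
#' the subdivision points (checked to keep the graph acyclic and binary).
#'
#' @param nLeaves number of leaves (>= 2)
#' @param nReticulations number of reticulation nodes (>= 0)
#' @param seed RNG seed
#' @return a [PhyloNetwork-class]
#' @export
randomBinaryNetwork <- function(nLeaves, nReticulations = 0L, seed = 1L) {
  stopifnot(nLeaves >= 2L, nReticulations >= 0L)
  .withSeed(seed, {
    # random binary tree: repeatedly join two roots under a fresh parent
    nodes <- seq_len(nLeaves)
    nextId <- nLeaves
    roots <- nodes
    edges <- matrix(integer(0), 0, 2)
    while (length(roots) > 1L) {
      pick <- sample.int(length(roots), 2L)
      nextId <- nextId + 1L
      edges <- rbind(edges, c(roots[pick[1L]], nextId),
                     c(roots[pick[2L]], nextId))
      roots <- c(roots[-pick], nextId)
    }
    descends <- function(edges, from, of) {
      # is `from` a descendant of (or equal to) `of`?
      frontier <- of
      while (length(frontier)) {
        if (from %in% frontier) return(TRUE)
        frontier <- edges[edges[, 2L] %in% frontier, 1L]
      }
      FALSE
    }
    for (r in seq_len(nReticulations)) {
      placed <- FALSE
      for (attempt in 1:100) {
        ePair <- sample.int(nrow(edges), 2L)
        e1 <- edges[ePair[1L], ]; e2 <- edges[ePair[2L], ]
        # subdivision point of e2 must not be below e1's child, else a cycle
        if (descends(edges, e2[2L], e1[1L])) next
        a <- nextId + 1L; b <- nextId + 2L; nextId <- nextId + 2L
        edges <- edges[-ePair, , drop = FALSE]
        edges <- rbind(edges,
                       c(e1[1L], a), c(a, e1[2L]),   # a splits e1 (a = reticulation)
                       c(e2[1L], b), c(b, e2[2L]),   # b splits e2
                       c(a, b))
        placed <- TRUE
        break
      }
      if (!placed)
        .tfStop("could not place requested reticulations", "treefeat_phylo_error")
    }
    phyloNetwork(edges, nNodes = nextId)
  })
}

#' Random small feature network (engine stress fixture)
#'
#' Draws a network with up to `maxVars` variables over random integer
#' domains (size <= `maxDomain`), and up to `maxItems` random constraints
#' and tabulated functions of arity <= `maxArity`, split over one to three
#' features.  Constraint predicates are random tables with the given
#' satisfaction probability; function values are small random integers.
#' Small enough for exhaustive enumeration, rich enough to exercise the
#' engine (including infeasible instances).
#'
#' @param seed RNG seed
#' @param maxVars,maxDomain,maxItems,maxArity size bounds
#' @param satisfaction probability a random constraint row is TRUE
#' @return a [FeatureNetwork-class]
#' @export
randomFeatureNetwork <- function(seed, maxVars = 8L, maxDomain = 4L,
                                 maxItems = 12L, maxArity = 3L,
                                 satisfaction = 0.8) {
  RandTable <- defineConstraintType("RandTable", function(v, dims, doms, tab) {
    idx <- 1L
    stride <- 1L
    for (j in seq_along(dims)) {
      idx <- idx + (match(v[j], doms[[j]]) - 1L) * stride
      stride <- stride * dims[j]
    }
    tab[idx]
  })
  RandFun <- defineFunctionType("RandFun", function(v, dims, doms, tab) {
    idx <- 1L
    stride <- 1L
    for (j in seq_along(dims)) {
      idx <- idx + (match(v[j], doms[[j]]) - 1L) * stride
      stride <- stride * dims[j]
    }
    tab[idx]
  })
  .withSeed(seed, {
    nv <- sample(2:maxVars, 1L)
    net <- featureNetwork()
    for (i in seq_len(nv)) {
      sz <- sample.int(maxDomain, 1L)
      net <- addVariables(net, 1L, sort(sample(-3:9, sz)))
    }
    nItems <- sample.int(maxItems, 1L)
    featPool <- paste0("f", seq_len(sample.int(3L, 1L)))
    for (it in seq_len(nItems)) {
      ar <- sample.int(min(maxArity, nv), 1L)
      scope <- sort(sample.int(nv, ar))
      doms <- variableDomains(net)[scope]
      dims <- lengths(doms)
      if (runif(1) < 0.4) {
        tab <- runif(prod(dims)) < satisfaction
        net <- addConstraint(net, RandTable(scope, dims = dims, doms = doms,
                                            tab = tab))
      } else {
        tab <- as.numeric(sample(-3:3, prod(dims), replace = TRUE))
        net <- addFunctions(net, sample(featPool, 1L),
                            RandFun(scope, dims = dims, doms = doms, tab = tab))
      }
    }
    net
  })
}
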