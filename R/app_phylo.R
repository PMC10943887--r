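# Small parsimony on phylogenetic networks: hardwired (all parent edges
# charged) and softwired (each node inherits from its best parent, realized
# by Boolean selector variables at reticulations), plus a Sankoff tree
# oracle for cross-checks.

#' Construct a phylogenetic network from a child -> parent edge list
#'
#' Validates rootedness (a unique parentless node), connectedness and
#' acyclicity.
#'
#' @param edges two-column matrix (or data.frame), column 1 child id,
#'   column 2 parent id
#' @param nNodes number of nodes (default: largest id)
#' @return a [PhyloNetwork-class]
#' @export
phyloNetwork <- function(edges, nNodes = max(edges)) {
  e <- matrix(as.integer(as.matrix(edges)), ncol = 2L)
  net <- new("PhyloNetwork", nNodes = as.integer(nNodes), edges = e)
  hasParent <- unique(e[, 1L])
  roots <- setdiff(seq_len(net@nNodes), hasParent)
  if (length(roots) != 1L)
    .tfStop("network must have a unique root (one parentless node)",
            "treefeat_phylo_error")
  # acyclicity by topological elimination of parentless nodes
  remaining <- e
  alive <- rep(TRUE, net@nNodes)
  repeat {
    tops <- setdiff(which(alive), remaining[, 1L])
    if (length(tops) == 0L) break
    alive[tops] <- FALSE
    remaining <- remaining[!(remaining[, 2L] %in% tops), , drop = FALSE]
  }
  if (any(alive)) .tfStop("network contains a cycle", "treefeat_phylo_error")
  comp <- rep(FALSE, net@nNodes)
  comp[roots] <- TRUE
  repeat {
    new <- unique(e[comp[e[, 2L]], 1L])
    if (all(comp[new])) break
    comp[new] <- TRUE
  }
  if (!all(comp)) .tfStop("network is not connected", "treefeat_phylo_error")
  net
}

#' Structural accessors of a phylogenetic network
#' @param net a [PhyloNetwork-class]
#' @return integer vector of node ids
#' @export
networkRoot <- function(net) setdiff(seq_len(net@nNodes), net@edges[, 1L])

#' @rdname networkRoot
#' @export
networkLeaves <- function(net) setdiff(seq_len(net@nNodes), net@edges[, 2L])

#' @rdname networkRoot
#' @export
reticulationNodes <- function(net) {
  tab <- table(net@edges[, 1L])
  as.integer(names(tab)[tab > 1L])
}

#' Is the network binary (at most two children and two parents per node)?
#' @param net a [PhyloNetwork-class]
#' @export
isBinaryNetwork <- function(net) {
  max(table(factor(net@edges[, 1L], seq_len(net@nNodes)))) <= 2L &&
    max(table(factor(net@edges[, 2L], seq_len(net@nNodes)))) <= 2L
}

.Distance <- defineFunctionType("Distance", function(v)
  as.numeric(v[1] != v[2]))
# An unselected reticulation edge contributes 0 (not +Inf): with both parent
# edges of a reticulation carrying an RDistance, exactly one of them is
# unselected for either selector value, so an infinite penalty would exclude
# every labeling; the 0 contribution realizes the per-node
# min-over-parents softwired score.
.RDistance <- defineFunctionType("RDistance", function(v, r)
  if (v[3] == r) as.numeric(v[1] != v[2]) else 0)

.checkLabeling <- function(net, sigma, phi) {
  leaves <- networkLeaves(net)
  phiIds <- as.integer(names(phi))
  if (!setequal(phiIds, leaves))
    .tfStop("leaf labeling must cover exactly the leaves",
            "treefeat_phylo_error")
  codes <- match(phi, sigma)
  if (anyNA(codes))
    .tfStop("leaf label outside the character alphabet", "treefeat_phylo_error")
  setNames(as.integer(codes), names(phi))
}

#' Hardwired network parsimony model
#'
#' One variable per network node whose value encodes its character; leaf
#' domains are fixed by the labeling (all constraints are expressed as
#' domain restrictions, so there are no constraints), and one 0/1
#' `Distance` function per edge forms the single feature `parsimony`.  The
#' dependency graph of this model is exactly the input network.  Minimal
#' parsimony scores are obtained by maximizing at weight -1 and negating
#' (see [parsimonyOptimize()]).
#'
#' @param net a [PhyloNetwork-class]
#' @param sigma character alphabet (vector; labels are matched against it)
#' @param phi leaf labeling: vector of characters named by leaf node id
#' @return a [FeatureNetwork-class]
#' @export
hardwiredModel <- function(net, sigma, phi) {
  codes <- .checkLabeling(net, sigma, phi)
  fn <- featureNetwork()
  for (v in seq_len(net@nNodes)) {
    dom <- if (as.character(v) %in% names(codes)) codes[[as.character(v)]]
           else seq_along(sigma)
    fn <- addVariables(fn, 1L, dom)
  }
  fn <- addFunctions(fn, "parsimony",
    lapply(seq_len(nrow(net@edges)), function(r) .Distance(net@edges[r, ])))
  fn
}

#' Softwired network parsimony model (binary networks)
#'
#' Extends the hardwired model by a Boolean selector variable per
#' reticulation node; each reticulation edge carries an `RDistance` that
#' evaluates to the 0/1 distance when the selector picks its parent (`r = 0`
#' for the first-seen "left" parent, `r = 1` for the "right") and `+Inf`
#' otherwise, so that under weight -1 the unselected parent edge is excluded
#' and each reticulation inherits from exactly one parent.
#'
#' @inheritParams hardwiredModel
#' @return a [FeatureNetwork-class]; selector variables follow the node
#'   variables in reticulation-node order
#' @export
softwiredModel <- function(net, sigma, phi) {
  if (!isBinaryNetwork(net))
    .tfStop("softwired model requires a binary network", "treefeat_phylo_error")
  codes <- .checkLabeling(net, sigma, phi)
  fn <- featureNetwork()
  for (v in seq_len(net@nNodes)) {
    dom <- if (as.character(v) %in% names(codes)) codes[[as.character(v)]]
           else seq_along(sigma)
    fn <- addVariables(fn, 1L, dom)
  }
  rets <- reticulationNodes(net)
  yOf <- setNames(net@nNodes + seq_along(rets), rets)
  for (i in seq_along(rets)) fn <- addVariables(fn, 1L, 0:1)
  funcs <- list()
  seen <- integer(0)
  for (r in seq_len(nrow(net@edges))) {
    child <- net@edges[r, 1L]; parent <- net@edges[r, 2L]
    if (child %in% rets) {
      side <- sum(seen == child)       # 0 for left (first-seen), 1 for right
      seen <- c(seen, child)
      funcs[[length(funcs) + 1L]] <-
        .RDistance(c(child, parent, yOf[[as.character(child)]]), r = side)
    } else {
      funcs[[length(funcs) + 1L]] <- .Distance(c(child, parent))
    }
  }
  addFunctions(fn, "parsimony", funcs)
}

#' Direct parsimony score of a full labeling
#'
#' Hardwired mode sums the 0/1 distance over every edge; softwired mode
#' charges each non-root node only for its most favorable parent.
#'
#' @param net a [PhyloNetwork-class]
#' @param psi full labeling: vector of character codes (or characters)
#'   indexed by node id
#' @param mode `"hardwired"` or `"softwired"`
#' @param phi optional leaf labeling to check `psi` against
#' @export
parsimonyScore <- function(net, psi, mode = c("hardwired", "softwired"),
                           phi = NULL) {
  mode <- match.arg(mode)
  if (!is.null(phi)) {
    for (v in names(phi))
      if (psi[[as.integer(v)]] != phi[[v]])
        .tfStop("labeling conflicts with the leaf labeling",
                "treefeat_phylo_error")
  }
  d <- function(x, y) as.numeric(x != y)
  if (mode == "hardwired") {
    sum(vapply(seq_len(nrow(net@edges)), function(r)
      d(psi[[net@edges[r, 1L]]], psi[[net@edges[r, 2L]]]), 0))
  } else {
    s <- 0
    for (u in seq_len(net@nNodes)) {
      parents <- net@edges[net@edges[, 1L] == u, 2L]
      if (length(parents))
        s <- s + min(vapply(parents, function(p) d(psi[[u]], psi[[p]]), 0))
    }
    s
  }
}

#' Solve network parsimony by cluster-tree elimination
#'
#' Builds the hardwired or softwired model, maximizes at feature weight -1
#' and reports the negated optimum as the parsimony score together with an
#' optimal labeling.
#'
#' @inheritParams hardwiredModel
#' @param mode `"hardwired"` or `"softwired"`
#' @param ... passed to [optimizeNetwork()]
#' @return list with `score`, `labeling` (characters from `sigma` per
#'   node) and `width`
#' @export
parsimonyOptimize <- function(net, sigma, phi,
                              mode = c("hardwired", "softwired"), ...) {
  mode <- match.arg(mode)
  model <- if (mode == "hardwired") hardwiredModel(net, sigma, phi)
           else softwiredModel(net, sigma, phi)
  res <- optimizeNetwork(model, weights = c(parsimony = -1), ...)
  list(score = -res$value,
       labeling = sigma[res$assignment[seq_len(net@nNodes)]],
       width = res$width)
}

#' Sankoff dynamic-programming oracle for tree parsimony
#'
#' Classic bottom-up minimum-mutation DP on trees (an error is raised if
#' the input has reticulations); written independently of the engine as a
#' cross-check for the network models.
#'
#' @inheritParams hardwiredModel
#' @param d optional substitution cost matrix `|sigma| x |sigma|`
#'   (default 0/1)
#' @return the minimum parsimony score
#' @export
sankoffOracle <- function(net, sigma, phi, d = NULL) {
  if (length(reticulationNodes(net)))
    .tfStop("Sankoff oracle requires a tree (no reticulations)",
            "treefeat_phylo_error")
  codes <- .checkLabeling(net, sigma, phi)
  k <- length(sigma)
  if (is.null(d)) { d <- matrix(1, k, k); diag(d) <- 0 }
  children <- lapply(seq_len(net@nNodes), function(v)
    net@edges[net@edges[, 2L] == v, 1L])
  cost <- matrix(Inf, net@nNodes, k)
  recurse <- function(v) {
    if (length(children[[v]]) == 0L) {
      cost[v, codes[[as.character(v)]]] <<- 0
      return(invisible(NULL))
    }
    for (c in children[[v]]) recurse(c)
    for (s in seq_len(k)) {
      tot <- 0
      for (c in children[[v]])
        tot <- tot + min(cost[c, ] + d[s, ])
      cost[v, s] <<- tot
    }
  }
  root <- networkRoot(net)
  recurse(root)
  min(cost[root, ])
}

setMethod("show", "PhyloNetwork", function(object) {
  cat(sprintf("PhyloNetwork: %d nodes, %d edges, %d leaves, %d reticulations\n",
              object@nNodes, nrow(object@edges),
              length(networkLeaves(object)),
              length(reticulationNodes(object))))
})
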