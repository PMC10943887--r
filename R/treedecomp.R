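# Tree decompositions: min-fill heuristic, gentle normalization, validation,
# and an exact small-instance treewidth oracle.

# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Primal (cliquified) adjacency matrix of a hypergraph.
.primalAdjacency <- function(h) {
  n <- h@nVariables
  A <- matrix(FALSE, n, n)
  for (e in h@hyperedges) {
    if (length(e) >= 2L) {
      A[e, e] <- TRUE
    }
  }
  diag(A) <- FALSE
  A
}

#' Children lists of a tree decomposition
#' @param td a [TreeDecomposition-class]
#' @return list of integer vectors, children per node
#' @export
tdChildren <- function(td) {
  ch <- vector("list", length(td@bags))
  for (u in seq_along(td@parent)) {
    p <- td@parent[u]
    if (!is.na(p)) ch[[p]] <- c(ch[[p]], u)
  }
  ch
}

#' Separator and difference sets of a tree decomposition
#'
#' For each non-root node `u`, `sep(u)` is the intersection of its bag with
#' the parent bag and `diff(u)` the remainder; together they partition the
#' bag.  The root gets empty sets.
#'
#' @param td a [TreeDecomposition-class]
#' @return list with components `sep` and `diff`, each a list per node of
#'   sorted integer vectors
#' @export
tdSeparators <- function(td) {
  k <- length(td@bags)
  sep <- vector("list", k); dif <- vector("list", k)
  for (u in seq_len(k)) {
    p <- td@parent[u]
    if (is.na(p)) {
      sep[[u]] <- integer(0); dif[[u]] <- sort(td@bags[[u]])
    } else {
      sep[[u]] <- sort(intersect(td@bags[[u]], td@bags[[p]]))
      dif[[u]] <- sort(setdiff(td@bags[[u]], td@bags[[p]]))
    }
  }
  list(sep = sep, diff = dif)
}

#' Width of a tree decomposition
#' @param td a [TreeDecomposition-class]
#' @return largest bag size minus one
#' @export
tdWidth <- function(td) max(vapply(td@bags, length, 0L)) - 1L

#' Is a tree decomposition gentle?
#'
#' Gentle means: the root bag is empty and every non-root node introduces
#' exactly one variable (`|diff(u)| == 1`); gentle decompositions have
#' exactly one tree edge per variable.
#'
#' @param td a [TreeDecomposition-class]
#' @export
isGentle <- function(td) {
  if (length(td@bags[[td@root]]) != 0L) return(FALSE)
  sd <- tdSeparators(td)
  all(vapply(seq_along(td@bags), function(u)
    u == td@root || length(sd$diff[[u]]) == 1L, TRUE))
}

#' Min-fill tree decomposition heuristic
#'
#' Repeatedly eliminates a vertex with minimum fill-in (number of missing
#' edges among its neighbors) from the primal graph of `h` (each hyperedge
#' cliquified), breaking ties uniformly at random; the bag of an eliminated
#' vertex is the vertex plus its current neighborhood.  The minimum-width
#' decomposition over `restarts` randomized runs is returned; results are
#' deterministic for a fixed `seed` and leave the caller's RNG untouched.
#'
#' @param h a [DependencyHypergraph-class]
#' @param seed integer seed for the randomized tie-breaking
#' @param restarts number of randomized runs (default 20)
#' @return a valid [TreeDecomposition-class] (rooted at an added empty bag)
#' @export
minFillDecompose <- function(h, seed = 1L, restarts = 20L) {
  n <- h@nVariables
  if (n < 1L) .tfStop("empty hypergraph", "treefeat_domain_error")
  A0 <- .primalAdjacency(h)
  best <- NULL; bestWidth <- Inf
  for (r in seq_len(restarts)) {
    td <- .withSeed(seed + r - 1L, .minFillOnce(A0))
    w <- tdWidth(td)
    if (w < bestWidth) { best <- td; bestWidth <- w }
  }
  best
}

.minFillOnce <- function(A0) {
  n <- nrow(A0)
  A <- A0
  alive <- rep(TRUE, n)
  order <- integer(n); bags <- vector("list", n)
  for (step in seq_len(n)) {
    cand <- which(alive)
    fill <- vapply(cand, function(v) {
      nb <- which(A[v, ] & alive)
      if (length(nb) < 2L) return(0L)
      sub <- A[nb, nb, drop = FALSE]
      as.integer((length(nb) * (length(nb) - 1L) - sum(sub)) / 2L)
    }, 0L)
    minf <- min(fill)
    ties <- cand[fill == minf]
    v <- if (length(ties) == 1L) ties else ties[sample.int(length(ties), 1L)]
    nb <- which(A[v, ] & alive)
    order[step] <- v
    bags[[step]] <- sort(c(v, nb))
    if (length(nb) >= 2L) A[nb, nb] <- TRUE
    diag(A) <- FALSE
    alive[v] <- FALSE
  }
  # Elimination-tree construction: parent of bag(step) is the bag of the
  # first-eliminated later vertex of its neighborhood; roots attach to a
  # fresh empty bag.
  elimStep <- integer(n); elimStep[order] <- seq_len(n)
  k <- n + 1L
  parent <- rep(NA_integer_, k)
  for (step in seq_len(n)) {
    rest <- setdiff(bags[[step]], order[step])
    parent[step] <- if (length(rest)) min(elimStep[rest]) else k
  }
  bags[[k]] <- integer(0)
  new("TreeDecomposition", bags = bags, parent = parent, root = k,
      nVariables = n)
}

#' Exact treewidth of a small hypergraph
#'
#' Dynamic programming over subsets of eliminated vertices (the elimination
#' degree of a vertex depends only on the eliminated set, not the order).
#' Serves as an independent oracle for the heuristic; guarded to at most 14
#' vertices.
#'
#' @param h a [DependencyHypergraph-class] with `<= 14` vertices
#' @return the minimum width over all tree decompositions
#' @export
exactTreewidth <- function(h) {
  n <- h@nVariables
  if (n > 14L) .tfStop("exactTreewidth is limited to 14 vertices",
                       "treefeat_size_error")
  if (n == 1L) return(0L)
  A <- .primalAdjacency(h)
  adjMask <- vapply(seq_len(n), function(v)
    sum(bitwShiftL(1L, which(A[v, ]) - 1L)), 0L)
  adjMask <- as.integer(adjMask)
  full <- bitwShiftL(1L, n) - 1L
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  popcount <- function(m) { c <- 0L; while (m > 0L) { c <- c + bitwAnd(m, 1L); m <- bitwShiftR(m, 1L) }; c }
  pc <- vapply(0:full, popcount, 0L)
  # effective degree of v after eliminating set S: vertices outside S
  # reachable from v through S
  elimDeg <- function(v, S) {
    reach <- adjMask[v]; processed <- 0L
    repeat {
      new <- bitwAnd(bitwAnd(reach, S), bitwNot(processed))
      if (new == 0L) break
      processed <- bitwOr(processed, new)
      for (b in which(bitwAnd(new, bit) != 0L)) reach <- bitwOr(reach, adjMask[b])
    }
    pc[bitwAnd(reach, bitwAnd(bitwNot(S), bitwNot(bit[v]))) + 1L]
  }
  f <- rep(Inf, full + 1L)
  f[full + 1L] <- -Inf
  bySize <- split(0:(full - 1L), pc[(0:(full - 1L)) + 1L])
  for (size in sort(as.integer(names(bySize)), decreasing = TRUE)) {
    for (S in bySize[[as.character(size)]]) {
      bestv <- Inf
      for (v in seq_len(n)) {
        if (bitwAnd(S, bit[v]) != 0L) next
        val <- max(elimDeg(v, S), f[bitwOr(S, bit[v]) + 1L])
        if (val < bestv) bestv <- val
      }
      f[S + 1L] <- bestv
    }
  }
  as.integer(f[1L])
}

#' Validate a tree decomposition against a hypergraph
#'
#' Reports each defining condition separately: (1) every variable occurs in
#' some bag, (2) every hyperedge is contained in some bag, (3) the nodes
#' containing any given variable form a connected subtree; plus gentleness.
#'
#' @param td a [TreeDecomposition-class]
#' @param h a [DependencyHypergraph-class]
#' @return list with logical components `coverage`, `hyperedges`,
#'   `connectivity`, `gentle`, and `valid` (conjunction of the first three)
#' @export
validateTd <- function(td, h) {
  n <- h@nVariables
  inBags <- sort(unique(unlist(td@bags)))
  coverage <- setequal(inBags, seq_len(n)) || (n == 0L)
  hyperedges <- all(vapply(h@hyperedges, function(e)
    any(vapply(td@bags, function(b) all(e %in% b), TRUE)), TRUE))
  connectivity <- TRUE
  for (v in seq_len(n)) {
    nodes <- which(vapply(td@bags, function(b) v %in% b, TRUE))
    if (length(nodes) == 0L) { connectivity <- FALSE; next }
    nedges <- sum(!is.na(td@parent[nodes]) & td@parent[nodes] %in% nodes)
    if (nedges != length(nodes) - 1L) connectivity <- FALSE
  }
  list(coverage = coverage, hyperedges = hyperedges,
       connectivity = connectivity, gentle = isGentle(td),
       valid = coverage && hyperedges && connectivity)
}

#' Normalize a tree decomposition to gentle form
#'
#' Inserts an empty root above the old root if needed, replaces every node
#' introducing several variables by a chain of bags each introducing exactly
#' one variable (in ascending variable-index order), and contracts edges
#' that introduce none.  Width and validity are preserved; the result has
#' exactly one tree edge per variable.
#'
#' @param td a valid [TreeDecomposition-class]
#' @return a gentle [TreeDecomposition-class]
#' @export
makeGentle <- function(td) {
  children <- tdChildren(td)
  newBags <- list(integer(0))       # node 1: the empty root
  newParent <- NA_integer_
  attach <- function(u, parentNode, parentBag) {
    bag <- sort(td@bags[[u]])
    dif <- setdiff(bag, parentBag)
    sepv <- intersect(bag, parentBag)
    node <- parentNode
    acc <- sort(sepv)
    for (v in dif) {               # ascending order: dif is sorted
      acc <- sort(c(acc, v))
      newBags[[length(newBags) + 1L]] <<- acc
      newParent[length(newParent) + 1L] <<- node
      node <- length(newBags)
    }
    for (c in children[[u]]) attach(c, node, bag)
  }
  attach(td@root, 1L, integer(0))
  new("TreeDecomposition", bags = newBags, parent = newParent, root = 1L,
      nVariables = td@nVariables)
}

#' Write / read a tree decomposition in a simple text format
#'
#' One line per bag (`bag <id> <var> ...`) and one per edge
#' (`edge <child> <parent>`); readable again with [readTd()], e.g. to inject
#' externally computed decompositions.
#'
#' @param td a [TreeDecomposition-class]
#' @param file path or connection
#' @export
writeTd <- function(td, file) {
  lines <- c(
    sprintf("nvars %d", td@nVariables),
    vapply(seq_along(td@bags), function(u)
      trimws(paste("bag", u, paste(td@bags[[u]], collapse = " "))), ""),
    vapply(which(!is.na(td@parent)), function(u)
      paste("edge", u, td@parent[u]), ""))
  writeLines(lines, file)
}

#' @rdname writeTd
#' @export
readTd <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "\\s+")
  nv <- 0L; bags <- list(); parent <- integer(0)
  for (tk in toks) {
    if (tk[1] == "nvars") nv <- as.integer(tk[2])
    else if (tk[1] == "bag") {
      id <- as.integer(tk[2])
      bags[[id]] <- if (length(tk) > 2L) sort(as.integer(tk[-(1:2)])) else integer(0)
      if (length(parent) < id) parent[id] <- NA_integer_
    } else if (tk[1] == "edge") {
      parent[as.integer(tk[2])] <- as.integer(tk[3])
    }
  }
  length(parent) <- length(bags)
  root <- which(is.na(parent))
  if (length(root) != 1L) .tfStop("malformed decomposition file: no unique root",
                                  "treefeat_io_error")
  new("TreeDecomposition", bags = bags, parent = parent, root = root,
      nVariables = nv)
}

setMethod("show", "TreeDecomposition", function(object) {
  cat(sprintf("TreeDecomposition: %d bags over %d variables, width %d%s\n",
              length(object@bags), object@nVariables, tdWidth(object),
              if (isGentle(object)) " (gentle)" else ""))
})
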