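# Cluster-tree elimination engine: algebra-generic forward message passing
# over a gentle tree decomposition, plus optimal and stochastic traceback.
#
# Message tables are dense vectors indexed by a mixed-radix encoding of bag
# assignments with the (single, gentle) difference variable as the fastest
# radix; the entries for one separator assignment are therefore contiguous,
# which both tracebacks exploit.

#' Evaluation algebras
#'
#' `maxAlgebra()` is the optimization algebra (max, +, Id) with excluded
#' value `-Inf`; `sumAlgebra()` is the partition-function/sampling algebra
#' (+, x, exp) with excluded value `0 = exp(-Inf)`.
#'
#' @return an [Algebra-class]
#' @export
maxAlgebra <- function() new("Algebra",
  choose = function(a, b) pmax(a, b), combine = `+`, lift = identity,
  neutralChoose = -Inf, neutralCombine = 0, excluded = -Inf, tag = "max")

#' @rdname maxAlgebra
#' @export
sumAlgebra <- function() new("Algebra",
  choose = `+`, combine = `*`, lift = exp,
  neutralChoose = 0, neutralCombine = 1, excluded = 0, tag = "sum")

.algebraTag <- function(algebra) {
  if (is(algebra, "Algebra")) return(algebra@tag)
  match.arg(algebra, c("max", "sum"))
}

.postorder <- function(td) {
  children <- tdChildren(td)
  out <- integer(0)
  walk <- function(u) {
    for (c in children[[u]]) walk(c)
    out[[length(out) + 1L]] <<- u
  }
  walk(td@root)
  out
}

.preorder <- function(td) rev(.postorder(td))

#' Build a cluster tree: place constraints and functions on a decomposition
#'
#' Every constraint and network function is assigned to the lowest (deepest)
#' node whose bag contains its scope; with a gentle decomposition this node
#' is unique up to bags of equal depth, in which case the smallest node id
#' is taken.  An error is raised if some scope is covered by no bag (the
#' decomposition is then invalid for this network).
#'
#' @param net a [FeatureNetwork-class]
#' @param td a gentle, valid [TreeDecomposition-class] for
#'   `dependencyGraph(net)`
#' @return a [ClusterTree-class]
#' @export
buildClusterTree <- function(net, td) {
  if (!isGentle(td)) .tfStop("cluster trees require a gentle decomposition",
                             "treefeat_td_error")
  depth <- integer(length(td@bags))
  for (u in .preorder(td)) {
    p <- td@parent[u]
    depth[u] <- if (is.na(p)) 0L else depth[p] + 1L
  }
  place <- function(scope) {
    cand <- which(vapply(td@bags, function(b) all(scope %in% b), TRUE))
    if (length(cand) == 0L)
      .tfStop("scope not covered by any bag: decomposition invalid for this network",
              "treefeat_td_error")
    cand[which.max(depth[cand])]
  }
  consNode <- vapply(net@constraints, function(co) place(co@scope), 0L)
  rows <- list()
  for (nm in names(net@features)) {
    fe <- net@features[[nm]]
    for (i in seq_along(fe@functions))
      rows[[length(rows) + 1L]] <-
        data.frame(feature = nm, index = i,
                   node = place(fe@functions[[i]]@scope),
                   stringsAsFactors = FALSE)
  }
  ft <- if (length(rows)) do.call(rbind, rows)
        else data.frame(feature = character(0), index = integer(0),
                        node = integer(0))
  new("ClusterTree", network = net, td = td,
      constraintNode = as.integer(consNode), functionTable = ft)
}

#' Constraints and functions placed at one node
#' @param ct a [ClusterTree-class]
#' @param u node id
#' @return list with components `constraints` (list of [Constraint-class])
#'   and `functions` (data.frame `feature`, `index`)
#' @export
placedAt <- function(ct, u) {
  list(constraints = ct@network@constraints[ct@constraintNode == u],
       functions = ct@functionTable[ct@functionTable$node == u,
                                    c("feature", "index"), drop = FALSE])
}

# Tabulate one constraint/function over the full grid of its scope domains.
.materializeItem <- function(item, domains, logicalValues = FALSE) {
  doms <- domains[item@scope]
  dims <- lengths(doms)
  total <- prod(dims)
  strides <- cumprod(c(1L, dims))[seq_along(dims)]
  V <- vapply(seq_along(dims), function(j)
    doms[[j]][((seq_len(total) - 1L) %/% strides[j]) %% dims[j] + 1L],
    integer(total))
  if (total == 1L) V <- matrix(V, nrow = 1L)
  vals <- apply(V, 1L, function(row) item@fn(row))
  if (logicalValues) vals <- as.logical(vals) else vals <- as.numeric(vals)
  list(dims = as.integer(dims), strides = as.numeric(strides), values = vals)
}

#' Materialize the value tables of all placed constraints and functions
#'
#' Each k-ary constraint/function is evaluated once for every assignment of
#' its scope and tabulated (`d^k` entries), so that forward passes only read
#' tables; semantics are unchanged by referential transparency.  Items whose
#' table would exceed `maxEntries` fall back to on-the-fly evaluation (a
#' message is emitted).  The total space used is `O(d^k m)` for `m` items.
#'
#' @param ct a [ClusterTree-class]
#' @param maxEntries per-item table size cap
#' @return a table set for [forwardPass()]; its attribute `entries` reports
#'   the total number of tabulated entries
#' @export
precomputeTables <- function(ct, maxEntries = 1e7) {
  net <- ct@network
  entries <- 0
  tabOrNull <- function(item, logical) {
    sz <- prod(lengths(net@domains[item@scope]))
    if (sz > maxEntries) {
      message("table for ", item@name, " exceeds cap (", sz,
              " entries); evaluating on the fly")
      return(NULL)
    }
    entries <<- entries + sz
    .materializeItem(item, net@domains, logical)
  }
  cons <- lapply(net@constraints, tabOrNull, logical = TRUE)
  funcs <- lapply(net@features, function(fe)
    lapply(fe@functions, tabOrNull, logical = FALSE))
  structure(list(constraints = cons, functions = funcs), entries = entries)
}

# Per-row table indices of an item on the implicit bag grid.  `pos` holds the
# 0-based position vectors of the bag variables; `bagVars` their ids.
.itemIndex <- function(scope, strides, pos, bagVars) {
  idx <- rep(1, length(pos[[1L]]))
  for (j in seq_along(scope))
    idx <- idx + pos[[match(scope[j], bagVars)]] * strides[j]
  idx
}

#' Forward pass: bottom-up message passing over a cluster tree
#'
#' For each non-root node `u` and each assignment of `sep(u)`, the message
#' to the parent is the choose-combination (max or sum) over the values of
#' the single difference variable of: the lifted, weighted values of the
#' constraints/functions placed at `u`, combined (plus or times) with the
#' child messages — invalid extensions contribute the algebra's excluded
#' value.  The root value is the combine-combination of the 0-ary messages
#' sent to the root: the optimal evaluation (max algebra) or the partition
#' function (sum algebra).  An infeasible network yields the excluded value
#' (`-Inf` or `0`).
#'
#' @param ct a [ClusterTree-class]
#' @param weights named numeric feature weights (default all 1)
#' @param algebra an [Algebra-class] or `"max"`/`"sum"`
#' @param tabulate evaluate items through materialized tables (default) or
#'   row by row (identical results; for cross-checking)
#' @param tables optional precomputed tables from [precomputeTables()]
#' @return a [ForwardResult-class]
#' @export
forwardPass <- function(ct, weights = NULL, algebra = "sum", tabulate = TRUE,
                        tables = NULL) {
  tag <- .algebraTag(algebra)
  net <- ct@network
  td <- ct@td
  w <- .fullWeights(net, weights)
  k <- length(td@bags)
  sd <- tdSeparators(td)
  children <- tdChildren(td)
  post <- .postorder(td)
  messages <- vector("list", k)
  tablesW <- vector("list", k)
  layout <- vector("list", k)
  if (is.null(tables) && tabulate) tables <- precomputeTables(ct)

  evalItem <- function(item, tab, pos, bagVars, vals, logicalValues) {
    if (!is.null(tab))
      return(tab$values[.itemIndex(item@scope, tab$strides, pos, bagVars)])
    V <- vapply(item@scope, function(v) vals[[match(v, bagVars)]],
                integer(length(pos[[1L]])))
    if (length(pos[[1L]]) == 1L) V <- matrix(V, nrow = 1L)
    out <- apply(V, 1L, function(row) item@fn(row))
    if (logicalValues) as.logical(out) else as.numeric(out)
  }

  for (u in post) {
    if (u == td@root) next
    sepv <- sd$sep[[u]]
    dvar <- sd$diff[[u]]
    bagVars <- c(dvar, sepv)
    doms <- net@domains[bagVars]
    dims <- lengths(doms)
    total <- prod(dims)
    strides <- cumprod(c(1, dims))[seq_along(dims)]
    pos <- lapply(seq_along(dims), function(j)
      ((seq_len(total) - 1L) %/% strides[j]) %% dims[j])
    vals <- lapply(seq_along(dims), function(j) doms[[j]][pos[[j]] + 1L])

    score <- numeric(total)
    valid <- rep(TRUE, total)
    for (ci in which(ct@constraintNode == u)) {
      co <- net@constraints[[ci]]
      tabc <- if (is.null(tables)) NULL else tables$constraints[[ci]]
      cv <- evalItem(co, tabc, pos, bagVars, vals, TRUE)
      valid <- valid & cv
    }
    ftab <- ct@functionTable
    frows <- which(ftab$node == u)
    for (r in frows) {
      alpha <- w[[ftab$feature[r]]]
      if (alpha == 0) next
      f <- net@features[[ftab$feature[r]]]@functions[[ftab$index[r]]]
      tabf <- if (is.null(tables)) NULL
              else tables$functions[[ftab$feature[r]]][[ftab$index[r]]]
      fv <- evalItem(f, tabf, pos, bagVars, vals, FALSE)
      score <- score + alpha * fv
    }
    if (tag == "max") {
      W <- score
      W[!valid] <- -Inf
    } else {
      W <- exp(score)
      W[!valid] <- 0
    }
    for (c in children[[u]]) {
      csep <- sd$sep[[c]]
      cdims <- lengths(net@domains[csep])
      cstr <- cumprod(c(1, cdims))[seq_along(csep)]
      cidx <- .itemIndex(csep, cstr, pos, bagVars)
      mv <- messages[[c]][cidx]
      W <- if (tag == "max") W + mv else W * mv
    }
    d1 <- dims[1L]
    nSep <- total %/% d1
    mat <- matrix(W, nrow = d1)
    if (tag == "max") {
      msg <- mat[1L, ]
      if (d1 > 1L) for (r in 2:d1) msg <- pmax(msg, mat[r, ])
    } else {
      msg <- .colSums(mat, d1, nSep)
    }
    messages[[u]] <- msg
    tablesW[[u]] <- W
    layout[[u]] <- list(diffVar = dvar, sepVars = sepv, d1 = d1,
                        diffDomain = doms[[1L]],
                        sepDomains = doms[-1L],
                        sepStrides = cumprod(c(1, dims[-1L]))[seq_along(sepv)])
  }
  rootKids <- children[[td@root]]
  vals0 <- vapply(rootKids, function(c) messages[[c]][1L], 0)
  rootValue <-
    if (length(rootKids) == 0L) { if (tag == "max") 0 else 1 }
    else if (tag == "max") sum(vals0) else prod(vals0)
  if (tag == "sum" && (is.nan(rootValue) || is.infinite(rootValue)))
    .tfStop("partition function overflowed double precision; rescale feature weights",
            "treefeat_overflow")
  new("ForwardResult", rootValue = rootValue, messages = messages,
      tables = tablesW, layout = layout, algebraTag = tag, weights = w,
      clusterTree = ct, preorder = as.integer(.preorder(td)))
}

#' Root value of a forward pass
#' @param fw a [ForwardResult-class]
#' @export
rootValue <- function(fw) fw@rootValue

# 0-based separator index per sample row; X is an n x nVariables matrix.
.sepIndices <- function(lay, X) {
  idx <- rep(0, nrow(X))
  for (j in seq_along(lay$sepVars)) {
    p <- match(X[, lay$sepVars[j]], lay$sepDomains[[j]]) - 1L
    idx <- idx + p * lay$sepStrides[j]
  }
  idx
}

#' Optimal traceback: recover one maximizing assignment
#'
#' Walks the cluster tree top-down in preorder; at each node the value of
#' the single introduced variable is chosen (first value in ascending domain
#' order) so that the bag evaluation reproduces the message sent to the
#' parent.  The result is a valid total assignment whose evaluation equals
#' the forward root value.
#'
#' @param fw a [ForwardResult-class] computed with the max algebra
#' @return integer assignment vector
#' @export
optimalTraceback <- function(fw) {
  if (fw@algebraTag != "max")
    .tfStop("optimal traceback requires a max-algebra forward pass",
            "treefeat_algebra_error")
  if (fw@rootValue == -Inf)
    .tfStop("infeasible: no valid assignment", "treefeat_infeasible")
  net <- fw@clusterTree@network
  x <- matrix(NA_integer_, 1L, nVariables(net))
  root <- fw@clusterTree@td@root
  for (u in fw@preorder) {
    if (u == root) next
    lay <- fw@layout[[u]]
    base <- lay$d1 * .sepIndices(lay, x)
    wv <- fw@tables[[u]][base + seq_len(lay$d1)]
    x[1L, lay$diffVar] <- lay$diffDomain[which.max(wv)]
  }
  as.integer(x[1L, ])
}

# Vectorized batch of stochastic tracebacks (rows = samples).
.traceSamples <- function(fw, n) {
  net <- fw@clusterTree@network
  root <- fw@clusterTree@td@root
  X <- matrix(NA_integer_, n, nVariables(net))
  if (n == 0L) return(X)
  for (u in fw@preorder) {
    if (u == root) next
    lay <- fw@layout[[u]]
    d1 <- lay$d1
    base <- d1 * .sepIndices(lay, X)
    idx <- rep(base, each = d1) + seq_len(d1)
    M <- matrix(fw@tables[[u]][idx], nrow = d1)
    if (d1 > 1L) for (r in 2:d1) M[r, ] <- M[r, ] + M[r - 1L, ]
    t <- runif(n) * M[d1, ]
    j <- if (d1 == 1L) rep(1L, n)
         else 1L + .colSums(M[-d1, , drop = FALSE] <=
                              matrix(t, d1 - 1L, n, byrow = TRUE), d1 - 1L, n)
    X[, lay$diffVar] <- lay$diffDomain[j]
  }
  X
}

#' Stochastic traceback: draw one exact Boltzmann sample
#'
#' Walks the cluster tree top-down; at each node a tracking value `t` is
#' drawn uniformly between 0 and the message value for the current separator
#' assignment, and the introduced variable's value is selected once `t`,
#' decremented by the partial Boltzmann factors, becomes negative.  The
#' returned assignment is valid and distributed as
#' `P(x) = exp(E(x, alpha)) / Z`.
#'
#' @param fw a [ForwardResult-class] computed with the sum algebra
#' @return integer assignment vector
#' @export
stochasticTraceback <- function(fw) {
  if (fw@algebraTag != "sum")
    .tfStop("stochastic traceback requires a sum-algebra forward pass",
            "treefeat_algebra_error")
  if (fw@rootValue <= 0)
    .tfStop("infeasible: no valid assignment", "treefeat_infeasible")
  as.integer(.traceSamples(fw, 1L)[1L, ])
}

#' Dump message tables as TSV (debugging aid)
#'
#' One block per non-root node: separator assignment columns plus the
#' message value.
#'
#' @param fw a [ForwardResult-class]
#' @param file path or connection
#' @export
writeMessages <- function(fw, file) {
  con <- if (is.character(file)) file(file, "w") else file
  if (is.character(file)) on.exit(close(con))
  root <- fw@clusterTree@td@root
  for (u in fw@preorder) {
    if (u == root) next
    lay <- fw@layout[[u]]
    msg <- fw@messages[[u]]
    hdr <- paste(c(sprintf("node_%d", u),
                   sprintf("X%d", lay$sepVars), "value"), collapse = "\t")
    writeLines(hdr, con)
    nSep <- length(msg)
    for (s in seq_len(nSep) - 1L) {
      assn <- vapply(seq_along(lay$sepVars), function(j)
        lay$sepDomains[[j]][(s %/% lay$sepStrides[j]) %% length(lay$sepDomains[[j]]) + 1L],
        0L)
      writeLines(paste(c("", assn, format(msg[s + 1L], digits = 17)),
                       collapse = "\t"), con)
    }
  }
  invisible(NULL)
}

setMethod("show", "ClusterTree", function(object) {
  cat(sprintf("ClusterTree: %d bags, width %d; %d constraints, %d functions placed\n",
              length(object@td@bags), tdWidth(object@td),
              length(object@constraintNode), nrow(object@functionTable)))
})

setMethod("show", "ForwardResult", function(object) {
  what <- if (object@algebraTag == "max") "E_max" else "Z"
  cat(sprintf("ForwardResult (%s algebra): %s = %g\n",
              object@algebraTag, what, object@rootValue))
})
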