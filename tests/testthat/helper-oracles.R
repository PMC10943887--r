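# Independent oracles used across the suite.  These enumerate the full
# assignment grid directly (no tree decomposition, no message passing), so
# they share no code path with the engine they check.

# Exhaustive enumeration of a feature network: validity mask and weighted
# evaluation for every point of the domain grid (vectorized via per-item
# value tables; the grid itself is implicit mixed-radix).
enumNet <- function(net, weights = NULL) {
  doms <- variableDomains(net)
  dims <- lengths(doms)
  total <- prod(dims)
  strides <- cumprod(c(1, dims))[seq_along(dims)]
  pos <- lapply(seq_along(dims), function(j)
    ((seq_len(total) - 1) %/% strides[j]) %% dims[j])
  tabIdx <- function(scope) {
    sdims <- lengths(doms[scope])
    sstr <- cumprod(c(1, sdims))[seq_along(scope)]
    idx <- rep(1, total)
    for (j in seq_along(scope)) idx <- idx + pos[[scope[j]]] * sstr[j]
    idx
  }
  tabOf <- function(item) {
    sdims <- lengths(doms[item@scope])
    tt <- prod(sdims)
    sstr <- cumprod(c(1, sdims))[seq_along(sdims)]
    V <- sapply(seq_along(sdims), function(j)
      doms[[item@scope[j]]][((seq_len(tt) - 1) %/% sstr[j]) %% sdims[j] + 1])
    if (tt == 1) V <- matrix(V, nrow = 1)
    apply(V, 1, function(r) item@fn(r))
  }
  valid <- rep(TRUE, total)
  for (co in net@constraints)
    valid <- valid & as.logical(tabOf(co))[tabIdx(co@scope)]
  w <- setNames(rep(1, length(featureNames(net))), featureNames(net))
  if (!is.null(weights)) w[names(weights)] <- weights
  E <- numeric(total)
  featTotals <- list()
  for (nm in featureNames(net)) {
    Fv <- numeric(total)
    for (f in net@features[[nm]]@functions)
      Fv <- Fv + as.numeric(tabOf(f))[tabIdx(f@scope)]
    featTotals[[nm]] <- Fv
    if (w[[nm]] != 0) E <- E + w[[nm]] * Fv
  }
  # decode row r of the implicit grid into an assignment vector
  decodeRow <- function(r) {
    vapply(seq_along(dims), function(j)
      doms[[j]][((r - 1) %/% strides[j]) %% dims[j] + 1], 0L)
  }
  # mixed-radix cell index (1-based) of an assignment matrix (rows = samples)
  encodeRows <- function(X) {
    idx <- rep(1, nrow(X))
    for (j in seq_along(dims))
      idx <- idx + (match(X[, j], doms[[j]]) - 1) * strides[j]
    idx
  }
  list(valid = valid, E = E, total = total, features = featTotals,
       decodeRow = decodeRow, encodeRows = encodeRows)
}

bruteMax <- function(bf) if (any(bf$valid)) max(bf$E[bf$valid]) else -Inf
bruteZ <- function(bf) sum(exp(bf$E[bf$valid]))

# Chi-square goodness of fit with pooling of low-expectation cells.
chisqPooledP <- function(obs, probs, minExpected = 5) {
  n <- sum(obs)
  expd <- n * probs
  big <- expd >= minExpected
  o <- c(obs[big], sum(obs[!big]))
  p <- c(probs[big], sum(probs[!big]))
  keep <- p > 0
  o <- o[keep]; p <- p[keep]
  stat <- sum((o - n * p)^2 / (n * p))
  stats::pchisq(stat, df = length(o) - 1, lower.tail = FALSE)
}

randomRna <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                               collapse = "")

# Exhaustive softwired parsimony: minimum over all 2^r selector fixings of
# the brute-force hardwired optimum on the displayed subgraph.
bruteSoftwired <- function(pn, sigma, phi) {
  rets <- reticulationNodes(pn)
  e <- pn@edges
  lv <- networkLeaves(pn)
  free <- setdiff(seq_len(pn@nNodes), lv)
  psi0 <- integer(pn@nNodes)
  psi0[lv] <- match(phi[as.character(lv)], sigma)
  grid <- as.matrix(expand.grid(rep(list(seq_along(sigma)), length(free))))
  combos <- as.matrix(expand.grid(rep(list(0:1), length(rets))))
  if (nrow(combos) == 0) combos <- matrix(0L, 1, 0)
  best <- Inf
  for (ci in seq_len(nrow(combos))) {
    keep <- rep(TRUE, nrow(e))
    for (j in seq_along(rets)) {
      pedges <- which(e[, 1] == rets[j])
      keep[pedges[if (combos[ci, j] == 0) 2 else 1]] <- FALSE
    }
    for (g in seq_len(max(1, nrow(grid)))) {
      psi <- psi0
      if (length(free)) psi[free] <- grid[g, ]
      s <- sum(psi[e[keep, 1]] != psi[e[keep, 2]])
      best <- min(best, s)
    }
  }
  best
}

# All encodings x_1..x_n (non-decreasing over 0..m) of alignments; returns a
# matrix of full value vectors including sentinels.  Independent alignment
# enumerator for small instances.
allAlignEncodings <- function(n, m) {
  rows <- list()
  grow <- function(prefix) {
    if (length(prefix) == n) {
      rows[[length(rows) + 1L]] <<- c(0L, prefix, m + 1L)
      return(invisible(NULL))
    }
    last <- if (length(prefix)) prefix[length(prefix)] else 0L
    for (v in last:m) grow(c(prefix, v))
  }
  grow(integer(0))
  do.call(rbind, rows)
}

# Direct score of an encoding under a linear scheme with an optional arc
# annotation (structure alignment oracle; no feature network involved).
directStructureScore <- function(x, a, b, scheme, pairs = NULL) {
  cols <- decodeAlignment(x, a, b)
  s <- scoreColumns(cols, scheme)
  if (!is.null(pairs) && nrow(pairs)) {
    n <- nchar(a)
    xv <- x[seq_len(n + 2)]
    bCodes <- rnaToCodes(b)
    matched <- c(FALSE, diff(xv[seq_len(n + 1)]) > 0)[-1]  # position i matched?
    for (r in seq_len(nrow(pairs))) {
      i <- pairs[r, 1]; j <- pairs[r, 2]
      if (matched[i] && matched[j] &&
          isCanonicalPair(bCodes[xv[i + 1]], bCodes[xv[j + 1]]))
        s <- s + scheme$tau
    }
  }
  s
}
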