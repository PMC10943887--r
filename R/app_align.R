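# Alignment models: linear gap, affine gap (Boolean match-state variables),
# and pseudoknot sequence-structure alignment, plus direct scoring, decoding
# and independent DP oracles.
#
# Position i of the first sequence is modeled by a variable whose value is
# the position of the second sequence it aligns to; deletion of i is encoded
# by repeating the previous value.  Sentinels X_0 = 0 and X_{n+1} = m+1 are
# explicit variables with singleton domains; X_i lives at R index i + 1.

.seq2 <- function(from, to) if (to >= from) from:to else integer(0)

#' Alignment scoring scheme
#'
#' Either scalar `match`/`mismatch` scores or a full symbol-pair matrix
#' `sigma` (with letter dimnames); `gamma` is the per-gap-position score.
#' Supplying the gap-opening score `beta` selects affine gap cost
#' `g(l) = beta + gamma * l`; omitting it, linear cost `g(l) = gamma * l`.
#' `tau` is the arc-match bonus of the sequence-structure model.
#'
#' @param match,mismatch scalar element scores (used when `sigma` is NULL;
#'   note sigma applies to every aligned pair, so mismatch columns score
#'   `mismatch`, 0 by default)
#' @param sigma optional square numeric matrix with identical row/column
#'   letter dimnames
#' @param gamma gap extension score per inserted/deleted position
#' @param beta optional gap opening score (affine mode)
#' @param tau optional arc match bonus
#' @export
alignScheme <- function(match = 2, mismatch = 0, sigma = NULL, gamma = -1,
                        beta = NULL, tau = NULL) {
  if (!is.null(sigma))
    stopifnot(is.matrix(sigma), !is.null(dimnames(sigma)),
              identical(rownames(sigma), colnames(sigma)))
  list(match = match, mismatch = mismatch, sigma = sigma, gamma = gamma,
       beta = beta, tau = tau)
}

.sigmaValue <- function(scheme, ca, cb) {
  if (!is.null(scheme$sigma)) scheme$sigma[ca, cb]
  else if (ca == cb) scheme$match else scheme$mismatch
}

.Leq <- defineConstraintType("Leq", function(v) v[1] <= v[2])
.Match <- defineFunctionType("Match", function(v, svals)
  if (v[1] < v[2]) svals[v[2]] else 0)
.Deletion <- defineFunctionType("Deletion", function(v, gamma)
  if (v[1] == v[2]) gamma else 0)
.DeletionOpen <- defineFunctionType("DeletionOpen", function(v, beta, gamma)
  if (v[1] == v[2]) beta + gamma else 0)
.DeletionAffine <- defineFunctionType("DeletionAffine",
  function(v, beta, gamma) {
    if (v[1] != v[2]) 0
    else if (v[3] == 1) beta + gamma   # previous position matched: gap opens
    else gamma                         # extends a deletion run
  })
.Insertion <- defineFunctionType("Insertion", function(v, gamma)
  if (v[1] != v[2]) gamma * (v[2] - v[1] - 1) else 0)
.InsertionAffine <- defineFunctionType("InsertionAffine",
  function(v, beta, gamma) {
    l <- v[2] - v[1] - 1
    if (v[1] != v[2] && l > 0) beta + gamma * l else 0
  })
.RelXY <- defineConstraintType("RelXY", function(v)
  v[3] == as.integer(v[1] < v[2]))
.BPMatch <- defineFunctionType("BPMatch", function(v, bCodes, tau) {
  if (v[3] == 1 && v[4] == 1 && v[1] >= 1 && v[2] >= 1 &&
      isCanonicalPair(bCodes[v[1]], bCodes[v[2]])) tau else 0
})

.xDomain <- function(i, n, m, band) {
  if (is.null(band)) return(0:m)
  anchor <- round(i * m / n)
  .seq2(max(0L, anchor - band), min(m, anchor + band))
}

.alignBase <- function(a, b, scheme, band) {
  n <- nchar(a); m <- nchar(b)
  if (n < 1L || m < 1L) .tfStop("empty sequence", "treefeat_parse_error")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  net <- addVariables(featureNetwork(), 1L, 0L)          # X_0
  for (i in seq_len(n)) net <- addVariables(net, 1L, .xDomain(i, n, m, band))
  net <- addVariables(net, 1L, m + 1L)                   # X_{n+1}
  for (i in .seq2(2L, n))
    net <- addConstraint(net, .Leq(c(i, i + 1L)))
  matches <- lapply(seq_len(n), function(i) {
    svals <- vapply(seq_len(m), function(j) .sigmaValue(scheme, av[i], bv[j]), 0)
    .Match(c(i, i + 1L), svals = svals)
  })
  net <- addFunctions(net, "match", matches)
  list(net = net, n = n, m = m)
}

#' Linear-gap sequence alignment model
#'
#' Variables `X_0..X_{n+1}` (sentinels fixed to 0 and m+1), `Leq`
#' monotonicity constraints, and features `match` (element scores when
#' `x_{i-1} < x_i`), `deletion` (`gamma` when `x_{i-1} = x_i`) and
#' `insertion` (`gamma (x_i - x_{i-1} - 1)` skipped positions of `b`).  The
#' optimum at weights 1 is the optimal alignment score.  `band` restricts
#' the domain of `X_i` to a window of half-width `band` around the diagonal
#' anchor `round(i m / n)` (a band too tight for any alignment surfaces as
#' an infeasible model at solve time).
#'
#' @param a,b sequences (character strings)
#' @param scheme an [alignScheme()] without `beta`
#' @param band optional non-negative integer
#' @return a [FeatureNetwork-class]
#' @export
linearAlignModel <- function(a, b, scheme = alignScheme(), band = NULL) {
  base <- .alignBase(a, b, scheme, band)
  net <- base$net; n <- base$n
  net <- addFunctions(net, "deletion", lapply(seq_len(n), function(i)
    .Deletion(c(i, i + 1L), gamma = scheme$gamma)))
  net <- addFunctions(net, "insertion", lapply(seq_len(n + 1L), function(i)
    .Insertion(c(i, i + 1L), gamma = scheme$gamma)))
  net
}

#' Affine-gap sequence alignment model
#'
#' Extends the linear model by Boolean match-state variables `Y_1..Y_n`
#' (`y_i = 1` iff position `i` is matched, tied by ternary constraints),
#' makes `Deletion` depend on `(X_{i-1}, X_i, Y_{i-1})` so a deletion
#' opening a gap costs `beta + gamma` and an extension `gamma`, and charges
#' insertion runs `g(l) = beta + gamma l` once per run.  With `beta = 0`
#' the optima coincide with the linear model.
#'
#' @inheritParams linearAlignModel
#' @param scheme an [alignScheme()] with `beta`
#' @return a [FeatureNetwork-class]; `Y_i` is variable `n + 2 + i`
#' @export
affineAlignModel <- function(a, b, scheme, band = NULL) {
  if (is.null(scheme$beta)) .tfStop("affine model requires beta",
                                    "treefeat_domain_error")
  base <- .alignBase(a, b, scheme, band)
  net <- base$net; n <- base$n
  for (i in seq_len(n)) net <- addVariables(net, 1L, 0:1)   # Y_i
  yv <- function(i) n + 2L + i
  for (i in seq_len(n))
    net <- addConstraint(net, .RelXY(c(i, i + 1L, yv(i))))
  dels <- c(list(.DeletionOpen(c(1L, 2L), beta = scheme$beta,
                               gamma = scheme$gamma)),
            lapply(.seq2(2L, n), function(i)
              .DeletionAffine(c(i, i + 1L, yv(i - 1L)),
                              beta = scheme$beta, gamma = scheme$gamma)))
  net <- addFunctions(net, "deletion", dels)
  net <- addFunctions(net, "insertion", lapply(seq_len(n + 1L), function(i)
    .InsertionAffine(c(i, i + 1L), beta = scheme$beta, gamma = scheme$gamma)))
  net
}

#' Pseudoknot sequence-structure alignment model
#'
#' The first sequence `a` carries an arc annotation `S` (crossing pairs
#' allowed).  On top of the linear-gap model, Boolean match indicators
#' `Y_1..Y_n` and one 4-ary `BPMatch` function per arc `(i, j)` award the
#' arc-match bonus `tau` when both endpoints are matched to positions of
#' `b` forming a canonical base pair.  The bonus cannot be expressed on
#' `(X_i, X_j)` alone because the canonical-pair test could spuriously hold
#' when `i` or `j` is deleted.
#'
#' @inheritParams linearAlignModel
#' @param S a [SecondaryStructure-class] or dot-bracket string for `a`
#' @param scheme an [alignScheme()] with `tau`
#' @return a [FeatureNetwork-class]
#' @export
structureAlignModel <- function(a, S, b, scheme, band = NULL) {
  if (is.null(scheme$tau)) .tfStop("structure model requires tau",
                                   "treefeat_domain_error")
  if (is.character(S)) S <- parseDotBracket(S)
  net <- linearAlignModel(a, b, scheme, band)
  n <- nchar(a)
  if (S@length != n) .tfStop("arc annotation length mismatch",
                             "treefeat_parse_error")
  for (i in seq_len(n)) net <- addVariables(net, 1L, 0:1)
  yv <- function(i) n + 2L + i
  for (i in seq_len(n))
    net <- addConstraint(net, .RelXY(c(i, i + 1L, yv(i))))
  bCodes <- rnaToCodes(b)
  if (nrow(S@pairs))
    net <- addFunctions(net, "bpmatch",
      lapply(seq_len(nrow(S@pairs)), function(r) {
        i <- S@pairs[r, 1L]; j <- S@pairs[r, 2L]
        .BPMatch(c(i + 1L, j + 1L, yv(i), yv(j)),
                 bCodes = bCodes, tau = scheme$tau)
      }))
  else net <- addFunctions(net, "bpmatch")
  net
}

#' Decode an alignment-model assignment into alignment columns
#'
#' Inverse of the value encoding: `x_{i-1} = x_i` is the deletion of `i`;
#' `x_{i-1} < x_i` matches `i` to `x_i` with `x_i - x_{i-1} - 1` insertion
#' columns before it.  Only the `n + 2` positional variables of the
#' assignment are consulted (extra Boolean variables are ignored).
#'
#' @param x assignment of an alignment model (values, not positions)
#' @param a,b the aligned sequences
#' @return data.frame with columns `a`, `b` (letters or `-`) and `type`
#'   (`match`, `mismatch`, `insertion`, `deletion`)
#' @export
decodeAlignment <- function(x, a, b) {
  n <- nchar(a); m <- nchar(b)
  xv <- as.integer(x[seq_len(n + 2L)])
  if (xv[1L] != 0L || xv[n + 2L] != m + 1L || is.unsorted(xv))
    .tfStop("not a valid alignment encoding", "treefeat_invalid_assignment")
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  ca <- character(0); cb <- character(0); ty <- character(0)
  prev <- 0L
  emitIns <- function(upto) {
    for (j in .seq2(prev + 1L, upto)) {
      ca <<- c(ca, "-"); cb <<- c(cb, bv[j]); ty <<- c(ty, "insertion")
    }
  }
  for (i in seq_len(n)) {
    xi <- xv[i + 1L]
    if (xi == prev) {
      ca <- c(ca, av[i]); cb <- c(cb, "-"); ty <- c(ty, "deletion")
    } else {
      emitIns(xi - 1L); prev <- xi
      ca <- c(ca, av[i]); cb <- c(cb, bv[xi])
      ty <- c(ty, if (av[i] == bv[xi]) "match" else "mismatch")
    }
  }
  emitIns(m)
  data.frame(a = ca, b = cb, type = ty, stringsAsFactors = FALSE)
}

#' Encode alignment columns back into assignment values
#'
#' Inverse of [decodeAlignment()] on well-formed alignments.
#'
#' @param columns data.frame as returned by [decodeAlignment()]
#' @param n,m sequence lengths
#' @return integer vector `x_0..x_{n+1}` of values
#' @export
encodeAlignment <- function(columns, n, m) {
  x <- integer(n + 2L)
  i <- 0L; j <- 0L
  for (r in seq_len(nrow(columns))) {
    if (columns$a[r] == "-") { j <- j + 1L }
    else if (columns$b[r] == "-") { i <- i + 1L; x[i + 1L] <- j }
    else { i <- i + 1L; j <- j + 1L; x[i + 1L] <- j }
  }
  x[1L] <- 0L; x[n + 2L] <- m + 1L
  x
}

#' Score alignment columns directly
#'
#' Element scores over aligned (match and mismatch) columns plus gap cost:
#' linear schemes charge `gamma` per gap column; affine schemes charge
#' `beta + gamma * l` per maximal run of `l` insertions or `l` deletions.
#' Used to cross-check model evaluations.
#'
#' @param columns data.frame as from [decodeAlignment()]
#' @param scheme an [alignScheme()]
#' @export
scoreColumns <- function(columns, scheme) {
  s <- 0
  aligned <- columns$type %in% c("match", "mismatch")
  for (r in which(aligned))
    s <- s + .sigmaValue(scheme, columns$a[r], columns$b[r])
  gapcols <- columns$type %in% c("insertion", "deletion")
  if (is.null(scheme$beta)) {
    s + scheme$gamma * sum(gapcols)
  } else {
    runs <- rle(columns$type)
    gl <- runs$lengths[runs$values %in% c("insertion", "deletion")]
    s + sum(scheme$beta + scheme$gamma * gl)
  }
}

#' Independent dynamic-programming alignment oracles
#'
#' `nwOracle` is a Needleman-Wunsch style quadratic DP for linear gap cost;
#' `gotohOracle` a three-state DP for affine cost `g(l) = beta + gamma l`.
#' Both are written independently of the feature-network engine and serve
#' as cross-checks of the model optima.
#'
#' @param a,b sequences
#' @param scheme an [alignScheme()]
#' @return the optimal alignment score
#' @export
nwOracle <- function(a, b, scheme = alignScheme()) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  g <- scheme$gamma
  M <- matrix(0, n + 1L, m + 1L)
  M[, 1L] <- g * (0:n); M[1L, ] <- g * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m))
    M[i + 1L, j + 1L] <- max(M[i, j] + .sigmaValue(scheme, av[i], bv[j]),
                             M[i, j + 1L] + g, M[i + 1L, j] + g)
  M[n + 1L, m + 1L]
}

#' @rdname nwOracle
#' @export
gotohOracle <- function(a, b, scheme) {
  n <- nchar(a); m <- nchar(b)
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  g <- scheme$gamma; be <- scheme$beta
  M <- matrix(-Inf, n + 1L, m + 1L)   # last column aligned
  D <- matrix(-Inf, n + 1L, m + 1L)   # last column deletes a_i
  I <- matrix(-Inf, n + 1L, m + 1L)   # last column inserts b_j
  M[1L, 1L] <- 0
  for (i in seq_len(n)) D[i + 1L, 1L] <- be + g * i
  for (j in seq_len(m)) I[1L, j + 1L] <- be + g * j
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- .sigmaValue(scheme, av[i], bv[j])
    M[i + 1L, j + 1L] <- s + max(M[i, j], D[i, j], I[i, j])
    D[i + 1L, j + 1L] <- max(M[i, j + 1L] + be + g, D[i, j + 1L] + g,
                             I[i, j + 1L] + be + g)
    I[i + 1L, j + 1L] <- max(M[i + 1L, j] + be + g, I[i + 1L, j] + g,
                             D[i + 1L, j] + be + g)
  }
  max(M[n + 1L, m + 1L], D[n + 1L, m + 1L], I[n + 1L, m + 1L])
}
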