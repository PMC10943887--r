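# User-facing solver facades and multidimensional Boltzmann sampling (MDBS).

# Shared pipeline: dependency graph -> min-fill -> gentle -> cluster tree.
.pipeline <- function(net, td = NULL, seed = 1L, restarts = 20L) {
  if (is.null(td)) {
    h <- dependencyGraph(net)
    td <- minFillDecompose(h, seed = seed, restarts = restarts)
  }
  if (!isGentle(td)) td <- makeGentle(td)
  buildClusterTree(net, td)
}

#' Exact optimization of a feature network
#'
#' Maximizes the weighted evaluation `E(x, alpha)` over all valid total
#' assignments via cluster-tree elimination (max algebra) and optimal
#' traceback.  For minimization, negate the relevant feature weights.
#'
#' @param net a [FeatureNetwork-class]
#' @param weights named feature weights (default all 1)
#' @param td optional [TreeDecomposition-class]; computed by min-fill if
#'   absent
#' @param seed,restarts passed to [minFillDecompose()]
#' @return list with `value` (the optimum), `assignment` (a maximizing valid
#'   assignment) and `width` (decomposition width used)
#' @export
optimizeNetwork <- function(net, weights = NULL, td = NULL, seed = 1L,
                            restarts = 20L) {
  ct <- .pipeline(net, td, seed, restarts)
  fw <- forwardPass(ct, weights, "max")
  list(value = fw@rootValue, assignment = optimalTraceback(fw),
       width = tdWidth(ct@td))
}

#' Partition function of a feature network
#'
#' Computes `Z = sum_x exp(E(x, alpha))` over valid total assignments (sum
#' algebra).  At all-zero weights this is the number of valid assignments.
#'
#' @inheritParams optimizeNetwork
#' @return the partition function (numeric scalar)
#' @export
partitionFunction <- function(net, weights = NULL, td = NULL, seed = 1L,
                              restarts = 20L) {
  ct <- .pipeline(net, td, seed, restarts)
  forwardPass(ct, weights, "sum")@rootValue
}

#' Exact Boltzmann sampling from a feature network
#'
#' One forward pass (sum algebra) followed by `n` independent stochastic
#' tracebacks; each sample is a valid assignment drawn with probability
#' `exp(E(x, alpha)) / Z`.
#'
#' @inheritParams optimizeNetwork
#' @param n number of samples (0 allowed)
#' @param seed optional RNG seed (set before drawing)
#' @param tdSeed,restarts passed to [minFillDecompose()]
#' @return integer matrix, one sample per row
#' @export
sampleNetwork <- function(net, weights = NULL, n, seed = NULL, td = NULL,
                          tdSeed = 1L, restarts = 20L) {
  ct <- .pipeline(net, td, tdSeed, restarts)
  fw <- forwardPass(ct, weights, "sum")
  if (fw@rootValue <= 0)
    .tfStop("infeasible: no valid assignment", "treefeat_infeasible")
  if (!is.null(seed)) set.seed(seed)
  .traceSamples(fw, as.integer(n))
}

#' Feature target for multidimensional Boltzmann sampling
#'
#' @param feature feature name
#' @param tau target value
#' @param delta non-negative tolerance; admissibility is the non-strict
#'   inequality `|F(x) - tau| <= delta`
#' @export
featureTarget <- function(feature, tau, delta) {
  stopifnot(delta >= 0)
  list(feature = feature, tau = as.numeric(tau), delta = as.numeric(delta))
}

.checkTargets <- function(net, targets) {
  if (!is.null(targets$feature)) targets <- list(targets)
  for (tg in targets)
    if (!tg$feature %in% names(net@features))
      .tfStop(paste("unknown feature in targets:", tg$feature),
              "treefeat_unknown_feature")
  targets
}

# Feature value used for targeting: the proxy if declared, else the induced
# function sum.
.targetValue <- function(net, feature, x) {
  fe <- net@features[[feature]]
  if (!is.null(fe@proxy)) fe@proxy(x) else featureValue(net, feature, x)
}

#' Is an assignment admissible for a set of feature targets?
#'
#' `TRUE` iff `|F(x) - tau_F| <= delta_F` for every targeted feature
#' (boundary inclusive); an empty target set is vacuously admissible.
#' Features with a declared proxy are evaluated through it.
#'
#' @param net a [FeatureNetwork-class]
#' @param x valid total assignment
#' @param targets list of [featureTarget()] entries
#' @export
isAdmissible <- function(net, x, targets) {
  targets <- .checkTargets(net, targets)
  for (tg in targets) {
    v <- .targetValue(net, tg$feature, x)
    if (!(abs(v - tg$tau) <= tg$delta)) return(FALSE)
  }
  TRUE
}

#' Root mean square deviation of estimated feature means from their targets
#'
#' @param means named numeric of estimated means
#' @param targets list of [featureTarget()] entries (must be non-empty)
#' @export
rmsdToTargets <- function(means, targets) {
  if (!is.null(targets$feature)) targets <- list(targets)
  if (length(targets) == 0L) .tfStop("empty target set", "treefeat_domain_error")
  dev <- vapply(targets, function(tg) means[[tg$feature]] - tg$tau, 0)
  sqrt(mean(dev^2))
}

#' MDBS configuration
#'
#' The weight-update rule, the defaults for `k`, `gamma` and `cooling`, and
#' the retention of early admissible samples are tunable choices of this
#' implementation (see the methods vignette), not canonical constants.
#'
#' @param k samples drawn per round
#' @param gamma tweak factor: weight-update step size
#' @param cooling factor in (0, 1] applied to `gamma` whenever a round fails
#'   to improve the best RMSD seen so far
#' @param K required number of admissible samples
#' @param maxRounds give up (with an error) after this many rounds
#' @param init initial weights (scalar or named vector; default 0)
#' @param normalize divide each update by the per-feature sample standard
#'   deviation (floored at 1e-6), making `gamma` dimensionless across
#'   heterogeneous features; set `FALSE` for the unnormalized rule
#' @export
mdbsConfig <- function(k = 100L, gamma = 0.5, cooling = 0.8, K = 100L,
                       maxRounds = 1000L, init = 0, normalize = TRUE) {
  stopifnot(k >= 1L, K >= 1L, gamma > 0, cooling > 0, cooling <= 1)
  list(k = as.integer(k), gamma = gamma, cooling = cooling, K = as.integer(K),
       maxRounds = as.integer(maxRounds), init = init, normalize = normalize)
}

#' Targeted sampling by multidimensional Boltzmann sampling
#'
#' Iteratively draws `k` Boltzmann samples per round, keeps the
#' `(tau, delta)`-admissible ones (accumulated across rounds), estimates the
#' targeted feature means and tweaks the weights to move them toward the
#' targets: `alpha_F <- alpha_F + gamma * (tau_F - mu_F) / s_F` with `s_F`
#' the per-round sample standard deviation of `F` (or 1 if
#' `normalize = FALSE`).  An annealing scheme multiplies `gamma` by the
#' cooling factor whenever a round does not improve the best RMSD so far.
#' Features with a proxy evaluator are targeted by proxy: the proxy supplies
#' the mean estimates and admissibility, while the update is applied to the
#' weight of the feature (whose network functions shape the distribution).
#'
#' @param net a [FeatureNetwork-class]
#' @param targets list of [featureTarget()] entries
#' @param config an [mdbsConfig()]
#' @param seed optional RNG seed
#' @param td,tdSeed,restarts decomposition options as in [sampleNetwork()]
#' @return list with `samples` (integer matrix of the first `K` admissible
#'   assignments, in generation order) and `trace` (per-round data.frame:
#'   weights, estimated means, RMSD, best RMSD, admissible counts, gamma)
#' @export
targetedSample <- function(net, targets, config = mdbsConfig(), seed = NULL,
                           td = NULL, tdSeed = 1L, restarts = 20L) {
  targets <- .checkTargets(net, targets)
  ct <- .pipeline(net, td, tdSeed, restarts)
  tabs <- precomputeTables(ct)
  if (!is.null(seed)) set.seed(seed)
  feats <- vapply(targets, function(tg) tg$feature, "")
  alpha <- .fullWeights(net, NULL, default = 0)
  if (!is.null(names(config$init))) alpha[names(config$init)] <- config$init
  else alpha[] <- config$init
  gamma <- config$gamma
  bestRmsd <- Inf
  pool <- NULL
  traceRows <- list()
  for (round in seq_len(config$maxRounds)) {
    fw <- forwardPass(ct, alpha, "sum", tables = tabs)
    S <- .traceSamples(fw, config$k)
    vals <- vapply(feats, function(f)
      apply(S, 1L, function(x) .targetValue(net, f, x)), numeric(config$k))
    if (config$k == 1L) vals <- matrix(vals, nrow = 1L)
    adm <- rep(TRUE, config$k)
    for (j in seq_along(targets))
      adm <- adm & (abs(vals[, j] - targets[[j]]$tau) <= targets[[j]]$delta)
    if (any(adm)) pool <- rbind(pool, S[adm, , drop = FALSE])
    mu <- colMeans(vals)
    s <- apply(vals, 2L, sd)
    rmsd <- rmsdToTargets(setNames(mu, feats), targets)
    improved <- rmsd < bestRmsd
    if (improved) bestRmsd <- rmsd
    traceRows[[round]] <- data.frame(
      round = round, rmsd = rmsd, bestRmsd = bestRmsd, gamma = gamma,
      admissible = sum(adm),
      totalAdmissible = if (is.null(pool)) 0L else nrow(pool),
      t(setNames(mu, paste0("mean.", feats))),
      t(setNames(alpha[feats], paste0("weight.", feats))))
    if (!is.null(pool) && nrow(pool) >= config$K) {
      return(list(samples = pool[seq_len(config$K), , drop = FALSE],
                  trace = do.call(rbind, traceRows)))
    }
    scale <- if (config$normalize) pmax(s, 1e-6) else rep(1, length(feats))
    for (j in seq_along(targets)) {
      f <- feats[j]
      alpha[[f]] <- alpha[[f]] + gamma * (targets[[j]]$tau - mu[j]) / scale[j]
    }
    if (!improved) gamma <- gamma * config$cooling
  }
  cond <- errorCondition(
    sprintf("MDBS: %d admissible samples after %d rounds (K = %d required)",
            if (is.null(pool)) 0L else nrow(pool), config$maxRounds, config$K),
    class = c("treefeat_mdbs_failure", "treefeat_error"),
    trace = do.call(rbind, traceRows))
  stop(cond)
}
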