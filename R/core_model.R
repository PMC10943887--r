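# Core feature-network construction and direct evaluation.

.tfStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "treefeat_error")))
}

.checkDomain <- function(domain) {
  if (length(domain) == 0L) .tfStop("empty domain", "treefeat_domain_error")
  d <- as.integer(domain)
  if (anyDuplicated(d)) .tfStop("duplicated domain value", "treefeat_domain_error")
  sort(d)
}

#' Create an empty feature network
#'
#' @return a [FeatureNetwork-class] with no variables, constraints or features
#' @examples
#' net <- featureNetwork()
#' net <- addVariables(net, 9, 1:4)
#' @export
featureNetwork <- function() new("FeatureNetwork")

#' Number of variables of a network
#' @param net a [FeatureNetwork-class]
#' @export
nVariables <- function(net) length(net@domains)

#' Variable domains of a network
#' @param net a [FeatureNetwork-class]
#' @return list of sorted integer vectors
#' @export
variableDomains <- function(net) net@domains

#' Append variables with a common domain
#'
#' Variables are indexed consecutively from 1; the indices of the new
#' variables are `nVariables(net) + 1, ...` in order.
#'
#' @param net a [FeatureNetwork-class]
#' @param count number of variables to add (>= 1)
#' @param domain finite set of integers (singletons allowed, e.g. sentinels)
#' @return the extended network; retrieve the fresh indices with
#'   [lastVariables()]
#' @export
addVariables <- function(net, count, domain) {
  count <- as.integer(count)
  if (length(count) != 1L || is.na(count) || count < 1L)
    .tfStop("count must be a positive integer", "treefeat_domain_error")
  d <- .checkDomain(domain)
  net@domains <- c(net@domains, rep(list(d), count))
  net
}

#' Indices of the most recently added variables
#' @param net a [FeatureNetwork-class]
#' @param count how many trailing variables
#' @export
lastVariables <- function(net, count) {
  n <- nVariables(net)
  seq.int(n - count + 1L, n)
}

.typeRegistry <- new.env(parent = emptyenv())

#' Define a reusable constraint type
#'
#' Returns a factory `function(scope, ...)` producing [Constraint-class]
#' instances; `...` are construction parameters captured by the value rule.
#' Identical construction parameters yield behaviorally identical constraints
#' (the value rule must be referentially transparent).  Types defined this
#' way are registered so their instances serialize to/from JSON.
#'
#' @param name type name
#' @param value `function(values, ...)` returning a logical; `values` is the
#'   vector of scope values in scope order
#' @return the factory function
#' @examples
#' NotEquals <- defineConstraintType("NotEquals",
#'   function(v) v[1] != v[2])
#' ne <- NotEquals(c(2L, 5L))
#' @export
defineConstraintType <- function(name, value) {
  force(value)
  factory <- function(scope, ...) {
    params <- list(...)
    new("Constraint", name = paste0(name, "_[", paste(scope, collapse = ","), "]"),
        scope = as.integer(scope),
        fn = function(vals) do.call(value, c(list(vals), params)),
        type = name, params = params)
  }
  assign(name, list(kind = "constraint", factory = factory), envir = .typeRegistry)
  factory
}

#' Define a reusable network-function type
#'
#' As [defineConstraintType()], but the value rule returns an extended real
#' (`+Inf`/`-Inf` permitted, e.g. to exclude alternatives under weighting).
#'
#' @inheritParams defineConstraintType
#' @examples
#' Card <- defineFunctionType("Card", function(v) length(unique(v)))
#' Card(c(2L, 3L, 5L, 6L))
#' @export
defineFunctionType <- function(name, value) {
  force(value)
  factory <- function(scope, ...) {
    params <- list(...)
    new("NetworkFunction",
        name = paste0(name, "_[", paste(scope, collapse = ","), "]"),
        scope = as.integer(scope),
        fn = function(vals) do.call(value, c(list(vals), params)),
        type = name, params = params)
  }
  assign(name, list(kind = "function", factory = factory), envir = .typeRegistry)
  factory
}

.checkScope <- function(net, scope) {
  if (any(scope > nVariables(net)))
    .tfStop("scope references unknown variable", "treefeat_scope_error")
}

.flatten <- function(dots) {
  out <- list()
  for (it in dots) {
    if (is.list(it)) out <- c(out, it) else out <- c(out, list(it))
  }
  out
}

#' Add constraints to a network
#' @param net a [FeatureNetwork-class]
#' @param ... [Constraint-class] objects or lists thereof
#' @return the extended network
#' @export
addConstraint <- function(net, ...) {
  items <- .flatten(list(...))
  for (co in items) {
    stopifnot(is(co, "Constraint"))
    .checkScope(net, co@scope)
    net@constraints <- c(net@constraints, co)
  }
  net
}

#' Add network functions to a named feature
#'
#' The feature is created on first use.  The feature value of a total
#' assignment is the sum of all its member function evaluations.
#'
#' @param net a [FeatureNetwork-class]
#' @param feature feature name
#' @param ... [NetworkFunction-class] objects or lists thereof
#' @return the extended network
#' @export
addFunctions <- function(net, feature, ...) {
  items <- .flatten(list(...))
  fe <- net@features[[feature]]
  if (is.null(fe)) fe <- new("Feature", name = feature)
  for (f in items) {
    stopifnot(is(f, "NetworkFunction"), !is(f, "Constraint"))
    .checkScope(net, f@scope)
    fe@functions <- c(fe@functions, f)
  }
  net@features[[feature]] <- fe
  net
}

#' Attach a proxy evaluator to a feature
#'
#' The proxy (`function(assignment)` on total assignments) replaces the
#' induced function sum when estimating feature means and admissibility in
#' [targetedSample()]; the sampling distribution itself is always governed by
#' the feature's network functions.
#'
#' @param net a [FeatureNetwork-class]
#' @param feature feature name (created if absent)
#' @param proxy `function(assignment)` returning a real
#' @export
setFeatureProxy <- function(net, feature, proxy) {
  fe <- net@features[[feature]]
  if (is.null(fe)) fe <- new("Feature", name = feature)
  fe@proxy <- proxy
  net@features[[feature]] <- fe
  net
}

#' Names of the features of a network
#' @param net a [FeatureNetwork-class]
#' @export
featureNames <- function(net) names(net@features)

.checkAssignment <- function(net, x) {
  n <- nVariables(net)
  if (length(x) != n)
    .tfStop("assignment must have one slot per variable (NA = unbound)",
            "treefeat_domain_error")
  x <- as.integer(x)
  for (i in seq_len(n)) {
    if (!is.na(x[i]) && !(x[i] %in% net@domains[[i]]))
      .tfStop(sprintf("value %d outside domain of variable %d", x[i], i),
              "treefeat_domain_error")
  }
  x
}

#' Is a (partial) assignment valid?
#'
#' An assignment (integer vector, `NA` for unbound variables) is valid iff
#' every constraint whose scope is fully bound evaluates to `TRUE`;
#' constraints with unbound scope variables are skipped, so the empty
#' assignment is always valid.
#'
#' @param net a [FeatureNetwork-class]
#' @param x integer vector of length `nVariables(net)`, `NA` = unbound
#' @export
isValid <- function(net, x) {
  x <- .checkAssignment(net, x)
  for (co in net@constraints) {
    v <- x[co@scope]
    if (!anyNA(v) && !isTRUE(co@fn(v))) return(FALSE)
  }
  TRUE
}

#' Evaluate one feature at a total assignment
#'
#' Returns the sum of the feature's network-function evaluations,
#' `F(x) = sum_f f(x)` (0 for a feature with no functions).  The proxy, if
#' any, is deliberately not consulted here; see [setFeatureProxy()].
#'
#' @param net a [FeatureNetwork-class]
#' @param feature feature name
#' @param x total assignment
#' @export
featureValue <- function(net, feature, x) {
  fe <- net@features[[feature]]
  if (is.null(fe)) .tfStop(paste("unknown feature:", feature),
                           "treefeat_unknown_feature")
  x <- .checkAssignment(net, x)
  if (anyNA(x)) .tfStop("featureValue requires a total assignment",
                        "treefeat_partial_assignment")
  s <- 0
  for (f in fe@functions) s <- s + f@fn(x[f@scope])
  s
}

.fullWeights <- function(net, weights = NULL, default = 1) {
  w <- setNames(rep(default, length(net@features)), names(net@features))
  if (!is.null(weights)) {
    unknown <- setdiff(names(weights), names(w))
    if (length(unknown))
      .tfStop(paste("unknown feature in weights:", paste(unknown, collapse = ", ")),
              "treefeat_unknown_feature")
    w[names(weights)] <- weights
  }
  w
}

#' Weighted evaluation of a valid total assignment
#'
#' Computes `E(x, alpha) = sum_F alpha_F * F(x)`.  Unnamed features default
#' to weight 1; a weight of exactly 0 annihilates the feature even when its
#' value is infinite.  Evaluating an invalid assignment is an error (the
#' optimization and sampling problems quantify over valid assignments only),
#' reported distinctly from domain errors.
#'
#' @param net a [FeatureNetwork-class]
#' @param x total assignment
#' @param weights named numeric of per-feature weights (default all 1)
#' @export
evaluateAssignment <- function(net, x, weights = NULL) {
  x <- .checkAssignment(net, x)
  if (anyNA(x)) .tfStop("evaluation requires a total assignment",
                        "treefeat_partial_assignment")
  if (!isValid(net, x))
    .tfStop("assignment violates a constraint", "treefeat_invalid_assignment")
  w <- .fullWeights(net, weights)
  e <- 0
  for (nm in names(net@features)) {
    if (w[[nm]] == 0) next
    e <- e + w[[nm]] * featureValue(net, nm, x)
  }
  e
}

#' Construct a dependency hypergraph directly
#' @param nVariables number of vertices
#' @param hyperedges list of integer vectors (scopes); duplicates collapsed
#' @export
hypergraph <- function(nVariables, hyperedges = list()) {
  edges <- lapply(hyperedges, function(e) sort(unique(as.integer(e))))
  edges <- unique(edges)
  new("DependencyHypergraph", nVariables = as.integer(nVariables),
      hyperedges = edges)
}

#' Dependency hypergraph of a network
#'
#' Vertices are all variables (including isolated ones); hyperedges are
#' exactly the scopes of the declared constraints and network functions,
#' with duplicates collapsed.
#'
#' @param net a [FeatureNetwork-class]
#' @return a [DependencyHypergraph-class]
#' @export
dependencyGraph <- function(net) {
  scopes <- c(lapply(net@constraints, function(co) co@scope),
              unlist(lapply(net@features,
                            function(fe) lapply(fe@functions, function(f) f@scope)),
                     recursive = FALSE))
  hypergraph(nVariables(net), scopes)
}

setMethod("show", "FeatureNetwork", function(object) {
  nf <- sum(vapply(object@features, function(fe) length(fe@functions), 0L))
  cat(sprintf("FeatureNetwork: %d variables, %d constraints, %d features (%d functions)\n",
              nVariables(object), length(object@constraints),
              length(object@features), nf))
  if (length(object@features))
    cat("  features:", paste(names(object@features), collapse = ", "), "\n")
})

setMethod("show", "DependencyHypergraph", function(object) {
  cat(sprintf("DependencyHypergraph: %d variables, %d hyperedges\n",
              object@nVariables, length(object@hyperedges)))
})
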