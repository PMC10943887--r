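#' @import methods
#' @importFrom stats runif sd setNames rbinom
#' @importFrom utils head tail
NULL

setClassUnion("functionOrNULL", members = c("function", "NULL"))

#' NetworkFunction: a local real-valued function over a small variable scope
#'
#' A network function maps the values of the variables in its `scope`
#' (given in scope order) to an extended real number.  Functions are grouped
#' into named features; the feature value of a total assignment is the sum of
#' its member functions.  Instances are usually created through factories
#' returned by [defineFunctionType()].
#'
#' @slot name human-readable instance label
#' @slot scope integer vector of variable indices (1-based, distinct)
#' @slot fn evaluator: `function(values)` with `values` ordered as `scope`
#' @slot type type name used for serialization (empty for ad hoc closures)
#' @slot params construction parameters, for serialization
#' @export
setClass("NetworkFunction",
  representation(name = "character", scope = "integer", fn = "function",
                 type = "character", params = "list"),
  prototype(type = NA_character_, params = list()))

#' Constraint: a Boolean network function
#'
#' Same layout as [NetworkFunction-class] but the evaluator returns a single
#' logical.  An assignment is valid iff all constraints whose scope is fully
#' bound evaluate to `TRUE`.
#' @export
setClass("Constraint", contains = "NetworkFunction")

setValidity("NetworkFunction", function(object) {
  if (length(object@scope) < 1L) return("scope must have arity >= 1")
  if (anyDuplicated(object@scope)) return("scope variables must be distinct")
  if (any(object@scope < 1L)) return("scope indices must be >= 1")
  TRUE
})

#' Feature: a named set of network functions, optionally with a proxy
#'
#' @slot name feature name
#' @slot functions list of [NetworkFunction-class] objects
#' @slot proxy optional `function(assignment)` returning a real; when present
#'   it is used for mean estimation and admissibility in targeted sampling
#'   ("targeting by proxy"), never for the sampling distribution itself.
#' @export
setClass("Feature",
  representation(name = "character", functions = "list", proxy = "functionOrNULL"),
  prototype(functions = list(), proxy = NULL))

#' FeatureNetwork: variables, finite integer domains, constraints, features
#'
#' The central modeling object: a constraint network extended by named
#' features (sets of real-valued local functions combined linearly through
#' per-feature weights).  Networks are built compositionally with
#' [addVariables()], [addConstraint()] and [addFunctions()]; constraint and
#' function instances are immutable once inserted.
#'
#' @slot domains list of sorted integer vectors, one per variable
#' @slot constraints list of [Constraint-class] objects
#' @slot features named list of [Feature-class] objects
#' @seealso [featureNetwork()], [evaluateAssignment()], [dependencyGraph()]
#' @export
setClass("FeatureNetwork",
  representation(domains = "list", constraints = "list", features = "list"),
  prototype(domains = list(), constraints = list(), features = list()))

setValidity("FeatureNetwork", function(object) {
  n <- length(object@domains)
  for (d in object@domains) {
    if (length(d) == 0L) return("empty domain")
    if (anyDuplicated(d)) return("duplicated domain value")
    if (is.unsorted(d)) return("domains must be sorted ascending")
  }
  for (co in object@constraints)
    if (any(co@scope > n)) return("constraint scope references unknown variable")
  for (fe in object@features)
    for (f in fe@functions)
      if (any(f@scope > n)) return("function scope references unknown variable")
  if (length(object@features) &&
      !identical(names(object@features),
                 vapply(object@features, function(f) f@name, "")))
    return("feature list names must match feature names")
  TRUE
})

#' DependencyHypergraph: variables and the scopes of all constraints/functions
#'
#' @slot nVariables number of vertices (variables)
#' @slot hyperedges list of integer vectors (deduplicated scopes)
#' @export
setClass("DependencyHypergraph",
  representation(nVariables = "integer", hyperedges = "list"))

setValidity("DependencyHypergraph", function(object) {
  for (e in object@hyperedges) {
    if (length(e) == 0L) return("empty hyperedge")
    if (any(e < 1L) || any(e > object@nVariables)) return("hyperedge out of range")
  }
  TRUE
})

#' TreeDecomposition: a rooted tree of variable bags
#'
#' Nodes are `1..length(bags)`; `parent[u]` gives the parent of `u`
#' (`NA` at the root).  The three defining conditions (variable coverage,
#' hyperedge coverage, connectivity of each variable's node set) are checked
#' by [validateTd()] against a hypergraph; [makeGentle()] normalizes to an
#' empty root bag with exactly one introduced variable per non-root node.
#'
#' @slot bags list of integer variable sets
#' @slot parent integer vector, `NA` for the root
#' @slot root root node id
#' @slot nVariables number of variables of the underlying hypergraph
#' @export
setClass("TreeDecomposition",
  representation(bags = "list", parent = "integer", root = "integer",
                 nVariables = "integer"))

setValidity("TreeDecomposition", function(object) {
  k <- length(object@bags)
  if (length(object@parent) != k) return("parent vector length mismatch")
  if (sum(is.na(object@parent)) != 1L) return("exactly one root required")
  if (is.na(object@parent[object@root])) TRUE else "root slot disagrees with parent vector"
})

#' Algebra: the semiring-like evaluation triple of the engine
#'
#' `choose` combines alternatives (max or sum), `combine` combines parts of a
#' solution (plus or times), and `lift` maps weighted function values into the
#' evaluation domain (identity or exp).  `excluded` represents an impossible
#' alternative (`-Inf` for optimization, `0` for partition functions) and
#' satisfies `lift(-Inf) == excluded` under the sampling algebra.
#'
#' @slot choose,combine binary operations
#' @slot lift unary map applied to weighted function values
#' @slot neutralChoose,neutralCombine identities of the two operations
#' @slot excluded value of an impossible alternative
#' @slot tag `"max"` or `"sum"`, used by the vectorized engine kernels
#' @seealso [maxAlgebra()], [sumAlgebra()]
#' @export
setClass("Algebra",
  representation(choose = "function", combine = "function", lift = "function",
                 neutralChoose = "numeric", neutralCombine = "numeric",
                 excluded = "numeric", tag = "character"))

#' ClusterTree: a gentle tree decomposition with constraint/function placement
#'
#' Every constraint and function of the network is placed at exactly one node
#' whose bag contains its scope; placement is at the lowest (deepest) such
#' bag.  Built by [buildClusterTree()].
#'
#' @slot network the [FeatureNetwork-class]
#' @slot td a gentle [TreeDecomposition-class]
#' @slot constraintNode node id per constraint (parallel to network constraints)
#' @slot functionTable data.frame with columns `feature`, `index`, `node`
#' @export
setClass("ClusterTree",
  representation(network = "FeatureNetwork", td = "TreeDecomposition",
                 constraintNode = "integer", functionTable = "data.frame"))

#' ForwardResult: messages and root value of a forward pass
#'
#' Holds, for every non-root node `u`, the message table `m[u -> parent]`
#' (one entry per assignment of `sep(u)`) and the materialized per-bag value
#' table used by the tracebacks.  `rootValue` is the combine-combination of
#' the 0-ary messages sent to the root: the optimal evaluation `E_max`
#' (max algebra) or the partition function `Z` (sum algebra).
#'
#' @slot rootValue numeric scalar
#' @slot messages list (per node) of numeric message tables
#' @slot tables list (per node) of per-bag value tables over bag assignments
#' @slot layout list (per node) of index layouts (bag variable order, radices)
#' @slot algebraTag `"max"` or `"sum"`
#' @slot weights full named weight vector used
#' @slot clusterTree the [ClusterTree-class] the pass was run on
#' @slot preorder node visiting order for tracebacks
#' @export
setClass("ForwardResult",
  representation(rootValue = "numeric", messages = "list", tables = "list",
                 layout = "list", algebraTag = "character", weights = "numeric",
                 clusterTree = "ClusterTree", preorder = "integer"))

#' SecondaryStructure: a set of base pairs on sequence positions 1..n
#'
#' Pairs are stored as a two-column integer matrix with `i < j`; every
#' position is involved in at most one pair (base-triplet-free).  Crossing
#' (pseudoknotted) pairs are allowed and flagged.
#'
#' @slot length sequence length n
#' @slot pairs two-column integer matrix of (i, j) pairs, i < j
#' @seealso [parseDotBracket()]
#' @export
setClass("SecondaryStructure",
  representation(length = "integer", pairs = "matrix"))

setValidity("SecondaryStructure", function(object) {
  p <- object@pairs
  if (ncol(p) != 2L) return("pairs must be a 2-column matrix")
  if (nrow(p)) {
    if (any(p < 1L) || any(p > object@length)) return("pair position out of range")
    if (any(p[, 1L] >= p[, 2L])) return("pairs must satisfy i < j")
    if (anyDuplicated(as.vector(p))) return("base triplet: position paired twice")
  }
  TRUE
})

#' DFA: deterministic finite automaton over a finite alphabet
#'
#' States are `1..nStates` with initial state 1; `transition[q, a]` is the
#' successor of state `q` on the `a`-th alphabet symbol (total).
#'
#' @slot nStates number of states
#' @slot alphabet character vector of symbols
#' @slot transition integer matrix `nStates x length(alphabet)`
#' @slot initial initial state id
#' @slot accepting integer vector of accepting state ids
#' @seealso [ahoCorasickDfa()], [dfaAccepts()], [dfaModel()]
#' @export
setClass("DFA",
  representation(nStates = "integer", alphabet = "character",
                 transition = "matrix", initial = "integer",
                 accepting = "integer"))

setValidity("DFA", function(object) {
  tr <- object@transition
  if (nrow(tr) != object@nStates || ncol(tr) != length(object@alphabet))
    return("transition matrix dimensions disagree with states/alphabet")
  if (any(tr < 1L) || any(tr > object@nStates))
    return("transition target out of range")
  TRUE
})

#' PhyloNetwork: rooted phylogenetic network (edges child -> parent)
#'
#' A rooted, connected DAG; the unique root has no parents, leaves have no
#' children, and reticulation nodes have more than one parent.
#'
#' @slot nNodes number of nodes (ids 1..nNodes)
#' @slot edges two-column integer matrix, column 1 child, column 2 parent
#' @seealso [phyloNetwork()], [hardwiredModel()], [softwiredModel()]
#' @export
setClass("PhyloNetwork",
  representation(nNodes = "integer", edges = "matrix"))
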