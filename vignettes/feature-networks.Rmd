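---
title: "Feature networks and cluster-tree elimination: models, algorithms, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feature networks and cluster-tree elimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treefeat)
```

# The model

A **feature network** is a constraint network extended by evaluation: a set
of variables $X_1,\dots,X_n$ with finite integer domains $D_i$, a set of
hard constraints $\mathcal C$ (Boolean functions on small variable subsets),
and a collection of named **features** $\mathcal F$, each a set of
real-valued local functions.  A total assignment $x$ is *valid* iff every
constraint is satisfied; a feature evaluates to the sum of its member
functions, $F(x)=\sum_{f\in F} f(x)$, and the overall evaluation is the
weighted combination

$$E(x,\alpha) = \sum_{F\in\mathcal F} \alpha_F\, F(x).$$

Two problems are solved on this model:

* **Optimization** — a valid assignment maximizing $E(x,\alpha)$ (minimize
  by negating weights);
* **Boltzmann sampling** — valid assignments drawn with probability
  $P(x)=\exp(E(x,\alpha))/Z$, where
  $Z=\sum_{x\ \mathrm{valid}}\exp(E(x,\alpha))$ is the partition function.

Distinguishing several named features (rather than one merged score) is
what makes *multidimensional* control possible: each feature has its own
weight, and targeted sampling (below) learns all weights jointly.

Variables are indexed 1-based throughout, the natural convention in R.
Domains are arbitrary finite integer sets, not just ranges; singleton
domains serve as sentinels and as domain-encoded constraints (e.g. fixed
leaf labels), which keeps several application models constraint-free.

# Solving: the same recursion under two algebras

Both problems factor over a **tree decomposition** of the **dependency
graph** — the hypergraph whose hyperedges are the scopes of all constraints
and functions.  A decomposition is a rooted tree of variable subsets
("bags") covering all variables and all scopes, such that the bags
containing any one variable form a connected subtree; its width is the
largest bag size minus one.  The engine requires (and
`makeGentle()` produces) a **gentle** decomposition: empty root bag and
exactly one variable introduced per non-root node, which gives exactly one
tree edge per variable and a one-variable decision per traceback step.

A **cluster tree** (`buildClusterTree()`) places every constraint and
function at the deepest bag containing its scope.  The forward pass
computes, bottom-up and per node $u$, a **message** table indexed by the
assignments of the separator $\mathrm{sep}(u)$ (the bag's intersection with
its parent).  Writing $\oplus$ for combination across alternatives,
$\otimes$ for combination across parts and $\ell$ for the lift of weighted
function values, the message is

$$m_{u\to v}(\bar x) \;=\; \bigoplus_{\bar x' \,:\, \bar x\cup\bar x'\
\mathrm{valid}} \Big[ \bigotimes_{f \in \phi(u)} \ell(\alpha_f f(\bar
x\cup\bar x')) \;\otimes \bigotimes_{c\ \mathrm{child}} m_{c\to u}(\bar
x\cup\bar x') \Big],$$

with $(\oplus,\otimes,\ell) = (\max,+,\mathrm{Id})$ for optimization and
$(+,\times,\exp)$ for partition functions.  Invalid extensions contribute
the algebra's *excluded* value ($-\infty$, respectively $0=e^{-\infty}$).
The root value is the $\otimes$-combination of the 0-ary messages sent to
the (empty) root — root subtrees are variable-disjoint, so their optima add
and their partition functions multiply.  An infeasible network cleanly
yields the excluded value.

Tracebacks run top-down in preorder.  The optimal traceback re-derives, at
each node, a value of the introduced variable whose bag evaluation
reproduces the stored message; the stochastic traceback draws a tracking
value uniformly below the message entry and decrements it by the partial
Boltzmann factors until it turns negative, which selects each value with
exactly its conditional Boltzmann probability, giving exact (not
approximate) samples from $P(x)$.

Time is $O(d^{w+1}(\mathfrak m+\mathfrak n))$ and space $O(d^w \mathfrak n)$
for domain size $d$, width $w$, $\mathfrak n$ variables and $\mathfrak m$
constraints/functions; the test suite asserts the space side as a
table-size invariant (no message table exceeds $d^{|\mathrm{sep}|}$
entries).

## Numerical and implementation choices

* **Dense mixed-radix tables.** Messages and per-bag value tables are dense
  numeric vectors indexed by a mixed-radix encoding of bag assignments with
  the introduced variable as the fastest-varying digit, so the entries for
  one separator assignment are contiguous; both tracebacks and the batched
  sampler exploit this.  This matches the $d^{|\mathrm{sep}|}$ space bound.
* **Precomputation.** Constraints and functions are tabulated over their
  scope grids ($d^k$ entries each, $O(d^k\mathfrak m)$ total) before the
  pass; referential transparency of value rules is therefore required.  A
  per-item cap falls back to on-the-fly evaluation, and a paired test
  asserts bit-identical results for both paths.
* **Infinities.** Function values may be $\pm\infty$; after weighting,
  $-\infty$ is excluded under maximization and becomes Boltzmann factor 0
  under sampling.  A weight of exactly 0 annihilates its feature even when
  the feature value is infinite (no `0 * Inf` artifacts).  Evaluating an
  *invalid* assignment raises an error instead of returning $-\infty$: both
  problems quantify over valid assignments only, and silent $-\infty$
  would mask modeling bugs.
* **Floating point.** Partition functions run in ordinary double precision
  (stochastic traceback needs additive partial sums, ruling out log-space
  messages); overflow to `Inf`/`NaN` raises a dedicated error suggesting
  weight rescaling.  Optimal traceback ties break toward the first value in
  ascending domain order, making optimizer output deterministic.
* **Seeding.** All sampling flows through R's RNG; solver facades accept an
  explicit seed, and every synthetic-instance generator seeds a local RNG
  and restores the caller's state.

# Tree decompositions

`minFillDecompose()` implements the randomized min-fill heuristic on the
primal graph (each hyperedge cliquified, the standard treatment under which
hyperedge coverage reduces to clique coverage): repeatedly eliminate a
vertex adding the fewest fill edges, breaking ties uniformly at random; the
bag of a vertex is its neighborhood at elimination, and bags are wired into
an elimination tree.  Defaults: 20 restarts, best width kept, deterministic
under the given seed.  `makeGentle()` then inserts an empty root, splits
multi-variable introductions into chains (ascending variable order, for
deterministic output) and contracts edges introducing nothing — width is
preserved exactly.

`exactTreewidth()` is an independent oracle for tests only: dynamic
programming over subsets of eliminated vertices (the elimination degree of
a vertex depends only on the eliminated *set*), guarded to 14 vertices.  On
100 random partial $k$-trees the heuristic always validates and never beats
the oracle; width *equality* is tracked but deliberately not asserted —
min-fill is a heuristic and occasional suboptimal widths on sparse graphs
are expected, not a defect.

# Targeted sampling (multidimensional Boltzmann sampling)

`targetedSample()` generates assignments admissible for feature targets
$|F(x)-\tau_F|\le\delta_F$ (boundary inclusive) by rejection from the
Boltzmann distribution, while learning weights that move the sampling means
onto the targets — rejection is most efficient when means and targets
coincide.  Per round it draws $k$ samples, keeps the admissible ones
(admissible samples from *early* rounds count toward the requested $K$;
they are perfectly valid draws and discarding them would only waste work),
estimates means $\hat\mu_F$, and updates

$$\alpha_F \leftarrow \alpha_F + \gamma\,(\tau_F-\hat\mu_F)/s_F,$$

where $s_F$ is the per-round sample standard deviation of $F$ floored at
$10^{-6}$ (set `normalize = FALSE` for the unnormalized rule).  Raising
$\alpha_F$ raises $E[F]$, so the sign is always right; the variance
normalization makes the step size $\gamma$ dimensionless, which matters
when, say, a count on the scale of dozens is targeted jointly with energies
on the scale of kcal/mol.  If a round fails to improve the best RMSD
$\sqrt{\mathrm{mean}_F (\hat\mu_F-\tau_F)^2}$ seen so far, $\gamma$ is
multiplied by the cooling factor $\Gamma$ — a simple annealing scheme that
damps oscillation around the targets.  The defaults ($k=100$,
$\gamma=0.5$, $\Gamma=0.8$, 1000 rounds maximum) are tunable heuristics,
not canonical constants; the procedure as a whole is a heuristic with a
hard guarantee only on its *output* (every returned sample satisfies the
tolerance, by rejection).

**Targeting by proxy.** A feature may declare a proxy evaluator on total
assignments.  The proxy then supplies the mean estimates and the
admissibility test, while the weight update still acts on the feature
itself, whose network functions shape the sampling distribution.  The
motivating use is RNA design: sample efficiently under a simple pairwise
energy model while *targeting* a richer external energy (e.g. a
nearest-neighbor folding model plugged in as the proxy).  The package
ships no such energy model itself — the hook is the interface.

On a separable check model (20 binary variables, feature = number of
ones, target $15\pm1$) the learned weight converges to the closed-form
Bernoulli tilt $\log(p/(1-p)) = \log 3$ within $\pm 0.2$, and the final
round's sample mean lies in $[14,16]$; both are asserted under a fixed
seed.

# Application models

**Graph coloring** (the running example and test fixture): one variable per
vertex, `NotEquals` per edge, and a feature of three 4-ary cardinality
functions counting distinct colors on cycles $(2,3,5,6)$, $(2,5,7,8)$,
$(5,6,7,8)$ of a 9-vertex graph.  Only the cycle edges plus the pair
$(6,8)$ and two connector edges $(1,2)$, $(4,5)$ are structurally forced by
the worked evaluations; the fixture fixes exactly that edge set, ordered so
that both reference colorings (evaluating to 11 and 10 at weight 1) are
proper.

**RNA design** (`designModel()`): variables are sequence positions over
A/C/G/U; each base pair in the union of the target structures imposes a
canonical-pair constraint; features are the per-position GC indicators
(`gc`, so its weight steers expected GC count) and one base-pair energy sum
per target structure (`E1`, `E2`, ...).  Sampling therefore follows
$P(s)\propto \exp(\alpha_{gc}\,\#GC)\prod_\ell \exp(\alpha_\ell E(s,S_\ell))$.
The default base-pair energy table (GC/CG $-3$, AU/UA $-2$, GU/UG $-1$) is a
configurable placeholder encoding only the usual stability ordering — it is
*not* a calibrated thermodynamic parameter set, and all quantitative tests
pass explicit tables.  Strict mode rejects crossing target structures (the
multitarget problem is stated for noncrossing targets); `allowCrossing`
lifts this, since the engine itself is agnostic.

**Motif control** (`ahoCorasickDfa()`, `dfaModel()`): a motif list compiles
to a trie-plus-failure-links automaton with all motif-ending states merged
into one absorbing state; `forbid` mode complements the acceptance.  The
word model adds one state variable per position and a ternary transition
constraint $y_i=\delta(y_{i-1},x_i)$, with the first state fixed and the
last restricted to accepting states, so the partition function at zero
weights counts accepted words.  Built `into` an existing design model it
composes with all other constraints and features; the price is extra
consecutive-position dependencies (and thus possibly width), traded against
the naive alternative of one $k$-ary constraint per window.

**Alignment** (`linearAlignModel()`, `affineAlignModel()`,
`structureAlignModel()`): position $i$ of the first sequence gets a
variable whose value is the matched position of the second; repeating the
previous value encodes deletion, and value jumps encode insertions — with
explicit sentinels $X_0=0$, $X_{n+1}=m+1$ this represents every alignment
uniquely (the encode/decode bijection is property-tested).  The element
score $\sigma$ applies to *every* aligned pair, so mismatch scores live in
the $\sigma$ table (default 0, reconciling match-only scoring with the
worked example).  Affine gap cost $g(\ell)=\beta+\gamma\ell$ uses Boolean
match-state variables $Y_i$: a deletion with the previous position matched
opens a gap ($\beta+\gamma$), otherwise it extends one ($\gamma$), and
insertion runs are charged $\beta$ once inside the generalized insertion
function.  The alternative ternary X-only formulation would cost an extra
linear factor; the Boolean-variable model keeps that factor constant, which
is why it is the default.  Structure alignment adds one 4-ary arc-match
bonus per arc of the (possibly crossing) annotation, gated on *both*
endpoints being matched — gating on the $X$ values alone would award the
bonus to deleted endpoints.  Banding restricts the domain of $X_i$ to a
window around the diagonal anchor $\mathrm{round}(i\,m/n)$; anchoring to a
guide alignment instead would be possible but needs an external guide, so
the diagonal is the default.  A band too tight for any alignment surfaces
as an infeasible model at solve time, not at build time.

**Network parsimony** (`hardwiredModel()`, `softwiredModel()`): one
variable per network node, leaf domains fixed by the labeling (no
constraints at all), one 0/1 distance function per edge; minimization is
maximization at weight $-1$, and the reported score is the negated optimum.
The model's dependency graph *is* the input network, so the width that
drives solving cost is the network's own treewidth.  Softwired parsimony
(binary networks) adds a Boolean selector per reticulation; each
reticulation edge carries a selector-gated distance that contributes the
0/1 distance when its parent is selected and 0 otherwise.  The 0 on the
unselected branch is essential: an infinite penalty there would exclude
*every* labeling, because for either selector value exactly one of the two
parent-edge functions is unselected — the zero contribution is what
realizes the per-node min-over-parents score, as validated against
exhaustive enumeration over all selector fixings.  "Left" and "right"
parent follow first appearance in the edge list; this affects selector
semantics only, not scores.  Only the 0/1 distance is built in; the Sankoff
oracle accepts an arbitrary cost matrix and tree-restricted inputs.

# What the synthetic generators emulate — and what they do not

The generators exist so every test input is constructed in code:

* `randomPartialKtree()` certifies treewidth $\le k$ by construction — the
  regime the solver is designed for; it does not emulate any particular
  application's dependency topology.
* `randomStructures()` draws the pair count as
  $\mathrm{Binomial}(\lfloor n/2\rfloor, p)$ (density $\approx p$, default
  0.3 — a typical paired fraction for short RNAs), places paired positions
  uniformly and matches them noncrossing (or uniformly, for pseudoknots).
  Real secondary structures have helices (stacked adjacent pairs) and loop
  length constraints; these generators make no such attempt, so passing
  tests certify combinatorial correctness, not biological realism.
* `randomBinaryNetwork()` grows a random binary tree and inserts each
  reticulation by subdividing two tree edges, with an explicit acyclicity
  check; real phylogenetic networks have reticulation patterns shaped by
  hybridization and transfer events that this does not model.
* `randomFeatureNetwork()` draws small networks with random tabulated
  constraints/functions — deliberately structureless, to stress the engine
  against exhaustive enumeration including infeasible instances.

Consequently, green tests demonstrate exactness of the algorithms on their
combinatorial domain.  They do not validate any energy model, substitution
model, or score scheme against data.

# Problem sizes used by the test and acceptance suites

Engine oracle checks enumerate 200 random networks of at most 8 variables
with domains of at most 4 values; sampling laws use 50,000 draws on the
2160 valid colorings of the fixture at two weight settings (chi-square
goodness of fit with pooling of cells below expectation 5); alignment
oracles compare 100 random instances each (sequences up to length 8,
integer scores, exact equality); parsimony uses 50 random trees and 20
binary networks with up to 4 reticulations against exhaustive selector
enumeration; decomposition properties run on 100 random graphs of up to 10
vertices against the exact oracle.  These sizes keep every suite exhaustive
where an oracle exists while completing in well under a minute per suite on
one core.

# Known limitations

* No constraint propagation, arc consistency, or search: solving is pure
  cluster-tree elimination, so dense models (large treewidth) are
  intractable by design.
* Partition functions in plain doubles can overflow for strongly weighted
  large models; the error suggests rescaling, but no automatic log-domain
  fallback exists (it would break stochastic traceback's partial sums).
* Alignment solving carries an extra linear factor over bespoke DP
  implementations (no per-bag DP specialization); banding is the practical
  mitigation.
* The affine alignment model charges gap openings via Boolean state
  variables; local/semiglobal variants and the ternary X-only deletion
  formulation are not implemented.
* MDBS has no convergence guarantee; pathological targets (e.g. mass on a
  tolerance window the model cannot reach) end with a max-rounds error
  carrying the trace.
* JSON round-tripping covers instances built from registered types with
  JSON-representable parameters; ad hoc closures and proxy evaluators do
  not serialize.
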