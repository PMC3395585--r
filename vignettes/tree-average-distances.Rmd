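---
title: "Tree-average distances on phylogenetic networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tree-average distances on phylogenetic networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadnet)
```

## The model

A rooted phylogenetic network `N = (V, A, r, X)` is a rooted acyclic
digraph whose vertices are species and whose arcs point from parent to
child. The *base set* `X` collects the taxa on which measurements (for
instance DNA, and hence distances) are possible: every leaf, the root
(in practice an extant outgroup used to place the root), and every
vertex of indegree 1 and outdegree 1, plus possibly further internal
vertices for which historical data happen to exist. A vertex of
indegree at least two is a *hybrid* (reticulation) vertex; one of
indegree one is a *normal* (tree) vertex.

Each arc `(a, b)` carries a nonnegative weight `w(a, b)`, the expected
genetic change along the arc, with one structural convention: arcs into
hybrid vertices weigh zero. A hybridization event is treated as
instantaneous — the hybrid inherits each character unchanged from one
of its parents — and all subsequent mutation is charged to the arc out
of the hybrid.

A *parent map* `p` picks one parent for every non-root vertex; keeping
only the chosen arcs yields a *displayed tree* `N_p` on the full vertex
set. With inheritance probabilities `alpha(u, h)` (the fraction of the
genome hybrid `h` inherits from parent `u`, summing to one over the
parents of `h`, independent across hybrids), each parent map has
probability `Pr(p) = prod_h alpha(p(h), h)`, and the **tree-average
distance** between two vertices is the expectation of the ordinary path
distance over displayed trees:

```
d(u, v; N) = sum_p Pr(p) d(u, v; N_p).
```

When every parent of a hybrid is equally likely the network is
*equiprobable* at that hybrid; biologically, true hybridization between
sexual species suggests roughly 50/50 inheritance, while backcrossing or
horizontal transfer makes other values likely.

Two structural conditions drive everything else:

* **normal**: every vertex outside `X` has a *tree-child* (a child of
  indegree one), and no arc is *redundant* (bypassed by a directed path
  from its tail to its head);
* **semibinary**: every hybrid has indegree exactly 2 and (unless a
  leaf) outdegree 1.

On normal networks with strictly positive weights on normal-headed arcs
the tree-average distance restricted to `X` is a metric, and distinct
parent maps display topologically distinct trees (so the average over
parent maps is an average over distinct displayed trees, `2^k` of them
for `k` hybrids). `check_metric()` verifies the axioms and lists
violating pairs and triples; distances *between internal vertices* are
also defined (and used internally) but are not metric — hybrid arcs
weigh zero, so distinct vertices can sit at distance zero.

## Identifiability and its reconstruction engine

The central result implemented here: if `N` is normal and semibinary,
and every hybrid is either declared equiprobable or sits in a
*grandparent configuration* — one parent `q2` has an ancestor `q3` with
a normal path down to `q2`, its own disjoint normal path to a taxon
`x3`, and no directed path to the other parent `q1` — then the exact
tree-average distances on `X` determine every arc weight and every
inheritance probability, by closed-form expressions.
`check_identifiability()` verifies the configuration per hybrid;
`fit_tree_average()` performs the recovery.

Why the configuration matters: counting parameters, a network with `n`
base-set taxa offers `choose(n, 2)` distances, and a normal semibinary
network has at most that many normal-headed arcs (`arc_count_bound()`).
The smallest one-hybrid network (fixture `"basic"`, four taxa, six
normal-headed arcs) exhausts the bound: its six distances cannot also
pin down a free inheritance probability, and the fit refuses unless the
hybrid is declared equiprobable. The `"grandparent"` fixture (five
taxa, eight normal-headed arcs) is the minimal configuration with slack
enough to recover `alpha` itself.

The engine classifies each normal-headed arc `(a, b)` by its
surroundings and dispatches to the matching identity:

* tail `taxon_path` — `a` reaches a taxon by a normal path avoiding
  `b` (four-point-style formulas, `fourpoint_weight()`);
* tail `hybrid_tail` — `a` is a hybrid and `b` its unique child
  (`hybrid_taxon_distance()`, `hybrid_child_weight()`);
* tail `hybrid_coparent` — `a` is the parent of a hybrid
  (`equiprobable_parent_distance()` / `equiprobable_parent_weight()`
  when the hybrid is equiprobable, otherwise `solve_inheritance()` /
  `hybrid_parent_weight()`);

crossed with head cases `taxon`, `two_tree_children`, and
`mixed_children` (one tree child plus a hybrid child), the last handled
by subtracting two parent-to-taxon distances through the head's taxon.
The case precedence (`taxon_path` before `hybrid_tail` before
`hybrid_coparent`, and analogously at the head) picks the identity with
the fewest hypotheses, which keeps dispatch deterministic and avoids
the alpha-dependent branch when it is not needed. All internal
distances needed by the subtraction schemes are themselves computed
from base-set distances only, never from the unknown weights.

`solve_inheritance()` recovers `alpha` at a hybrid in the grandparent
configuration from ten taxon-pair distances among
`{r, x1, x2, x3, y}`. It first reads off the alpha-free segments
(root-to-junction, junction-to-`q3`, `q3`-to-`x3`, hybrid-to-`y`) by
four-point combinations, then eliminates the remaining three equations
in `alpha` and two segment lengths. The direct closed-form expressions
for the same quantities are evaluated as a mandatory cross-check
(within 1e-9 in double mode, exactly in rational mode); disagreement
raises an internal-consistency error rather than returning a value.
Degenerate geometry (a zero junction-to-grandparent segment, which
makes the denominator vanish) and recovered probabilities outside the
open interval (0, 1) — including exactly 0 or 1, where the model
degenerates to a tree plus a dead arc — are reported as errors: such
input cannot have been generated by the model with positive weights.

### Determinism and tie-breaks

Vertex labels are opaque strings; every choice (parent-map enumeration
order, normal-path witnesses, which hybrid child anchors a case, which
parent is `q2`) is resolved in lexicographic label order, with the
nearest grandparent candidate tried first. Witness choice does not
affect recovered values on model-generated input (an invariant the test
suite checks); determinism makes runs reproducible and case logs
readable. The `case_log` component of a fit records, per arc, the case
pair and every witness used.

## Exact arithmetic

Identifiability is an exact statement, so the forward model and the
engine run in exact rational arithmetic whenever weights and
probabilities are rational: a vectorised fraction class (`rational()`)
with numerator and denominator as integer-valued doubles, reduced after
every operation, refusing (with an error) any intermediate beyond
2^53 where double integers lose exactness. On exact input, a
round-trip `distance_matrix()` → `fit_tree_average()` has residual
identically zero, and quantities like 11/3 survive bit-exactly.
Distances supplied as plain doubles (for example read from a decimal
file) run the same formulas in double precision: values within 1e-9 of
zero are treated as zero, recovered weights in (−1e-9, 0) are clamped
to zero with a warning, and anything more negative is an
inconsistent-distances error. File readers keep exactness where the
text allows it: integers, `p/q` fractions and short decimals (at most
six decimal places) become rationals; longer decimals become doubles.

Probability tables are validated at construction, not at use: values
outside [0, 1] or not summing to one (exactly for rationals, within
1e-12 for doubles) are rejected by `inheritance_model()`. Zero weights
on normal arcs are accepted by the forward model — the distance is
still well defined — but `check_metric()` is the advertised guard, since
the metric identity axiom needs strictly positive normal-arc weights.

## The synthetic generator

`random_network()` grows a random rooted binary tree and adds hybrids
one at a time: two tree arcs with incomparable heads are subdivided and
joined to a fresh hybrid carrying a new leaf. After each addition the
network is re-validated — normality, the semibinary condition, and
(unless inheritance is equiprobable) the grandparent configuration —
and failures are rolled back and resampled, so every emitted network
lies in the identifiable class by construction. Defaults, chosen once
as realistic study conditions: arc weights uniform on quarter-integers
in [1, 10] (strictly positive, in arbitrary units of expected change);
inheritance probabilities uniform on {3/40, ..., 37/40}, i.e. bounded
away from the degenerate endpoints inside (0.05, 0.95); identical seeds
give identical output.

What the generator emulates is the *mathematical* data-generating
process: exact tree-average distances from a known network. It does not
emulate estimation noise in distances, model misspecification of the
substitution process, unknown network topology, or hybrids of indegree
three or more. Passing tests therefore demonstrate correctness of the
identities and the engine on exact inputs — the theory's own claim —
and say nothing about robustness to noisy distance estimates, which the
exact theory does not cover (there is deliberately no least-squares
mode).

Problem sizes used by the test suite and acceptance script, chosen to
exercise every case while keeping runs comfortably reproducible on a
laptop: the named fixtures (4–11 taxa), and sweeps of 100 generated
networks with 4–12 leaves and 0–3 hybrids (seeds 0–99), which complete
in well under a minute and visit every tail/head case pair including
the subtraction schemes.

## Known limitations

* Topology is an input: the network itself is not inferred from
  distances (that is a separate reconstruction problem); only its
  weights and probabilities are.
* Hybrids of indegree ≥ 3 are out of scope (the semibinary check
  rejects them), as is recovery of a free `alpha` when the grandparent
  configuration fails — the `"basic"` fixture demonstrably has
  infinitely many solutions there, so the fit refuses rather than
  guessing.
* Exact rational mode is limited to components below 2^53; pathological
  weight denominators can overflow, at which point the error suggests
  double mode rather than silently losing exactness.
* Extended-Newick output labels every internal vertex (the identities
  refer to internal names); anonymous-interior Newick from other tools
  gains synthetic labels on read and will not round-trip names.
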