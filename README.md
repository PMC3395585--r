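# tadnet — tree-average distances on rooted phylogenetic networks

Phylogenies with hybridization or lateral gene transfer are rooted
networks, not trees: a *hybrid* vertex has two parents and inherits each
character from one of them, with probability `alpha(u, h)` of coming
from parent `u`. Every choice of one parent per hybrid (a *parent map*
`p`) displays a tree `N_p` with probability
`Pr(p) = prod_h alpha(p(h), h)`, and the **tree-average distance**
between two measurable taxa is the expected path distance over the
displayed trees:

```
d(x, y; N) = sum over p of  Pr(p) * d(x, y; N_p),
```

where arc weights `w(a, b) >= 0` measure expected genetic change and
arcs into hybrids weigh zero (the hybridization itself is
instantaneous). On *normal* networks (tree-child outside the base set,
no redundant arcs) with positive weights this distance is a metric on
the base set `X` (root/outgroup, leaves, and any measurable internal
vertices).

The package is for people working with distance-based phylogenetics on
reticulate evolution. It implements both directions:

* **forward**: validate a network (normal / semibinary / redundant-arc
  checks), enumerate parent maps and displayed trees and their splits,
  and compute the tree-average distance matrix in exact rational
  arithmetic;
* **inverse**: given the network and its exact distances on `X`,
  recover *every* arc weight and *every* inheritance probability by
  closed-form case analysis (`fit_tree_average()`). This works whenever
  the network is normal and semibinary and each hybrid is either
  declared equiprobable or has a parent with a *grandparent
  configuration* (an ancestor with its own independent path to a
  taxon); `check_identifiability()` tests the condition per hybrid.

A generator of random normal semibinary networks
(`random_network()`), extended-Newick and PHYLIP square-matrix I/O, and
a command line (`exec/tadnet`, or `run_cli()`) round out the toolkit.

## Worked example

The `"grandparent"` fixture is the smallest configuration in which an
inheritance probability is identifiable: a hybrid `h0` with parents
`q1`, `q2`, where `q2`'s parent `q3` carries its own path to a taxon.
Ten taxon-pair distances face nine unknowns (eight weights on
normal-headed arcs plus `alpha`):

```r
library(tadnet)
fx <- example_network("grandparent")   # alpha(q1, h0) = 3/10
dm <- distance_matrix(fx$network, fx$model)
print(dm)
#> Tree-average distance matrix on 5 taxa (exact)
#>    r  x1  x2  x3   y
#> r  0 6.0 5.0 4.0 4.0
#> x1 6 0.0 9.0 8.0 6.8
#> x2 5 9.0 0.0 5.0 4.2
#> x3 4 8.0 5.0 0.0 4.6
#> y  4 6.8 4.2 4.6 0.0

fit <- fit_tree_average(fx$network, dm)
coef(fit, exact = TRUE)
#>     w(h0->y)    w(q1->h0)    w(q1->x1)    w(q2->h0)    w(q2->x2)    w(q3->q2)
#>          "1"          "0"          "3"          "0"          "2"          "1"
#>    w(q3->x3)      w(r->v)     w(v->q1)     w(v->q3) alpha(q1,h0) alpha(q2,h0)
#>          "2"          "1"          "2"          "1"       "3/10"       "7/10"
fit$residual
#> [1] 0
```

Every weight comes back exactly (the entries `6.8 = 34/5` etc. are
stored as rationals), the inheritance probability `3/10` is recovered
from distances alone, and the residual — the largest difference between
the input matrix and the matrix recomputed from the fitted parameters —
is identically zero. `summary(fit)` additionally shows, per arc, which
tail/head case and which witness taxa the engine used.

The same from the shell:

```sh
exec/tadnet simulate --leaves 6 --hybrids 2 --seed 7 \
    --out-network net.nwk --out-distances d.phy --exact
exec/tadnet validate --network net.nwk
exec/tadnet reconstruct --network net.nwk --distances d.phy --root root \
    --out-weights w.tsv --out-alpha a.tsv --exact
```

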