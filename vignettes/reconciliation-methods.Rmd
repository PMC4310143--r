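---
title: "Methods: exact all-optimal cophylogeny reconciliation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact all-optimal cophylogeny reconciliation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cophyrec)
```

## The model

A reconciliation maps every vertex of a rooted binary parasite tree *P*
onto a vertex of a rooted binary host tree *H*, extending the observed
leaf association φ. Two structural constraints make a map γ admissible:
no parasite vertex may map to a proper ancestor of its parent's image,
and every internal parasite vertex must keep at least one child inside
the host subtree rooted at its own image. The event at an internal
vertex *v* with image *h* and child images *u₁*, *u₂* is then forced by
the geometry:

* **cospeciation** — *h* internal and *u₁*, *u₂* lie in the two
  different child subtrees of *h*;
* **duplication** — both children stay in the subtree of *h* without
  that split pattern (including either child sitting on *h* itself);
* **host switch** — exactly one child stays below *h*, the other lands
  on a vertex *incomparable* to *h* (neither ancestor nor descendant).

Anything else is invalid. Losses are charged on descending path
segments only: a cospeciation at *h* with child images at distance
*d₁*, *d₂* costs `(d₁−1) + (d₂−1)` losses (the path passes through a
child of *h* "for free" on each side), a duplication costs `d₁ + d₂`,
and a switch charges the distance down to the *staying* child's image
while the jumping branch carries no losses — the landing site *is* the
jumped child's image. This convention is the only one under which
zero-loss solutions with many switches exist, which is what makes
free-loss cost vectors combinatorially explosive.

The total cost is linear, `c_c·#c + c_d·#d + c_s·#s + c_l·#l`, with all
four costs arbitrary reals. Negative costs are deliberately supported
(e.g. rewarding cospeciations with `c_c = −1`); nothing in the
algorithm assumes monotonicity.

## The dynamic program and the solution DAG

`fill_dp()` computes `D[p, h]`, the minimum cost of reconciling the
clade at parasite vertex *p* with *p* mapped to host vertex *h*,
visiting parasite vertices in postorder. Because the cost decomposes
over internal vertices (each vertex carries its own event and loss
charges), the recursion is exact for any real cost vector.

For each cell the children *p₁*, *p₂* may be placed at any pair (x, y)
consistent with one of the three events. Each event region is
*separable* — its cost is an x-part plus a y-part — so the minimum over
a region is a sum of two one-dimensional minima, and the set of all
optimal pairs is the Cartesian product of the two argmin sets. One
subtlety: the duplication region is "subtree(h)² minus the
cospeciation pairs", which is not a product set; it is decomposed into
seven separable blocks built from {h}, the left child subtree and the
right child subtree. Keeping the regions event-consistent (rather than
letting a duplication-priced minimum range over the whole subtree)
matters as soon as the duplication cost is below the cospeciation cost:
the event of a solution is *derived from the mapping*, so a pair that
classifies as cospeciation must never be priced as a duplication.

Per cell the DP stores every cost-optimal (x, y) pair (at most n²),
tagged with its event and, for switches, the takeoff-to-landing
distance. These per-cell alternative lists form a DAG rooted at the
optimal root cells; every choice of one alternative per visited cell is
one optimal reconciliation and vice versa. Filling is O(n³m) time and
space, with all host subtree/incomparability/distance queries served by
precomputed O(n²) tables.

Ties are detected with an absolute tolerance of 1e-9; with
integer-valued cost vectors (the ordinary use case) all arithmetic is
exact and the tolerance is inert.

## Counting and enumeration

`count_optimal()` multiplies and sums counts along the DAG
(`N(cell) = Σ_alternatives N(left child cell)·N(right child cell)`),
memoized per cell, so counting costs no more than extracting one
solution. Counts routinely exceed 2⁶⁴, so the arithmetic uses exact
base-10⁶ limb integers implemented in the package; the suite validates
the limbs against double arithmetic in the exact range, against known
constants, and against modular recomputations of the same DAG count.

`solution_iterator()` enumerates by an odometer over per-cell
alternative indices: the deepest (rightmost) advanceable choice point is
incremented and everything below it reset to its first configuration.
Consecutive solutions therefore cost O(m) amortized work, the support
structure is linear in *m*, and the stream is deterministic: root cells
in host postorder, then alternatives ordered cospeciation <
duplication < switch, then by the children's postorder ids. A
`max_solutions` cap supports instances whose counts make full
enumeration meaningless; truncation is always flagged.

## Time feasibility

A switch implies the donor and recipient host lineages coexisted. With
takeoff vertex *h* and landing vertex *l*, the package adds the
precedence constraints `parent(h) → l` and `parent(l) → h` to the
ancestry digraph of internal host vertices (leaf endpoints are
represented by their parents; the self-loops this creates for switches
between sibling leaves are vacuous and dropped). The reconciliation is
time-feasible iff this digraph is acyclic — checked with a single
`igraph::is_dag()` pass over the O(n²)-edge graph. A hand-rolled
exhaustive oracle (existence of a total order of internal host vertices
satisfying every edge) guards this encoding in the test suite for hosts
with up to 7 internal vertices; a constructed pair of crossed switches
on a 4-leaf host provides the canonical infeasible fixture. Note that
constraints only ever accumulate: adding a switch can turn a feasible
solution infeasible, never the reverse.

## Bounded-distance switches

The k-bounded variant restricts every switch's takeoff-to-landing
distance (topological edge count on the undirected host path; branch
lengths are read but ignored) to at most *k*. The bound enters the DP
only through the candidate landing sets, so `k ≥ diameter(H)` is
exactly the unbounded problem (asserted in the suite as full
solution-set equality) and the optimal cost is non-increasing in *k*.

Three derived quantities support the workflow on instances whose
unbounded optimum is infeasible or unmanageably numerous:

* `compute_k_start()` — the smallest maximum-switch-distance over all
  optimal solutions, obtained without enumeration by a min–max DP over
  the solution DAG (min over alternatives of the max of child values
  and the alternative's own switch distance; min and max distribute
  over the DAG exactly as cost does).
* `find_kA()` — decrement *k* from `k_start` until some optimal
  solution at that bound is time-feasible; the cost there upper-bounds
  the cheapest acyclic reconciliation.
* `find_kprime()` — increment from `k_start` to the first bound whose
  optimum equals the unbounded cost *and* has a feasible solution,
  shrinking the solution set without losing optimality.

Both scans re-solve the DP per *k* (bounds move by a handful of steps
in practice, so incremental updating would buy little) and re-enumerate
under a solution cap, reporting "undetermined" rather than guessing
when the cap is hit.

## Root selection

For an unrooted parasite (gene) tree, `select_root()` roots on every
edge in turn, solves each rooted instance, and returns the cheapest
rooting; ties go to the smallest edge index in the postorder edge
ordering, making the choice reproducible.

## Synthetic data and what the tests show

`random_instance()` draws host and parasite topologies by iterative
uniform leaf attachment — exactly uniform over rooted binary
leaf-labelled topologies — and associates each parasite leaf with a
uniformly random host leaf; everything is a pure function of the seed.
These fixtures are deliberately structure-free: real host–parasite
associations are phylogenetically correlated, so real instances have
far fewer switches and far more feasible optima than these. Passing the
oracle-equivalence suite therefore certifies the *algorithms* (cost
optimality, completeness of enumeration, exact counting, feasibility
verdicts) on arbitrary topologies and cost regimes, but says nothing
about biological interpretation of any particular dataset.

Problem sizes used by the suite: 200 random instances with up to 6
leaves per tree (where the exhaustive oracle enumerates every candidate
mapping in vectorized form), feasibility oracles up to 7 internal host
vertices (≤ 5040 total orders), a 20+20-leaf instance for enumeration
throughput, and a 64+64-leaf caterpillar×balanced family with free
losses whose exact count has 34 digits — the size at which exactness
beyond 2⁶⁴ is actually exercised.

## Degenerate inputs and numerical choices

Single-leaf trees are legal (the reconciliation is the forced leaf
association at cost 0). A valid reconciliation always exists for any
`k ≥ 1` — mapping every internal vertex to the corresponding LCA uses
only cospeciations, duplications and losses — so "no solution" can only
be reported for tables inspected at non-optimal cells; the code paths
exist and return `opt = Inf` with an empty solution stream. Infinity is
a first-class cell value: arithmetic with it stays infinite and such
cells store no alternatives. Event-count classes, the feasibility
split, and all report orderings are deterministic so identical runs
produce byte-identical output.

## Known limitations

* Non-binary (polytomous) trees are rejected rather than resolved.
* Branch lengths and dated trees are ignored; switch distance is purely
  topological.
* The enumeration delay is O(m) amortized (worst-case resets are
  bounded by the DAG height ≤ 2m), not worst-case-per-solution linear.
* No probabilistic/likelihood reconciliation and no per-edge costs.
* The feasibility test constrains host-side orderings only.
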