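---
title: "Anonymizing attributed medical social networks by greedy k-member clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Anonymizing attributed medical social networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanonet)
```

## The problem

Hospitals and registries release patient data for research with unique
identifiers (names, SSNs) removed, but the released records still carry
*quasi-identifiers* — age, gender, zip code, marital status — that an
attacker can join against public data to re-recover identities and, with
them, the sensitive diagnosis. When the release also includes a social
network over the patients (who is related to whom), the graph structure
itself becomes further background knowledge for the attacker.

`kanonet` implements a release procedure with a *k-anonymity* guarantee
for such attributed graphs: patients are grouped into clusters of at
least `k`, each cluster is published as a single supernode carrying only
*generalized* attributes (a numeric interval, a coarser category), its
member count and its internal edge count, and cluster pairs are linked by
superedges carrying only cross-edge counts. Within a cluster, the `k`
or more patients are mutually indistinguishable, both by attributes and
by wiring.

The linkage-attack auditor makes the threat concrete. On the bundled
seven-row hospital table and six-row public table, joining on zip code
and age uniquely re-identifies five of the six public individuals:

```{r}
lt <- link_attack_tables()
linkage_attack(lt$private, lt$public, c("Zip", "Age"))
```

`generalized_linkage()` repeats the join after generalizing both tables
identically; match sets can only grow as levels coarsen, which is exactly
the mechanism the clustering release relies on.

## Distances

The graph is undirected and unweighted, held as a symmetric binary
adjacency matrix over an ordered node list. Two distances drive the
clustering:

* **Node distance.** For nodes $v_i, v_j$ with a shortest path of $d$
  edges (hence $mn = d + 1$ nodes), $D(v_i, v_j) = d / mn = d/(d+1)$:
  $0$ for a node and itself, $1/2$ for neighbours, approaching $1$ for
  remote pairs. The definition is silent on disconnected pairs; we define
  their distance as exactly $1$, the supremum of the connected values,
  which keeps the stated $[0, 1]$ range and reads naturally as maximal
  dissimilarity. Shortest paths are computed by breadth-first search
  (via `igraph`); a nested-loop Floyd–Warshall transcription serves as
  the independent oracle in the test suite.

* **Structure distance.** The distance from a node to a cluster is the
  mean node distance to the cluster's members — also in $[0, 1]$.

## Information loss

A release is scored by two normalized losses.

**Generalization loss.** Each cluster $s_j$ publishes, per numeric
attribute, the interval $[\min, \max]$ of its members' values and, per
categorical attribute, the lowest common ancestor of the members' values
in that attribute's generalization hierarchy. With $p$ numeric and $q$
categorical attributes over $n$ records,

$$\mathrm{GLoss} = \frac{\sum_j |s_j|\,\bigl(\mathrm{Attr}(s_j) +
\mathrm{Cate}(s_j)\bigr)}{n\,(p+q)},$$

where $\mathrm{Attr}$ sums interval widths over the *global* attribute
ranges (computed once over the whole dataset, before clustering) and
$\mathrm{Cate}$ sums the subtree height of each lowest common ancestor
over the height of its hierarchy. Two conventions close small gaps in
the definition: an attribute whose global range is zero contributes
nothing (every cluster is already fully specific on it, and the ratio
would otherwise be $0/0$), and a leaf's subtree has height zero, so each
categorical term is in $[0,1]$. GLoss is $0$ for all-singleton
partitions and $1$ for a single cluster spanning every global range and
generalizing every categorical attribute to its root.

**Structure loss.** Publishing only edge *counts* hides which specific
pairs are wired. For a cluster with $e$ of $\binom{|s|}{2}$ possible
internal edges the intra-cluster loss is $2e\,(1 - e/\binom{|s|}{2})$,
zero when the cluster is edgeless or complete and largest when half the
pairs are linked; the inter-cluster loss for a pair of clusters is
$2e\,(1 - e/(|s_i||s_j|))$ on the $|s_i||s_j|$ possible cross edges.
Their sum, normalized by $n(n-1)/4$, is the structure loss, in $[0,1]$.

On the analytic maxima of these components: the intra-cluster term is
maximized at $e = \binom{|s|}{2}/2$, giving $|s|(|s|-1)/4$ per cluster.
The matching inter-cluster bound is conventionally stated as
$|s_i||s_j|/4$, but substituting the maximizing count
$e = |s_i||s_j|/2$ into the loss gives $|s_i||s_j|/2$.
`structural_loss_bounds()` therefore reports both — `max_inter_stated`
for reference and `max_inter_derived` for any normalization check — and
the package's own assertions use the derived value. (Note also that the
maximizing $e$ need not be an integer; for odd pair counts the best
*integer* edge count attains slightly less than the bound, which is why
the test suite checks the real-valued maximum and only an inequality for
integer counts.)

**Total loss** is the unweighted sum $\mathrm{GLoss} + \mathrm{SLoss}$.
This is the unique reading consistent with the reference grids bundled
in `printed_loss_grids()`: their cell-wise sum is minimized at
$(k=3, a=1)$ at $0.302819$, exactly the sum of the two corresponding
cells ($0.118513 + 0.184306$). The weight $a$ steers the clustering
objective, not the report.

## The greedy clustering algorithm

`greedy_k_cluster(g, records, schema, k, a)`:

1. While at least `k` nodes are unassigned: open a cluster at the
   unassigned node of maximum degree (the most structurally exposed
   node), then repeatedly add the unassigned node with the smallest
   candidate cost until the cluster has exactly `k` members.
2. Fewer than `k` nodes remain: append each leftover, in input order, to
   the existing cluster it is cheapest to join. No undersized cluster is
   ever produced, so the output always satisfies `assert_k_anonymous()`.

The candidate cost of adding node $v$ to cluster $s$ is the convex
combination

$$a \cdot \frac{\mathrm{Attr}(s \cup \{v\}) + \mathrm{Cate}(s \cup
\{v\})}{p+q} \;+\; (1-a) \cdot D(v, s).$$

The design was genuinely open here: the source method states only that
the nearest unallocated node joins the cluster, while its experiments
clearly vary an attribute/structure weight. We chose the convex
combination because both terms already share the $[0,1]$ scale, the two
extremes collapse cleanly ($a=0$ ignores attributes entirely, $a=1$
ignores the wiring), and it reproduces the qualitative behaviour of the
reference grids — generalization loss falls as $a$ grows, structure loss
rises with $k$. The original weighting formula is not recoverable from
the published numbers, and we make no attempt to reverse-engineer it
cell by cell.

Determinism without randomness: every tie (seed selection, candidate
selection, leftover placement) breaks toward the smallest input-order
index, so identical inputs give identical partitions. Internally the
clusters keep incremental generalization state (interval hulls, running
lowest common ancestors, running distance sums), which the test suite
checks against a naive re-run built from the public
`seed_node()`/`candidate_cost()` functions.

`k` must satisfy $2 \le k \le n$ (`k = 1` anonymity is vacuous). There
is no post-hoc swap or re-optimization phase. An exhaustive-enumeration
oracle (`brute_force_partition()`, capped at $n \le 10$ because the
number of set partitions grows super-exponentially) confirms on seeded
small instances that the greedy total loss is never below the true
optimum, and typically close to it.

## Hierarchies and their defaults

Hierarchies are rooted trees in a small JSON format
(`{"root": {"child": {...}, "leaf": {}}}`). For the bundled 60-patient
benchmark the defaults are deliberately minimal: Gender and Smoke are
flat two-leaf trees, Marriage a flat three-leaf tree (height 1 each),
and Zip a three-level tree (full code → 3-digit prefix → root,
height 2) built from the observed codes — the prefix level mirrors how
postal codes aggregate geographically. The original taxonomy figures
are not recoverable in full detail from the source text, so these
reconstructions are package defaults, overridable via the JSON file
passed to `read_inputs()`.

## The synthetic network generator

The 60-patient benchmark's true edge list was never published, so
`synth_edges()` provides seeded stand-ins: an Erdős–Rényi model (each
pair linked independently with probability `mean_degree / (n-1)`) and a
ring-lattice model with Watts–Strogatz-style rewiring
(`rewire_prob = 0.1` by default, the customary small-world setting; `0`
gives the exact lattice). The package's benchmark condition is the
Erdős–Rényi model at mean degree 4 — a realistic density for a sparse
acquaintance network of this size, chosen once and used for all tests
and for the shipped `patients60_synthetic_edges.tsv` (seed 1).

What the generator does and does not emulate: it reproduces the size,
sparsity and (for the ring model) local clustering of a small social
network, but not degree heterogeneity, community structure or
homophily between attributes and wiring. Tests passing on these graphs
therefore establish the *correctness and invariants* of the metrics and
the algorithm (k-anonymity, conservation laws, ranges, determinism,
oracle agreement), not that real networks would yield any particular
loss value. In particular the reference loss grids cannot be reproduced
numerically without the original edge list; on synthetic edges the
pipeline's loss surface behaves the same way qualitatively but sits at
different levels, and the package reports those values as what they are
(`*_synthetic`).

## Numerical and scale choices

* All loss computations are plain double arithmetic; the independent
  nested-loop oracles agree with the production implementations to
  `1e-12` on seeded instances ($n = 8$), and exact rational examples
  (e.g. a structure loss of exactly $1/2$ on a partitioned 4-path) are
  asserted without tolerance.
* Property suites use seeded graphs of 5–13 nodes (200 instances for
  conservation/range laws, 100 for distance symmetry) and the full
  $10 \times 6$ parameter sweep on the 60-node benchmark; these sizes
  exercise every code path while keeping the default test run fast.
* The exhaustive oracle enumerates all valid partitions ($4140$ set
  partitions at $n = 8$ before the size filter) with a lexicographic
  tie-break, so "greedy ≥ optimum" is checked against the true minimum.
* Degenerate inputs are first-class: empty edge lists, disconnected
  graphs, constant numeric attributes, and single-cluster partitions all
  have defined, tested behaviour.

## Limitations

* The greedy pass has no refinement phase; it can and does end above the
  exhaustive optimum on adversarial small instances.
* k-anonymity of the release is the guarantee; diversity of the
  sensitive values within a cluster (l-diversity, t-closeness) is out of
  scope, as are weighted/directed/evolving graphs and suppression-based
  recoding.
* The linkage auditor models exact joins on quasi-identifiers (after
  optional generalization); probabilistic record linkage is not modelled.
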