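---
title: "Normalized L3 link prediction: models, simulations and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalized L3 link prediction: models, simulations and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(l3npred)
```

## The problem and the model

A PPI network is an undirected simple graph whose nodes are proteins and
whose edges are observed physical interactions. High-throughput screens
leave these networks incomplete, so link predictors score every non-adjacent
node pair ("candidate edge") by how strongly the observed topology suggests
a missing interaction. Two competing topological principles exist. The
common-neighbor (triadic closure) principle scores shared immediate
neighbors; in a PPI network, however, two proteins with many shared partners
tend to have *similar* interfaces, and similar interfaces generally do not
dock with each other. The L3 principle instead counts paths of length three:
x interacts with u, whose interface matches v's, which interacts with y —
direct evidence that x's interface is compatible with y's.

For a candidate pair {x, y}, the package works with the *L3-elements*:
U = N(x) ∩ N(N(y)) and V = N(y) ∩ N(N(x)). Every length-3 path is x–u–v–y
with u ∈ U and v ∈ V; paths are simple (u ≠ v is automatic in a simple
graph once {x, y} is non-adjacent). A node may sit in both U and V, and the
score sums run over ordered role assignments: such a node may serve as u in
one term and v in another, never both roles in one term.

The *ideal L3 graph* formalizes maximal evidence: a complete bipartite graph
on U and V, x adjacent to exactly U, y to exactly V. The L3N score measures
how closely the actual neighborhood resembles this ideal by multiplying, for
each U–V edge, similarity factors for the conditions N(x) = U, N(y) = V,
N¬x(u) = V, N¬y(v) = U, N(x) = N¬y(v) and N(y) = N¬x(u), where
N¬b(a) = N(a) \ {b}; the two factors that do not depend on (u, v) are
hoisted outside the sum. The similarity metric f is pluggable: the simple
ratio f1 (maximal already when one set contains the other) or the Jaccard
coefficient f2 (maximal only at equality). L3N′ uses the un-deleted
neighborhoods N(u), N(v) in all four inner factors, which deliberately
offsets each comparison by the anchoring edge to x or y: among u-nodes whose
remaining neighborhood is fully contained in V, the one with the larger
neighborhood then scores higher, which is the desired behavior because a
larger matched neighborhood is stronger evidence of compatibility.

Closed forms on the ideal graph with |U| = |V| = n anchor the
implementation and its tests: the path-count control and both L3N variants
equal n²; L3 equals n²/(n+1); L3N′(f1) equals n²·(n/(n+1))²; Sim equals
2n²/(n+1); CH2 equals n²(n+1).

## Parameters that matter

* **metric** (`"f1"`/`"f2"`, no default): f1 is tolerant of partially
  observed neighborhoods (subset suffices), f2 stricter. Both are exposed
  everywhere the score family is.
* **seed** (integer, default 1): every source of randomness — tie-breaks,
  simulation edge orders, split sampling, the random control — flows from
  one root seed through a deterministic stream-derivation, so any result is
  reproducible from its logged seed.
* **Tie-breaking**: candidates sharing a score are shuffled by a seeded
  draw. This matches the uniform-random control's protocol and makes
  precision–recall bands honest instead of artifacts of insertion order.
* **Candidate universe**: all unordered non-adjacent pairs over the graph's
  nodes. `restrict = "l3"` is a fast path that scores only pairs joined by
  a length-2 or length-3 path; every excluded pair provably scores 0 under
  an L3-family predictor and is kept in the table as a score-0 tail, so the
  positive-score ranking is unchanged.
* **Simulation sizes** (`build_ideal_l3(n_u, n_v)`): the canonical
  perturbation study uses the square graph with 50 nodes per part (2450
  removable compatible edges, 2550 insertable incompatible ones). The
  package's own test suite runs the stochastic orderings at 20 nodes per
  part with 5 repeats, a size at which the qualitative orderings are stable
  across seeds while a full run stays cheap.
* **Duplication–mutation generator** (`p_keep = 0.7`, `p_anchor = 0.1`):
  retention near 0.7 gives realistic interactome-like degree heterogeneity
  (heavy tails, many low-degree proteins) at moderate density; anchor
  probability 0.1 keeps duplicate–parent interactions rare, as in the
  standard duplication–divergence picture. Both are exposed; the defaults
  are fixed once here and used throughout.
* **`recall_cap`** (default none): PR curves can optionally stop at a fixed
  recall (e.g. 10%) to focus on the top of the ranking, the regime that
  matters when proposing candidates for experimental validation.

## Degenerate inputs and numerical choices

* **Zero-denominator rule**: any similarity metric whose denominator set is
  empty returns 0 — the conservative no-evidence value — keeping all scores
  finite.
* **Adamic–Adar** uses the natural logarithm; a common neighbor of degree
  ≤ 1 would divide by log 1 = 0 and is skipped (such a node is in fact
  impossible, since a common neighbor of x and y has degree ≥ 2).
* **Trace normalization** divides each (predictor, repeat) trajectory by
  its own maximum; all scores are non-negative, so trajectories land in
  [0, 1] with maximum exactly 1, and an all-zero trajectory stays zero.
* **Partial AUC** of an insertion trace integrates from the argmin of the
  median trajectory to the end, x rescaled over that window; if the minimum
  sits at the last point the window is empty and the partial AUC is 0.
* **Savitzky–Golay smoothing** (degree 3, window 21) is presentation-only:
  all AUCs and statistics are computed on unsmoothed trajectories unless a
  smoothed trace is passed explicitly.
* **Degenerate t-test**: two constant samples give p = 1 at equal means and
  p = 0 otherwise; otherwise the pooled-variance two-tailed two-sample
  t-test is used.
* **Edge iteration** is always in sorted identifier order wherever order
  could leak into results; graphs are never mutated in place during
  scoring, and the simulations log their edit order so any trajectory can
  be replayed exactly.

## Simulation protocols

`run_removal_sim()` deletes the compatible edges {u_i, v_j} (i ≠ j) one at
a time in uniformly random order; the index-matched edges {u_i, v_i} are
protected, which keeps (x, y, U, V) fixed — asserted at every step. A
predictor faithful to the L3 principle should lose score at least as fast
as the raw path count; division-based normalizations like L3's square root
instead flatten early losses when degrees are high.

`run_insertion_sim()` adds the incompatible edges ({u_i, u_j}, {v_i, v_j},
{x, v_i}, {y, u_i}) in uniformly random order. Insertions of {x, v} and
{y, u} can change the membership of U and V, so by default the L3-elements
are recomputed from their definitions at every iteration;
`freeze_elements = TRUE` implements the alternative reading that keeps U
and V at their ideal values. The choice matters: with frozen elements the
path-count control is constant (no inserted edge joins U to V), while the
recomputed reading lets inserted edges create genuinely new length-3 paths,
which is what the non-linear late-trajectory growth reflects. Recomputation
is the default because U and V are *defined* as functions of the current
graph.

## The evaluation harness

Monte-Carlo splits hide a fixed fraction of edges uniformly at random
(repeated with derived seeds); k-fold CV partitions the edge set instead. A
5-fold split trains on 80% of the edges, so it is comparable to a 20%
Monte-Carlo removal — the package's tests confirm the two give
statistically indistinguishable PR AUCs on a synthetic interactome.

`inject_negatives()` *replaces* a fraction of train edges with uniformly
sampled non-edges of the original network, holding the edge count fixed.
Corrupted true edges do not join the hidden ground truth: evaluation always
scores recovery of the originally removed set, now from partially falsified
data. The summary `delta_pr_auc()` is defined here as the mean over
consecutive ratio steps of the relative change of mean PR AUC; the
per-repeat-slope alternative was considered and rejected as it weights
noisy baselines more heavily. `overlap_ratio()` divides by the common top-k
size, which is the denominator consistent with comparing equally sized
prediction sets.

PR curves walk the ranking one candidate at a time (no score-level
grouping; the seeded tie-break makes this well defined), maintaining
tp + fn = |truth| and tp + fp = steps; the AUC is the trapezoid under
precision over the walked recall range, anchored at recall 0, so a perfect
ranking scores exactly 1. Whether zero-score candidates should be kept in a
ranking at all is a convention; keeping them (shuffled among themselves)
makes every truth pair reachable by the walk and is the package's explicit
choice.

## What the synthetic generators do and do not show

The ideal-L3 gadget networks and the duplication–mutation generator
exercise every stage of the pipeline with known ground truth: gadgets make
the hidden {x, y} edges the only candidates completing an ideal L3
neighborhood, and the DMC model produces realistic degree heterogeneity.
Neither reproduces other features of curated interactomes — study bias,
dataset-specific annotation conventions, correlated false negatives from
individual assays, or the sheer scale of modern databases. Passing the
package's tests therefore demonstrates correctness of the machinery and the
qualitative sensitivity behavior of the predictors, not field performance
on any particular database; real edge lists can be evaluated through the
same `load_edge_list()` → `score_all_candidates()` → `pr_curve()` path.

## Known limitations

* The CH2 score as printed in the literature cannot *decrease* under a
  single incompatible within-part insertion into an ideal L3 graph: a new
  {u_i, u_j} edge enlarges the community-intersection numerator
  |N(u) ∩ (U ∪ V)| while x and y are excluded from its denominator. Its
  insertion trace therefore starts non-decreasing, unlike every other
  L3-family predictor implemented here; the test suite asserts this
  formula-level property explicitly rather than the dip one might expect by
  analogy.
* Scoring all candidates is quadratic in nodes at heart (O(m²n) overall for
  the L3N family); the pure-R implementation targets the network sizes used
  in the examples and tests (hundreds of nodes, thousands of candidate
  pairs). Very large interactomes need the `restrict = "l3"` fast path and
  patience, or an external scorer.
* The dataset loader's column filter is generic (column index plus accepted
  values); it does not implement any database's full annotation dialect.
* Self-interactions can never enter the network container (a simple graph);
  they are counted in the load manifest instead.

## Reported numbers

Every number quoted in the package documentation is computed by the code
itself: the README example output comes from running the example, and the
quantitative claims are recomputed by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R` at run time.
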