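---
title: "Link prediction with average-centrality-filtered common neighbors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link prediction with average-centrality-filtered common neighbors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkSAC)
```

## The problem and the model

Link prediction asks which non-adjacent node pairs of an observed
undirected, unweighted simple graph are most likely to be (or become)
connected. In molecular interaction networks this prioritizes candidate
interactions for experimental validation; in collaboration or social
networks it anticipates future ties. Local similarity indices answer with a
score per pair; pairs are ranked and the top of the ranking is the
prediction.

The common-neighbor index `CN(v, u) = |Γ(v) ∩ Γ(u)|` is the simplest such
score but treats all shared neighbors alike. The SAC family refines it with
a parameter-free importance filter: compute a node centrality `C(·)`,
average it over the whole graph,

$$A_C(G) = \frac{1}{N}\sum_{v \in V} C(v),$$

and count only the common neighbors at or above that average:

$$\mathrm{SAC}_C(v, u) = \bigl|\{\,x : x \in \Gamma(v)\cap\Gamma(u)
\ \text{and}\ C(x) \ge A_C(G)\,\}\bigr|.$$

Two consequences follow directly from the definition and are enforced as
test invariants:

* **Dominance**: `0 ≤ SAC ≤ CN` for every pair and every centrality kind.
* **Scale invariance**: rescaling the centrality rescales its average
  identically, so the threshold test — and hence every SAC score — is
  unchanged. On a degree-regular graph every node sits exactly at the
  average and `SAC_D` degenerates to `CN` (the comparison is inclusive).

Four centralities instantiate the family: degree and local clustering
coefficient (local information), closeness and betweenness (global
shortest-path information). For comparison the package carries the
classical indices (Jaccard, Adamic–Adar, resource allocation, preferential
attachment) and two newer centrality-based scores, CCPA and KNLP.

## Conventions and parameters

**Degree denominator.** The textbook degree centrality divides by `N − 1`,
but the worked example this package reproduces divides by `N` (a degree-3
node of the 8-node example has centrality 0.375 = 3/8, its graph average
0.375). `degreeCentrality()` exposes `denominator = "N"` (default) or
`"N-1"`; by scale invariance the choice cannot affect SAC output, which the
suite asserts bit-for-bit.

**Closeness on disconnected graphs.** The classical formula
`(N − 1) / Σ_u D(v, u)` assumes connectivity. We use the reachable-set
variant `(R_v − 1)/Σ D × (R_v − 1)/(N − 1)` (R_v = number of nodes
reachable from v), which reduces exactly to the classical value on
connected graphs and degrades gracefully — isolated nodes score 0 — when an
edge holdout disconnects the training graph.

**Betweenness** is accumulated over unordered pairs and normalized by
`(N − 1)(N − 2)/2` by default; again only reported values, never SAC
scores, depend on the flag. A conservation identity — the unnormalized
scores sum to `Σ_{pairs} (D(u, v) − 1)`, exactly 19 on the packaged toy
graph — and a brute-force path-enumeration oracle pin the implementation.

**Eigenvector centrality** (needed by KNLP) is the principal adjacency
eigenvector, non-negative, unit Euclidean norm, computed by power iteration
on `A + I`. The unit shift leaves eigenvectors untouched but makes the
leading eigenvalue strictly dominant, so bipartite-like graphs (stars,
trees), whose adjacency spectrum is symmetric about zero, converge too.
Defaults: `tol = 1e-6` (L1 change per iterate), `maxIter = 1000`;
non-convergence is an error naming the residual.

**Adamic–Adar logarithm.** The natural log reproduces the worked-example
row (two degree-3 common neighbors give 2/ln 3 ≈ 1.82, printed 1.8; base-10
would give 4.19). A common neighbor in a simple graph always has degree
≥ 2, so the log never vanishes.

**CCPA** is `α·CN + (1 − α)·N/D` with shortest-path distance `D`; the
default `α = 0.8` is the value consistent with the published worked
example, and the disconnected-pair limit `N/D → 0` is used. **KNLP** is
`(CS_v + CS_u)/(CC_v + CC_u + ε)` with eigenvector scores CS, clustering
coefficients CC, and guard `ε = 1e-6` (no published value; any small
positive constant only perturbs ties among pairs whose clustering sums are
all zero).

**Adjacent pairs** are a precondition error for every index (all
definitions are stated for non-adjacent pairs); `allowAdjacent = TRUE`
overrides, which is occasionally useful for diagnostics.

**Determinism.** Node labels are opaque strings ordered numerically when
all labels are unsigned integers and in C-locale otherwise; rankings sort
by descending score with ties broken by this canonical pair order, so runs
are reproducible across platforms.

## The worked-example fixture and its errata

The eight-node, twelve-edge example graph is published only as a drawing,
so `toyGraph()` ships a reconstruction: `reconstructToyEdges()` enumerates
every graph with degree sequence (3, 3, 2, 5, 4, 3, 2, 2), the six
tabulated pairs non-adjacent, and nodes 4 and 7 as the common neighbors of
(1, 2), then scores each candidate against every published table cell that
is mutually consistent. A subtlety the derivation uncovered: the local rows
alone (CN, Jaccard, Adamic–Adar, resource allocation, preferential
attachment, degree-based SAC) admit exactly *two* graphs — swapping edges
{1–8, 3–6} for {1–3, 6–8} preserves all degrees and every tabulated
common-neighbor set — and only the clustering-dependent cells separate
them. With those included the maximizer is unique and equals the packaged
edge set; the test suite re-runs the whole search.

Eleven published cells are incompatible with *every* graph satisfying the
consistent rows and are recorded as errata in `toyTable2()` (one CN cell,
one betweenness-SAC cell, three each for closeness-SAC, clustering-SAC and
CCPA). `checkToyTable()` asserts consistent cells match at one-decimal
display (accepting the table's mix of rounding and truncation — 0.45 prints
as 0.4, 2.064 as 2) **and that erratum cells disagree**, so a code change
that silently "fixes" an erratum is flagged. The KNLP row is recorded as
unverified: its printed values match no normalization we could reconstruct,
and the guard constant used for it was never stated.

## Evaluation protocol

`splitEdges()` removes a uniform random 20 % of edges (floor, minimum one)
under a caller seed; the node set is preserved, and a split that
disconnects the training graph is allowed and announced. Candidates are
**all** pairs non-adjacent in the training graph — the standard choice; the
protocol this mirrors never states its negative set, which is one reason
published dataset-level AUROC/AUPR values are not exactly recomputable and
are not targeted here. Positives are exactly the held-out edges.

AUROC uses the midrank (Mann–Whitney) formulation, equal to the trapezoidal
ROC area and verified against an O(n_pos · n_neg) pairwise-counting oracle
to 1e-12. AUPR is average precision (precision at each positive's rank,
averaged), verified against explicit step enumeration. Top-k evaluation
literally restricts both metrics to the k top-scored candidates (ties at
the boundary resolved canonically); a single-class subset — inevitable at
small k — yields flagged `NA`s rather than an error, and the unrestricted
metrics are always reported alongside. One split per seed is shared across
measures, so comparisons are paired.

## What the synthetic benchmark shows, and what it cannot

The end-to-end checks run on a two-community stochastic block model (two
blocks of 100 nodes, within-block edge probability 0.12, between-block
0.01), chosen so that common neighbors are genuinely informative: the test
asserts CN's unrestricted AUROC exceeds the 0.5 random baseline by at least
0.1 averaged over 20 seeds. Sizes were chosen as the smallest scale at
which community structure dominates sampling noise; the full 11-measure run
takes about a second.

Synthetic graphs exercise correctness and determinism, not biological
realism: they lack the heavy-tailed degree distributions, assortativity
patterns and measurement noise of real interaction networks, so passing
benchmarks here says nothing about which measure will win on a given real
dataset. The harness accepts any edge list, and the published real-network
comparisons can be rerun by downloading the corresponding edge lists and
pointing `runExperiment()` or the `evaluate` CLI subcommand at them.

## Known limitations

* Directed, weighted and bipartite graphs are out of scope.
* `nonAdjacentPairs()` materializes O(N²) candidates; practical up to a few
  thousand nodes, beyond which negative sampling (not implemented, since
  the reference protocol does not define it) would be needed.
* KNLP scores are only meaningful relative to one another within a graph;
  their scale depends on the eigenvector normalization convention.
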