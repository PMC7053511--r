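---
title: "Activity-stratified proximity networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Activity-stratified proximity networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Grazing herds organize their social life differently depending on what they
are doing: animals that graze shoulder-to-shoulder may scatter when they rest,
and a few individuals may act as social anchors during inactive phases.
`herdnet` analyses this structure from focal-sampling data: an observer walks
the herd in half-hour steps, and for each animal records the single activity
it performs — one of grazing, moving, standing, ruminating, wallowing, lying,
drinking — and which herd-mates it is in close proximity to (within about a
metre, or in contact, while performing the *same* activity).

The analysis treats each (activity, period) pair as its own binary undirected
network over the *full* herd: vertices are all animals, an edge is a recorded
proximity pair, and animals doing something else in that period are isolated
vertices. Activities that do not occur in a period still contribute an empty
network, so a design with \(P\) periods always yields \(7P\) networks. With
the default design (91 animals, 240 periods) that is 1680 networks and
\(1680 \times 91 = 152\,880\) vertex-cases — these counting identities are
used as structural self-checks throughout the test suite.

## Indices

Global indices per network, on the adjacency matrix \(\alpha\) with \(N\)
vertices:

* **Density** \(D = \sum_{ij} \alpha_{ij} / (N^2 - N)\): the realized
  fraction of possible (ordered) pairs. The symmetric matrix counts every
  edge twice in both numerator and denominator.
* **Number of components**, by graph traversal; isolates are singleton
  components, so an empty herd network has \(N\) components.
* **Clustering coefficient** \(CC = \frac{1}{N}\sum_i CC_i\), where
  \(CC_i\) is the fraction of pairs of \(i\)'s neighbours that are
  themselves connected. \(CC_i := 0\) when \(\deg_i < 2\), and the average
  runs over all \(N\) vertices (the formula divides by \(N\)); an option
  restricts the average to vertices of degree \(\ge 2\).

Local (per-vertex) centralities:

* **Degree** \(\deg_i = \sum_j \alpha_{ij}\).
* **Closeness** \(Cl_i = 1 / \sum_j d_{ij}\), with \(d_{ij}\) the unweighted
  geodesic distance. On fragmented networks the sum over all vertices is
  infinite, so the sum runs over vertices *reachable* from \(i\), and
  isolates score 0. This keeps the index finite and monotone in
  connectivity, and matches common graph-library behaviour.
* **Betweenness** \(b_i = \sum_{\{j,k\}} g_{j(i)k} / g_{jk}\): the raw
  Freeman sum over unordered pairs, endpoints excluded, no normalization.
  Computed with Brandes' dependency accumulation and verified in the tests
  against exhaustive geodesic enumeration.
* **Eigenvector centrality**: the Perron–Frobenius eigenvector of the
  adjacency matrix, normalized to maximum entry 1.

## Numerical choices

Eigenvector centrality is the one index with real numerical subtlety on this
ensemble, because most networks are fragmented:

* The power iteration starts from the all-ones vector and runs on the
  spectrally shifted matrix \(A + I\). The shift leaves eigenvectors
  unchanged but guarantees convergence on bipartite components (a star has
  eigenvalues \(\pm\sqrt{k}\); unshifted iteration oscillates between the
  two eigenspaces forever).
* Iteration is per connected component. Two *different* components can have
  leading eigenvalues that differ by an arbitrarily small amount; iterating
  on the whole matrix then contracts with ratio
  \((\lambda_2 + 1)/(\lambda_1 + 1)\) arbitrarily close to 1 and stalls. Per
  component the Perron root is simple and convergence is geometric. The
  per-component eigenvalues are then compared: only components attaining the
  network-wide maximum (ties within `1e-8`) keep their entries, all others
  are zeroed — in exact arithmetic this is identical to the whole-matrix
  limit.
* Convergence is declared when successive max-normalized iterates differ by
  less than `1e-10` in max norm (cap 10 000 iterations per component); the
  result satisfies \(A e = \lambda e\) to better than `1e-8` on the dominant
  component. Entries below `1e-8` are clamped to exactly 0 so that
  rank-based statistics downstream see true zeros rather than numerical
  dust.
* Exact ties between components (e.g. two isomorphic cliques) are resolved
  by the symmetric all-ones start: all tied components keep their entries,
  each normalized to maximum 1. This is a convention, stated rather than
  derived.

Degenerate inputs follow fixed conventions so that every network in the
ensemble remains usable by the correlation stage: an empty network has
density 0, \(N\) components, clustering 0 and all centralities 0. Density is
undefined for \(N < 2\) (`net_density()` raises an error; the index table
reports `NA`).

## Spearman associations

Three data sets are assembled:

1. per network: global indices + seven binary activity indicators (exactly
   one indicator is 1 per row — the network's own activity);
2. per (network, vertex): centralities + the same indicators;
3. per (network, vertex) within one activity at a time: centralities + the
   animal's age (years) and gender (female = 1, male = 2).

Each (variable, index) pair gets a Spearman rank correlation: Pearson
correlation of midranks (average ranks for ties), two-tailed p from
\(t = \rho\sqrt{(n-2)/(1-\rho^2)}\) on \(n - 2\) degrees of freedom, with
\(\rho = \pm 1 \mapsto p = 0\); significance is flagged at 0.05 and 0.01 and
no multiple-testing correction is applied by default (a deliberate mirror of
common practice in the source literature; the raw p-values are all reported,
so any correction can be applied downstream). An exact permutation p-value
is available for \(n \le 8\) (full enumeration; beyond that the factorial
blow-up buys nothing over the t approximation). Pairs where either vector is
constant — e.g. every centrality inside an activity that never occurred —
are undefined and reported as `NA` with the reason, not silently dropped.
Activity coding uses seven separate binary indicators because the
correlogram reports one correlation per (activity, index) pair; a single
7-level code could not produce that. Empty networks are *included* as cases
at their degenerate-convention values: excluding them would leave rare
activities with almost no variation, and the strong negative density
correlations of rare activities depend on their many empty networks being
real observations.

## The synthetic herd generator

No field data ship with the package, so a seeded generator emulates the
observation design end-to-end: 88 females with ages drawn from a truncated
normal on 0.5–23 years (the pre-truncation location is solved numerically so
the *truncated* mean hits the 9-year target), 3 males aged 2.5–3 years, and
240 periods. Per period, each animal draws one activity from a multinomial
whose baseline prevalences are reweighted per animal by
\(\exp(\beta_{\text{age}} z_{\text{age}} + \beta_{\text{male}}
\text{male})\); because proximity partners exist only within an activity,
these participation biases are what generate age and gender gradients in the
centralities. Animals sharing an activity are partitioned into groups
(shifted-Poisson sizes, greedy fill, remainder forms the last group); each
group gets a random spanning chain — guaranteeing group connectivity — plus
every remaining within-group pair independently with probability
`group_closure`. Chain and closure decouple the density knob from the
clustering knob. Activities with `hub_attachment` > 0 instead wire active
animals to a designated hub animal, producing star-shaped components.

The default profiles encode the qualitative herd structure the pipeline is
meant to detect, chosen by reasoning about what each knob does to each
index rather than fitted to anything: grazing cohesive and nearly closed
(mean group 9, closure 0.85), moving/standing intermediate with negative age
bias and positive male bias, ruminating/wallowing/drinking sparse with small
open groups, and lying sparse but fully hub-attached. Two constraints
deserve note because they pull against each other: lying must be sparse
enough to sit *above* the ensemble median in component counts, yet its
single star must cover enough animals that its rows carry more eigenvector
mass than the pooled remainder (whose largest contribution is the dominant
grazing clique). Prevalence 0.08 with full attachment to one hub satisfies
both; with several hubs the star splits and only the largest piece scores,
which destroys the effect. The activity prevalences themselves are
plausibility values (no time-budget table exists for this design), kept
fixed across the package.

What the generator does *not* emulate: temporal autocorrelation of
activities across periods, spatial movement, kinship structure, observer
error, and seasonal variation. Passing recovery tests therefore shows that
the pipeline detects the intended structure when it is present and seeded
into clean data — not that field data of this design would show it.

## Problem sizes and testing

The unit tests run the pipeline on reduced designs (typically 3–6 periods,
full 91-animal herd) where every stage is exercised but cheap; the
acceptance-style checks run the full 240-period design across three master
seeds (a run takes tens of seconds), verify the counting identities
240/1680/152 880, compare every index against brute-force oracles
(Floyd–Warshall distances, exhaustive geodesic enumeration, union-find
components, dense eigendecomposition) on hundreds of random graphs with
\(N \le 7\), and check the Spearman implementation against explicit midrank
construction to \(10^{-12}\). All randomness is seed-derived; two runs with
the same configuration are byte-identical.

## Known limitations

* Spearman p-values ignore the non-independence of vertex-cases from the
  same network (and of networks from the same period). A node-permutation /
  QAP-style null would be the principled alternative and is left as future
  work; with \(n\) in the tens of thousands the t-based p-values are best
  read as descriptive flags.
* Closeness and eigenvector conventions on fragmented graphs are choices,
  not mathematical necessities; both are documented above and the clustering
  variant is switchable.
* The generator's group-size law (shifted Poisson) is a modelling
  convenience; only the monotone effect of its mean matters to the tests.
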