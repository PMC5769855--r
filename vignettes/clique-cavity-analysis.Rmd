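---
title: "Cliques, cavities, and persistent homology of weighted networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cliques, cavities, and persistent homology of weighted networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cliquecavity)
```

## The model

A structural brain network is a weighted symmetric adjacency matrix **A**
on $n$ nodes (brain regions), with $w_{ij} \ge 0$ the density of white
matter streamlines between regions $i$ and $j$ and a zero diagonal. Two
mesoscale objects are extracted from it.

**Cliques.** A $k$-clique is a set of $k$ all-to-all connected nodes; any
subset of a clique is a clique (a *face*), and a clique contained in no
larger clique is *maximal*. Node participation $P_k(v)$ counts the maximal
$k$-cliques containing $v$, and $P(v) = \sum_k P_k(v)$. Cliques are read
off the network after thresholding it at an edge density $\rho$: the
$\lfloor \rho\, n(n-1)/2 \rfloor$ heaviest edges are retained, with the
denominator counting *all* unordered node pairs, so that density always
refers to the same scale regardless of how sparse the input is.

**Cavities.** The weight rank clique filtration turns **A** into a nested
sequence of binary graphs $G_0 \subset G_1 \subset \dots \subset G_{|E|}$
by adding one edge at a time in decreasing weight order; each step is
indexed by its edge density $\rho_i = i / (n(n-1)/2)$. On each $G_i$ we
take the flag (clique) complex — every $(k{+}1)$-clique becomes a
$k$-simplex — and compute homology with $\mathbb{Z}_2$ coefficients. A
$k$-cycle is a family of $(k{+}1)$-cliques whose $k$-faces each occur an
even number of times; two cycles are equivalent when they differ by a
boundary; a non-trivial equivalence class is a topological cavity. Each
cavity is summarised by the density at which its class first appears
($\rho_{birth}$), the density at which it is first triangulated shut
($\rho_{death}$), the lifetime $\rho_{death} - \rho_{birth}$, and the
death-to-birth ratio $\pi = \rho_{death}/\rho_{birth}$, which highlights
early-born, long-surviving cavities.

We restrict attention to dimensions 1 and 2. The dimension cap is a
parameter (`max_dim`) and can be raised at cost; in practice
higher-dimensional classes are rare in connectome-scale networks and the
simplex enumeration grows quickly with dimension.

## The persistence computation and its oracle

`persistent_homology()` enumerates all cliques of the final graph with up
to `max_dim + 2` nodes (via igraph's clique enumerator), stamps each with
the step at which its last edge arrives, and runs the standard
persistence column reduction over $\mathbb{Z}_2$ one boundary matrix at a
time, from the top dimension down, with clearing: a $d$-simplex paired as
a "low" in the $(d{+}1)$-boundary reduction is a known class birth, so its
own column is skipped one dimension down. Dimension-1 births are
identified separately by union-find (an edge is a birth exactly when it
closes a cycle). Classes never filled in are reported with
$\rho_{death} = \infty$; they arise whenever the input network is
incomplete, since absent edges are never added.

Correctness is not taken on faith. `betti_curves()` computes
$\beta_k(\rho)$ at every filtration step by a completely separate route —
incremental Gaussian elimination ranks of the boundary matrices,
$\beta_d = n_d - \mathrm{rank}\,\partial_d - \mathrm{rank}\,\partial_{d+1}$
— and the test suite checks, over hundreds of random filtrations, that the
number of alive bars equals the oracle's Betti number at every step, and
that the Euler characteristic computed from simplex counts equals the
alternating Betti sum (with the top dimension consistently truncated to
its boundary kernel). The acceptance script re-runs both checks on 200
random geometric filtrations of 6–10 nodes; these sizes keep the
exhaustive oracles exact and the whole check under a few minutes on one
CPU, while exercising every code path (births, finite and infinite
deaths, simultaneous same-step events).

### Numerical choices

- **Ties.** The filtration requires strictly decreasing weights. The
  default tie-break is deterministic: stable sort by decreasing weight,
  ties broken by lexicographic node-pair order. The stochastic
  alternative — adding independent uniform noise from $[0, 10^{-4}]$ to
  every positive weight (`add_tiebreak_noise()`, seeded) — is provided
  because persistence is stable: a perturbation smaller than the smallest
  weight gap cannot change the diagram, and a perturbation that only
  reorders ties moves birth/death densities by at most one step. A strict
  mode errors on duplicate weights instead.
- **Zero-persistence pairs.** With per-edge granularity, a single edge can
  both create and (via a clique arriving at the same step) kill a class.
  Such pairs carry no topological information at the step resolution, so
  the default diagram drops them; `drop_zero = FALSE` retains them.
- **Granularity.** Cliques are stamped by their latest edge; within a
  step, simplices are ordered by dimension and lexicographic node order,
  which is filtration-consistent (faces never follow cofaces).
- **Degenerate inputs.** Empty graphs give $\beta_0 = n$ and empty
  diagrams; complete graphs give contractible complexes (no bar survives
  at $\rho = 1$), which the tests assert for $n \le 10$.

## Minimal cycle representatives

For a dimension-1 class, the network is thresholded at the step
immediately preceding the birth edge (all strictly earlier edges), and
every minimum-length path between the birth edge's endpoints is recovered
by breadth-first search; each path plus the birth edge is a candidate
representative, kept after verifying it is closed and non-bounding at the
birth slice. "Minimal" means minimum node count (topological hop length);
minimum-total-weight representatives would be a reasonable alternative and
are deliberately not implemented. When several minimum-length paths arise
from different equivalence classes, all are recorded, each tagged with an
equivalence-class id — any of them could be the class generator. The graph
just before the birth step is used; including the birth edge itself would
change nothing, since a shortest path never uses the edge it is meant to
close.

For dimension 2, representatives are found by exhaustive search over node
subsets containing the birth triangle, in increasing size up to
`node_cap` (default 12): within each subset, the $\mathbb{Z}_2$ kernel of
the triangle boundary map restricted to the subset is enumerated, and
solutions containing the birth triangle, using every node of the subset,
and non-bounding in the full slice are returned. Exceeding the cap raises
a diagnostic error — never a silent truncation — so a pathological input
cannot masquerade as a clean result. The representative count cap
(default 100 per class) serves the same purpose.

## Weighted graph statistics

- **Communicability** $C = \exp(D^{-1/2} A D^{-1/2})$, $D =
  \mathrm{diag}(s_i)$, computed as an exact matrix exponential (never a
  truncated series). The strength normalisation makes $C$ invariant under
  global weight rescaling; an isolated node makes the normalisation
  undefined and is reported by name.
- **Weighted rich club** $\phi^w(k) = W_{>k} / \sum_{l=1}^{E_{>k}}
  w_l^{ranked}$, over all $k$ with a non-empty $>k$ subgraph (others are
  flagged undefined). The null ensemble rewires the binary graph by
  degree-preserving double-edge swaps (10 attempted swaps per edge,
  exposed as `swaps_per_edge`) and then reassigns the original weight
  multiset to the new edges by rank-matching the product of the
  endpoints' original strengths. Exact strength preservation under
  rewiring is over-constrained; this rank-matching scheme preserves the
  degree sequence exactly and the strength sequence approximately (rank
  correlation above 0.95 on 50-node geometric test networks), which is
  the property the test suite enforces. Significance per $k$ is a
  one-sample, one-sided t-test of the null sample against the observed
  value at $\alpha = 0.05$, with no multiple-comparison correction; a
  two-sample form is not applicable since the observed value is a single
  number.
- **Cores.** One iterative-pruning routine serves both decompositions: a
  node's k-core (s-core) level is the largest degree (strength) threshold
  it survives. s-core thresholds are scanned over the sorted observed
  strengths rather than a continuous grid — between two observed values
  the pruning outcome cannot change. The standard "at least $k$"
  convention is the default; a strict "greater than $k$" mode is provided
  for comparison with texts that phrase it that way.

## The minimally wired null model and synthetic data

The spatial null model places nodes at given 3D coordinates and links
every pair with weight $w_{ij} = 1/d(i,j)$, the inverse Euclidean
distance, then (typically) thresholds at the empirical density. Only
relative distances matter after rank filtration, so coordinate units are
arbitrary; the construction is invariant under rigid motions, which the
tests verify.

Because the imaging data behind a connectome study is rarely available,
the package treats synthetic generators as first-class:

- `planted_cavity_network()` assigns strictly decreasing integer weights
  by explicit rank so that a prescribed shell completes at a prescribed
  edge index and its killing edge arrives at another — births and deaths
  are exact by construction, not estimated. The bundled fixtures are the
  square (one 1-cavity at $\rho = 4/6 \to 5/6$), the pentagon (born
  $5/10$, shrunk by one chord, killed at $7/10$), and the octahedral
  sphere (one 2-cavity at $12/15 \to 13/15$).
- `random_geometric_network()` gives dense spatial networks with almost
  surely distinct weights.
- `perturb_scans()` emulates repeat scans of one subject: multiplicative
  log-normal weight jitter (log-sd 0.05 by default — small enough to
  preserve most of the rank order, as repeated measurements of the same
  anatomy should) plus optional Bernoulli edge deletions with matched
  weak insertions. No generative model of real inter-scan variability is
  claimed; this is the simplest mechanism that produces the two failure
  modes the matching heuristic must face (reordered filtrations and
  missing/spurious edges).

What the generators deliberately do **not** emulate: empirical streamline
weight distributions, region-size effects on edge weights, or spatial
autocorrelation of noise. Passing tests therefore demonstrate algorithmic
correctness on networks with planted ground truth, not that any particular
biological claim holds in real data.

## Cross-scan cavity matching

Whether "the same" cavity exists in another network is not well defined;
the package implements a two-part domain heuristic. Let $N_0, \dots, N_m$
be the node sets of the reference class's minimal representatives.

1. **Cycle present** (`rule1_nodes_form_cycle()`): the scan's induced
   subgraph on some $N_i$, filtered by its own edge ranks, carries
   precisely one non-trivial class of the reference dimension at some
   step. The subgraph's own density scale is used — the question is about
   the connection pattern among these nodes, not about the whole network.
2. **Similar cavity** (`rule2_similar_cavity()`): among scan classes of
   the reference dimension whose birth simplex contains a reference node,
   in increasing birth density: (a) a minimal generator of the scan class
   equals or is $\mathbb{Z}_2$-equivalent to a reference representative;
   (b, dimension 1) some cycle in the class at birth uses at least all
   but one node of some $N_i$, at most two extra nodes, with the $N_i$
   nodes in their original cyclic order — interpreted up to rotation and
   reflection, since an undirected cycle has no starting point or
   handedness; (c) (a) or (b) holds at some $\rho \in [\rho_{birth},
   \rho_{death})$. Subrule (c) is implemented by re-testing at every edge
   step in the interval; this is a superset of the steps at which the
   class's minimal representatives can change, hence equivalent to
   checking only those, and the fixtures are small enough that the
   simpler loop costs nothing.

The candidate filter is the procedure's documented false-negative mode: a
scan class whose birth edge avoids every reference node is never
examined. The package reproduces this behaviour (and tests it) rather
than "fixing" it, because the heuristic's value lies in being the stated,
conservative procedure. Subrule (b)'s cyclic-order condition is
undefined for 2-cycles, so dimension-2 matching uses subrules (a) and
(c)(a) only.

Matching requires **both** parts to call a cavity present in a scan.

## Pipeline, determinism, and parameters that matter

`run_full_analysis()` chains every stage from matrix files on disk,
writing delimited tables and a JSON manifest (parameters, seed, input and
output MD5 hashes). All randomness — tie-break noise, rich-club rewiring,
scan generation — flows from the single recorded seed, and two runs with
the same config are byte-identical, which the acceptance checks assert
via file hashes.

| parameter | default | meaning |
|---|---|---|
| `rho` | 0.25 | edge density threshold for clique analyses (fraction of all node pairs) |
| `max_dim` | 2 | highest homology dimension computed |
| `noise_epsilon` | 1e-4 | tie-break noise bound (weight units) |
| `n_null` | 1000 | rewired nulls for the rich club |
| `swaps_per_edge` | 10 | attempted double-edge swaps per edge when rewiring |
| `node_cap` / `cap` | 12 / 100 | 2-cycle search and representative-count guards |

Where a group of repeat networks is analysed, the default order is
average-then-threshold: the element-wise mean matrix (zeros included) is
thresholded once, rather than thresholding each network first. Both
orders are expressible with the exported functions; averaging first is the
default because the thresholded consensus network is the object the
clique and cavity analyses describe.

Persistence is computed on the full weighted network by default, so that
late-arriving weak edges can still kill classes; pass a thresholded
network to reproduce a thresholded run, at the cost of more infinite
bars.

## Known limitations

- The reduction is exact but written for desk-scale networks (tens to a
  few hundred nodes); no cohomology, zigzag, or approximate/landmark
  computation is attempted, and dimension-0 classes are reported only
  through $\beta_0$ curves.
- The rich-club null's strength preservation is approximate by
  construction; the swap count and the scheme are exposed and documented
  rather than hidden.
- The 2-cycle search is exponential in the subset size and guarded by
  caps; it is meant for the handful of long-lived classes one actually
  inspects, as is the matching heuristic.
- Matching can miss genuinely similar cavities (the birth-edge filter
  above) and is a per-class decision, not a globally optimal
  correspondence between two diagrams.
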