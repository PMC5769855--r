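# cliquecavity

Clique and cavity analysis of weighted structural brain networks in R.

Structural connectomes — brain regions linked by white-matter streamline
counts — contain two complementary kinds of mesoscale architecture. Densely
interconnected region sets (*cliques*) are candidate local processing
units, while *topological cavities* — loops and shells of cliques that
enclose a void where strong connections are conspicuously absent — are
candidate routes for segregated, parallel information flow. `cliquecavity`
is for network neuroscientists (and anyone analysing weighted, spatially
embedded networks) who want to quantify both, compare them to a
wiring-cost-minimising spatial null model, and test whether a cavity found
in one network recurs across repeated scans.

## What it computes

Given a weighted symmetric adjacency matrix **A** on *n* nodes:

- **Weight rank clique filtration.** Edges are added one at a time in
  decreasing weight order, giving nested binary graphs
  G₀ ⊂ G₁ ⊂ … ⊂ G|E|, each indexed by edge density ρ = i / (n(n−1)/2).
- **Persistent homology over Z₂** of the flag (clique) complexes, in
  dimensions 1–2: each topological cavity is reported with its birth and
  death densities (ρ_birth, ρ_death), lifetime ρ_death − ρ_birth, and
  death-to-birth ratio π = ρ_death/ρ_birth, via standard boundary-matrix
  column reduction with clearing. An independent Gaussian-elimination rank
  oracle (`betti_curves()`) cross-checks the diagram.
- **Minimal cycle representatives** of any class at its birth density: all
  minimum-node cycles through the birth edge (breadth-first search over
  shortest paths, dimension 1) or an exhaustive capped subset search
  (dimension 2), each verified closed and non-bounding.
- **Maximal cliques and node participation** P_k(v), the number of maximal
  k-cliques containing node v, with per-cognitive-system aggregation and
  real-minus-null difference tables.
- **Weighted graph statistics**: communicability
  C = exp(D^{−1/2} A D^{−1/2}), the weighted rich-club coefficient
  φ^w(k) = W_{>k} / Σ_{l≤E_{>k}} w_l^ranked with degree-preserving rewired
  nulls and one-sided t-tests, and k-core / s-core decompositions.
- **Minimally wired null model**: the complete network with
  w_ij = 1/d(i,j) on the node coordinates, thresholded at the empirical
  density.
- **Cross-scan cavity matching**: the two-part heuristic (cycle present on
  the reference nodes; similar cavity via subrules 2a / 2b / 2c) for
  deciding whether a reference cavity recurs in another scan.
- **Synthetic generators** with exact ground truth: planted-cavity
  networks, random geometric networks, and perturbed scan ensembles — so
  the whole pipeline is testable without any imaging data.

## Worked example

A planted octahedral shell (6 nodes, 12 edges, 8 triangles) with one
antipodal diagonal added afterwards encloses exactly one 2-dimensional
cavity, born when the shell's last edge arrives (ρ = 12/15 = 0.8) and
killed by the diagonal (ρ = 13/15 ≈ 0.867):

```r
library(cliquecavity)

po   <- planted_octahedron()
filt <- build_filtration(po$network)
dgm  <- persistent_homology(filt)
tidy(dgm)
#> # A tibble: 1 × 8
#>   dimension birth_step death_step rho_birth rho_death lifetime    pi
#>       <int>      <int>      <int>     <dbl>     <dbl>    <dbl> <dbl>
#> 1         2         12         13       0.8     0.867   0.0667  1.08

reps <- minimal_2cycles(filt, dgm[dgm$dimension == 2, ][1, ])
reps[, c("dimension", "n_nodes", "class_id")]
#> # A tibble: 1 × 3
#>   dimension n_nodes class_id
#>       <int>   <int>    <int>
#> 1         2       6        1
```

The recovered minimal representative is the full shell: 6 nodes, 8
triangles, one equivalence class. Matching it against three noisy repeat
"scans" of the same network finds the same cavity in each, by generator
equivalence (subrule *a*) at the same birth density:

```r
scans <- perturb_scans(po$network, n_scans = 3, weight_jitter = 0.05, seed = 7)
match_cavities(reps, scans)
#> # A tibble: 3 × 10
#>   scan  dimension rule1 rule1_first_rho rule2 subrule rule2_rho rho_birth
#>   <chr>     <int> <lgl>           <dbl> <lgl> <chr>       <dbl>     <dbl>
#> 1 scan1         2 TRUE              0.8 TRUE  a             0.8       0.8
#> 2 scan2         2 TRUE              0.8 TRUE  a             0.8       0.8
#> 3 scan3         2 TRUE              0.8 TRUE  a             0.8       0.8
```

`autoplot(dgm)` draws the persistence diagram;
`run_full_analysis(run_config(...))` executes the entire pipeline (load /
average / threshold → cliques & statistics → persistence → minimal cycles
→ null model → matching) from matrix files on disk and writes delimited
tables plus a JSON manifest of parameters, seeds and file hashes.

## Package layout

- `R/network.R` — `weighted_network` class, file I/O, density thresholding,
  tie-breaking, group averaging
- `R/synthetic.R` — planted-cavity, geometric, and scan-ensemble generators
- `R/cliques.R`, `R/graph-stats.R` — maximal cliques, participation,
  communicability, rich club, cores
- `R/filtration.R`, `R/persistence.R`, `R/gf2.R` — filtration, flag
  complex, Z₂ reduction, rank oracle
- `R/cycles.R`, `R/matching.R` — minimal representatives, equivalence,
  cross-scan matching
- `R/pipeline.R` — end-to-end orchestration
- `vignettes/clique-cavity-analysis.Rmd` — methods and design notes
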