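# nichegraph

Bi-level graph analysis of spatial single-cell cohorts: discover recurring
tumor-microenvironment (TME) patterns in multiplexed imaging data (IMC,
CODEX, MIBI), stratify patients by the patterns their tissues contain, and
relate the resulting subgroups to survival. The package is aimed at
computational pathology and spatial-omics analysts who have per-cell tables
(coordinates + phenotype per cell, from published segmentation/phenotyping
pipelines) and per-patient clinical tables.

## The model

**Cellular graph.** Each patient's tissue is a weighted complete graph over
its cells. For cells *v<sub>i</sub>*, *v<sub>j</sub>* in the same image,

&nbsp;&nbsp;&nbsp;&nbsp;*w<sub>ij</sub>* = exp(−α · d(*v<sub>i</sub>*, *v<sub>j</sub>*)²),

with d the Euclidean centroid distance in μm and α = 0.01 by default, so
cells under 3 μm apart have weights above 0.9 and cells beyond 22 μm fall
below 0.01. Self-loops give the adjacency **A** a unit diagonal; multiple
cores of one patient enter as disconnected components.

**Soft-WL subtree kernel.** Every cell roots a depth-*h* subtree summarised
by a graph-convolution embedding: starting from the one-hot phenotype
encoding **x**(0), *h* sweeps of **x** ← **A x** give **x**(*h*) — row *i*
of **A**<sup>*h*</sup>**X**(0). Instead of requiring isomorphic subtrees
(hopeless on weighted complete graphs), embeddings pooled over the
discovery cohort are clustered PhenoGraph-style (exact Euclidean k-NN graph,
k = 100; Jaccard reweighting of neighbor sets; Louvain communities). Each
cluster is a **TME pattern** with signature S(c) = the centroid of its
member embeddings. A patient is then the histogram φ(G) of its patterns,
and inter-patient similarity is the cosine kernel

&nbsp;&nbsp;&nbsp;&nbsp;κ(G<sub>i</sub>, G<sub>j</sub>) = ⟨φ(G<sub>i</sub>), φ(G<sub>j</sub>)⟩ / (‖φ(G<sub>i</sub>)‖₂ ‖φ(G<sub>j</sub>)‖₂) ∈ [0, 1].

**Population graph.** Each patient keeps its k★ = 30 most similar peers;
edges are reweighted by the intersection-over-union of the two
neighbor sets, and Louvain communities of this graph are the patient
subgroups. Per subgroup the package reports Kaplan-Meier curves, the
G-sample log-rank test, Cox hazard ratios (subgroup vs rest, Efron ties,
likelihood-ratio p), and characteristic patterns — those whose
Hodges-Lehmann statistic (median of all pairwise in-vs-out proportion
differences) strictly exceeds 50% of the subgroup maximum. External cohorts
are projected onto a fitted model at three levels: cells → phenotypes (by
nearest shared-antigen centroid), subtrees → patterns (nearest signature),
patients → subgroups (similarity-weighted 3-NN vote).

Comparator representations (phenotype abundance, pairwise phenotype
proximity, niche-category abundance, classic WL subtree kernels on
binarized graphs, or any external per-patient embedding) plug into the same
population-graph and survival machinery.

## Worked example

The package ships a synthetic-cohort generator that plants niche
archetypes, subgroup mixture profiles, and subgroup-linked survival, so the
whole pipeline can be exercised without any download:

```r
library(nichegraph)

sim <- simulate_cohort(sim_config(n_patients = 24, niches_per_patient = 4,
                                  cells_per_niche = 40, background_rate = 5,
                                  image_size = 700, seed = 42))
fit <- softwl_fit(sim$cells, clinical = sim$clinical,
                  vocabulary = sim$vocabulary,
                  config = run_config(min_cells = 1, k_pheno = 60,
                                      k_star = 8, random_seed = 1))
fit
#> <softwl_fit>
#>   patients:   24
#>   phenotypes: 6
#>   patterns:   16
#>   subgroups:  3  (modularity 0.419)
#>   log-rank:   chi2 = 1.525, df = 2, p = 0.467
```

16 patterns were discovered and the 24 patients fall into 3 subgroups; at
this toy size the subgroup survival difference is not significant
(log-rank p = 0.467). Per-subgroup hazard ratios (each subgroup against the
rest):

```r
fit$survival$cox
#> # A tibble: 3 × 8
#>   subgroup     n n_events    hr conf.low conf.high p.value note
#>      <int> <int>    <int> <dbl>    <dbl>     <dbl>   <dbl> <chr>
#> 1        1    10        8 1.87     0.683      5.10   0.226 <NA>
#> 2        2     8        5 0.657    0.225      1.91   0.431 <NA>
#> 3        3     6        3 0.725    0.200      2.63   0.614 <NA>
```

Characteristic patterns per subgroup (Hodges-Lehmann statistic above half
the subgroup maximum):

```r
dplyr::filter(fit$characteristic, selected) |> head(3)
#> # A tibble: 3 × 6
#>   subgroup pattern     hl max_hl threshold selected
#>      <int> <chr>    <dbl>  <dbl>     <dbl> <lgl>
#> 1        1 P1      0.186   0.186    0.0932 TRUE
#> 2        1 P7      0.153   0.186    0.0932 TRUE
#> 3        1 P10     0.0992  0.186    0.0932 TRUE
```

`tidy(fit)` returns per-patient subgroups and pattern proportions,
`glance(fit)` a one-row model summary, `autoplot(fit$model)` the signature
heatmap, `autoplot(fit$population)` the population graph, and
`plot_km(fit$survival$km)` the survival curves. `softwl_map(fit, cells2)`
projects a second cohort onto the fitted model; `comparator_fit()` runs the
alternative patient representations. A command-line front-end with
`simulate` / `fit` / `map` / `compare` subcommands is installed at
`system.file("cli", "nichegraph.R", package = "nichegraph")`.

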