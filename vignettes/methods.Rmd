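---
title: "Methods: bi-level graph analysis of spatial single-cell cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bi-level graph analysis of spatial single-cell cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how the package's model works, what its tunable
parameters mean, and the numerical and design choices made where more than
one defensible option existed. It states no empirical result beyond what
the test suite and `scripts/acceptance.R` themselves compute.

## The two graph levels

**Cell level.** A patient's tissue is modelled as a weighted complete graph
per image: `w_ij = exp(-alpha * d_ij^2)` with `d_ij` the Euclidean distance
between cell centroids in micrometers. Coordinates are used as provided, in
an arbitrary per-image frame — distances are translation/rotation invariant
and no rescaling is applied. Images of one patient are disconnected
components (cross-image weights exactly 0); self-loops set the adjacency
diagonal to 1. The assumption is that cell-cell interaction strength decays
smoothly and isotropically with distance; the Gaussian form concentrates
essentially all weight within ~sqrt(ln(100)/alpha) ≈ 21 μm of a cell at the
default `alpha = 0.01` 1/μm².

**Subtree embeddings.** Each cell roots a depth-`h` subtree whose levels
are successive neighborhoods. On weighted complete graphs isomorphic
subtrees are vanishingly rare, so subtrees are compared through embeddings:
`h` sweeps of `x <- A x` starting from one-hot phenotypes, equivalently
rows of `A^h X(0)`. The two forms are asserted equal to 1e-9 on random
graphs in the tests; the implementation uses the matrix form. Row sums of
the embedding equal row sums of `A^h` (mass conservation), which the tests
also assert. The threshold `tau` (default 0.01) only delineates the
*reported* neighborhood (`(A^h)_ij > tau`, strictly) for interpretability —
sizes and radii per cell — and never alters embedding values.

**Pattern discovery.** Embeddings from the entire discovery cohort are
pooled into one clustering, PhenoGraph-style: exact Euclidean k-NN
(`k_pheno = 100`; neighbor ties broken by distance then row index), Jaccard
reweighting of each k-NN edge by the overlap of the endpoints' neighbor
sets (self excluded), then Louvain at resolution 1 under a fixed seed.
Embeddings are clustered unnormalized: signatures are arithmetic means of
raw member embeddings, so normalizing rows first would make the signature
inconsistent with its members (an optional L1 flag exists, default off).
Clustering operates on the final-depth embeddings only, not concatenations
across depths.

The number of patterns `C` is *emergent*. Louvain maximizes modularity, and
on a k-NN graph of a broad, dense cluster, modularity is genuinely higher
for a partition of that cluster into density strata than for the cluster
kept whole. Two practical consequences, both visible in the tests:

* when `k_pheno` is comparable to the size of a well-separated cluster,
  the within-cluster k-NN graph is near-complete and the cluster is
  recovered exactly;
* when clusters are much larger than `k_pheno` (the realistic regime for a
  cohort pooling tens of thousands of subtrees), each archetype is refined
  into several almost perfectly pure patterns. Recovery of planted
  archetypes is therefore judged at archetype granularity:
  `align_patterns_to_archetypes()` assigns each pattern to the archetype
  whose mixture is closest in cosine to the pattern's signature (using only
  signatures, never per-cell truth), and the adjusted Rand index is
  computed on the induced cell partition. Requiring the raw Louvain
  partition to match a three-way planted labelling would contradict the
  modularity objective the method itself prescribes.

**Patient level.** Pattern histograms (one count per rooted subtree, so a
patient's histogram sums to its cell count) define the cosine kernel, with
unit self-similarity guaranteed (identical histograms short-circuit to
exactly 1, avoiding a 1-ulp wobble from the norm product). The population
graph keeps each patient's `k_star = 30` most similar peers (self excluded
— including self would add a constant to every overlap and only compress
the IoU range; the choice is flagged here because either convention is
defensible), reweights all patient pairs by the IoU of their neighbor
sets, drops zero-IoU pairs, and detects Louvain communities under a fixed
seed. Communities are relabelled by descending size (ties: smallest patient
index) so subgroup numbering is stable across reruns; modularity is
reported so near-ties between partitions are visible.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `alpha` | 0.01 | 1/μm² | edge-weight decay; 0.9 weight at 3 μm, 0.01 at ~21.5 μm |
| `h` | 2 | sweeps | subtree depth; deeper mixes larger neighborhoods |
| `tau` | 0.01 | influence | neighborhood reporting cutoff on `A^h` entries |
| `k_pheno` | 100 | neighbors | granularity of pattern discovery |
| `k_star` | 30 | neighbors | population-graph neighborhood size |
| `min_cells` | 500 | cells | patient inclusion; strictly fewer is excluded, pooled over a patient's images |
| `positivity_threshold` | 0.01 | proportion | pattern-positive iff proportion >= threshold |
| `hl_fraction` | 0.5 | fraction | characteristic iff statistic > fraction × subgroup max (strict) |
| `knn_map` | 3 | neighbors | external-patient subgroup vote |
| `sparsify_epsilon` | 0 | weight | optional cutoff; 0 keeps the exact complete graph |

Strictness conventions: binarization for the classic WL comparator keeps an
edge iff `w >= threshold` (so the largest surviving integer distance at the
defaults is 21 μm, since exp(-0.01·21²) ≈ 0.0122 ≥ 0.01 > exp(-0.01·22²));
neighborhood membership is strict (`> tau`); the characteristic-pattern
rule is strict (`>` half the max, boundary equality excluded); pattern
positivity is inclusive (`>=` 1%). Argmin ties (nearest centroid, nearest
signature) break to the lower index and are logged; a tied subgroup vote
falls back to the single most similar neighbor.

## Statistics

Survival estimation is delegated to the `survival` package behind the
package's own interface, validated against hand-computed product-limit and
log-rank examples so the backend could be swapped: Kaplan-Meier per group,
G-sample log-rank (`survdiff`, chi-square with G−1 df), and one Cox fit per
subgroup against the rest with Efron tie handling (the convention is
recorded in the output; the data sources this method targets do not state
one), Wald 95% CIs, and likelihood-ratio p-values. A subgroup containing
every patient has no baseline and is an error; a subgroup with no events on
one side is reported as non-estimable rather than crashing. All p-values
are two-sided and **no multiple-testing correction is applied anywhere** —
reports are per-pattern/per-subgroup descriptive screens, and downstream
users should correct according to their own inference goals.

The Hodges-Lehmann statistic is the median of all `|in| × |out|` pairwise
differences of per-patient pattern proportions (even grids average the two
central order statistics); the tests check it against full-grid enumeration
up to 50×50. Clinical associations use Spearman correlations between
subgroup indicators and one-hot clinical indicators (constant vectors
reported as missing) and Mann-Whitney U for proportion-vs-category
comparisons.

Pattern categories: signature mass is summed per phenotype category
(tumor/immune/stromal); the pattern takes the dominant category when its
share reaches `interface_cutoff = 0.5` (boundary inclusive), otherwise it
is an interface niche. The 0.5 rule is the package's own quantitative
reading of "mixed"; it is configurable. Merging of near-duplicate patterns
is deliberately left to the user (a curation step), not automated.

## The synthetic generator

`simulate_cohort()` emulates exactly the structure the method assumes:
recurring local niches (isotropic Gaussian clouds of cells, sd =
radius/2, phenotypes drawn from archetype mixtures), patient subgroups that
differ only in archetype mixture proportions, uniform background cells, and
subgroup-linked exponential survival with an independent exponential
censoring clock (the simplest model with a closed-form check: the Cox
hazard ratio for a binary covariate tends to the event-rate ratio).
Defaults — 60 patients, 3 balanced subgroups, 3 archetypes at 90%
category purity, subgroup profiles 70/15/15, 8 niches × 70 cells at 50 μm
radius in a 1 mm² image, ~15 background cells, hazards 0.08/0.04/0.02 per
month with censoring rate 0.015 — give patients that clear the 500-cell
inclusion filter and produce cell densities (centroid spacing ~7-10 μm in
niches) in the range of dense tissue regions.

What it does **not** emulate: segmentation errors, antigen spillover,
spatially varying background, phenotype gradients within a niche,
non-proportional hazards, or informative censoring. Passing the
planted-recovery tests therefore shows the pipeline is correct and
sensitive under its own assumptions, not that it is robust to the
artifacts of real multiplexed images.

Expression columns (optional, 4 antigens by default) place each phenotype
at a well-separated centroid with Gaussian noise, enough to exercise the
shared-antigen phenotype mapping; they are not a model of real antibody
panels.

## Problem sizes and runtimes

The reference recovery experiment uses the generator defaults (60 patients,
~34,000 pooled subtrees, `k_pheno = 100`, `k_star = 30`) plus a second
independently seeded cohort mapped onto the fitted model; it completes in a
few minutes on one CPU, and the smaller fixtures used by the unit tests
(6-18 patients, ~25 cells per niche) run in seconds. These sizes were
chosen as the smallest at which all three planted structures (archetypes,
subgroups, held-out mapping) are cleanly identifiable; nothing in the
implementation depends on them. The k-NN search is exact (blocked distance
computation with partial selection), so results carry no approximate-index
nondeterminism; Louvain is seeded and its input edge lists are built in a
deterministic order.

## Known limitations

* Louvain's resolution-1 modularity fixes the granularity of both
  clustering levels; the pattern count is data-dependent and should not be
  compared across cohorts of very different size.
* The population-graph IoU step assumes `k_star` is meaningfully smaller
  than the cohort; for cohorts near `k_star` the neighbor sets saturate and
  community structure washes out (the fit warns and reduces `k_star` to
  n−1 when necessary).
* Cross-cohort phenotype mapping uses raw expression with Euclidean
  distance (an optional z-scaling flag exists, default off); no
  batch-effect correction is attempted.
* Survival analyses are univariate by design (subgroup vs rest); covariate
  adjustment is out of scope.
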