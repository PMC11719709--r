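---
title: "Comparative developmental trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative developmental trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

devoalign reconstructs developmental trajectories from time-series
single-cell RNA-seq of two related species and compares them: which lineage
does each early cell feed, how do the two species' developmental clocks map
onto one another, and which regulator–target relationships are conserved,
temporally or spatially shifted, lost, or newly gained. The package couples
an optimal-transport trajectory model with an exact earth-mover-distance
time alignment and a cell-level co-expression classifier, and ships a
two-species embryo simulator with full ground truth so every step can be
scored against what actually generated the data.

This vignette is the methods account: the models, the parameters that
matter, what the simulator does and does not emulate, and the numerical
choices inside the solvers.

# Trajectory model: unbalanced entropic optimal transport

Cells sampled at consecutive time points $t$ and $t{+}1$ are linked by a
coupling $\gamma \in \mathbb{R}_{\ge 0}^{n_t \times n_{t+1}}$ minimizing

$$
\langle C, \gamma\rangle \;-\; \varepsilon H(\gamma)
\;+\; \lambda_1\,\mathrm{KL}(\gamma \mathbf{1} \,\|\, a)
\;+\; \lambda_2\,\mathrm{KL}(\gamma^\top \mathbf{1} \,\|\, b),
$$

where $C_{ij}$ is squared Euclidean distance in the per-species PCA
embedding, $H(\gamma) = -\sum_{ij} \gamma_{ij}(\log\gamma_{ij} - 1)$, and
the KL penalties softly tie the coupling's marginals to prescribed source
and target weights $a, b$. Marginals are soft because embryos grow and
lineages expand at different rates: a proliferating cell should export more
mass than its share of the source distribution.

The solver is generalized Sinkhorn scaling on $K = e^{-C/\varepsilon}$:

$$
u \leftarrow \left(\frac{a}{Kv}\right)^{\lambda_1/(\lambda_1+\varepsilon)},
\qquad
v \leftarrow \left(\frac{b}{K^\top u}\right)^{\lambda_2/(\lambda_2+\varepsilon)},
\qquad \gamma = \mathrm{diag}(u)\, K\, \mathrm{diag}(v).
$$

Parameters, with units and defaults (`pipeline_config()`):

* `epsilon = 0.05` — entropic regularization, in units of squared embedding
  distance. Small enough that couplings are near-deterministic for
  well-separated populations, large enough that the scaling iteration is
  stable in double precision at these cost scales.
* `lambda1 = 1` — source-marginal penalty. Deliberately loose: this is the
  slack through which differential proliferation is expressed.
* `lambda2 = 50` — target-marginal penalty. Tight: every observed cell at
  $t{+}1$ must be accounted for; descendants do not go missing.
* `growth_iters = 20` — outer growth-learning iterations (below).

`solve_unbalanced_ot()` iterates to `tol = 1e-9` on the scaling change
(`max_iter = 10000`) and warm-starts from previous scalings when available,
which makes the 20 outer iterations cheap after the first.

## Growth-rate learning

Per-cell growth rates $g_i$ (offspring per hour) are learned by alternating
transport with a multiplicative update, initialized at the population-level
rate $(N_{t+1}/N_t)^{1/\Delta t}$. Each round sets the source marginal
$a \propto g^{\Delta t}$ scaled so $\sum a = N_{t+1}/N_t$, solves the
transport problem, and re-estimates
$g_i \leftarrow \big((\gamma\mathbf{1})_i / \bar a\big)^{1/\Delta t}
(N_{t+1}/N_t)^{1/\Delta t}$: a cell exporting more mass than average is
growing faster than average. A design point worth stating explicitly: the
*target* marginal is also scaled to the total ratio,
$b = (N_{t+1}/N_t)/n_{t+1}$ per cell, so that the coupling's total mass
reflects the expansion rather than being pinned back to 1 by the tight
$\lambda_2$ penalty. With both marginals carrying the expansion, learned
rates recover simulated exponential growth (the transport property tests
check a doubling population yields $\sum\gamma \approx 2$ and
$g \approx \sqrt{2}$ per hour over a 2 h interval).

## Fate probabilities, commitment views, lineage trees

Couplings are row-normalized into Markov transition matrices and chained
(`compose_maps()`) from any early time point to the final one. Summing the
composed transition probabilities over the cells of each terminal lineage
gives each early cell a probability distribution over fates
(`fate_probabilities()`); rows sum to 1 by construction and cells whose
row mass underflows are flagged rather than silently renormalized.

`triangle_projection()` renders two competing fates barycentrically with
"other" as the third vertex; a cell is called committed when its top fate
probability exceeds `fate_threshold = 0.7` — beyond a 2:1 margin over all
alternatives combined.

`build_lineage_graph()` aggregates fate flows between cluster–time-point
nodes. Nodes with fewer than `tree_min_cells = 10` cells are dropped
(probability estimates over fewer cells are noise), and edges carrying less
than `tree_edge_cutoff = 0.15` of their source node's outgoing mass are
pruned; surviving edge weights are renormalized. `graph_edge_f1()` scores a
predicted graph against the simulator's generating tree at edge level.

# Cross-species time alignment by exact earth mover distance

Both species are restricted to 1:1 orthologs and embedded in one shared
gene space: the pooled, per-gene standardized cells-by-genes matrix is
decomposed by SVD and both species' cells are projected on the same top-$k$
right singular vectors. This "shared directions" construction guarantees
two properties the tests rely on: identical datasets land on identical
coordinates, and a common permutation of the gene rows leaves coordinates
unchanged.

For each terminal lineage, the cells of species A at time $s$ and species B
at time $t$ — weighted by their fate probability toward that lineage,
renormalized within species and time point — form two weighted point
clouds, compared by exact earth mover distance: the unregularized optimal
transport cost under the Euclidean ground metric. Each species-A time point
is paired with the species-B time point of minimal EMD (ties broken toward
the earliest B time point, so a flat valley never inflates an offset), and
the per-lineage offset distribution summarizes heterochrony.

The EMD is exact, not entropically smoothed, because the alignment signal
is a difference between nearby EMD values; regularization bias of order
$\varepsilon\log n$ would be comparable to the signal. The solver
(`src/emd.cpp`) is a transportation simplex: a least-cost greedy initial
solution completed to a spanning-tree basis (union-find, zero-flow basics
for degenerate rows), dual variables by traversal of the basis tree,
most-negative reduced-cost pricing, and leaving-arc selection along the
unique basis cycle. Reduced-cost tolerance is $10^{-12}$ relative to the
cost scale. Clouds larger than `max_points` are down-sampled
weight-proportionally under a fixed seed before the solve; the pipeline
uses `max_points = 400`, which keeps a full 4-lineage, 6-time-point
alignment around half a minute on one core while leaving the median-offset
estimates unchanged relative to larger caps.

One numerical point cost a debugging session and is worth recording: the
pairwise-distance matrix is computed with the direct
subtract-then-square formula (`stats::dist`), not the expanded
$\|x\|^2 + \|y\|^2 - 2x^\top y$ form. The expanded form leaves
cancellation residue of order $10^{-16}\|x\|^2$ for coincident points,
which the square root amplifies to spurious distances of order $10^{-8}$ —
enough to make `emd(X, X)` visibly nonzero.

# Co-expression and interaction evolution

All co-expression calls are made in raw UMI space, where the detection
semantics are unambiguous: a cell co-expresses a regulator–target pair when
both genes have $\ge 1$ UMI; co-expression is moderate-to-high when both
have $\ge 2$ UMIs. `coexpression_timecourse()` tallies these per time
point; `coexpression_cluster_counts()` tallies co-expressing cells per
cluster.

`classify_interaction()` is a decision cascade over the two species'
profiles, ordered so that the cheap, high-confidence calls come first:

1. **indeterminate** — fewer than `min_expressing_cells = 20` cells express
   either gene in either species: no power to call anything.
2. **lost** — species A has co-expression signal, species B has no
   moderate-to-high co-expressing cell anywhere and at most
   `max_stray_low_cells = 2` low ones; both genes individually expressed in
   B. The interaction is gone, not the genes.
3. **novel** — the mirror image.
4. **shifted_temporal** — both species have signal but co-expression onset
   (first time point with proportion $\ge$ `min_signal_prop = 0.005`)
   differs by at least `min_shift_hours = 4` after discounting any known
   global offset between the species' clocks (`global_offset_hours`, e.g.
   an alignment-estimated heterochrony): a pair-specific shift, not the
   whole embryo running late.
5. **shifted_spatial** — onsets agree but the distribution of co-expressing
   cells over homolog-mapped clusters overlaps by less than
   `min_cluster_overlap = 0.5` (overlap = $\sum_c \min(f^A_c, f^B_c)$ over
   shared cluster labels).
6. **conserved** — otherwise.

Every call returns its evidence (onsets, counts, overlap) so a borderline
label can be audited.

# The synthetic two-species embryo

`simulate_two_species()` generates both species from one configuration:

* a branching lineage tree (default: root splits into ectoderm and
  mesendoderm at 7 hpf; mesendoderm into endoderm and mesoderm at 10 hpf;
  mesoderm into skeletogenic and pigment at 13 hpf) with equal mass splits
  at branch events and exponential growth (`growth_rates = 0.15`/h);
* lineage expression programs of `n_program_genes = 10` genes each,
  switched on by a logistic gate
  $1/(1 + e^{-k(t - t_\mathrm{on})})$ with `gate_steepness` $k = 4$/h — a
  sharp but not discontinuous onset, so onset times remain identifiable at
  3 h sampling spacing;
* a species-B specification delay `onset_delay_B = 3` h added to every
  non-root program onset — the engineered heterochrony the alignment must
  recover;
* injected regulator–target interactions with per-pair status in species B
  (`conserved`, `lost`, `shifted:+Δ`, `novel`), amplitude
  `amp_interaction = 4` over a lognormal baseline, zero baseline leak, and
  (by default) an independent secondary expression domain for each target
  in a disjoint terminal lineage — so a "lost" interaction leaves both
  genes individually expressed, and loss must be read from co-occurrence,
  not from presence;
* measurement noise: negative binomial counts (`nb_dispersion = 2`),
  independent dropout (`dropout_rate = 0.15`), and lognormal per-cell depth
  (`mean_depth_umis = 1200`, `depth_sigma = 0.35`).

These defaults are the study conditions for every headline analysis; they
are chosen once as a realistic mid-density embryo time course and the
tests are run against them as-is.

What the simulator does **not** emulate — and hence what passing tests do
not establish about real data: ambient RNA and doublets; batch and
technology effects between the two species' protocols; continuous
(non-gated) expression dynamics and partial, biased ortholog maps;
cell-cycle structure; and spatial context beyond the discrete lineage
labels. Results on real embryos additionally depend on preprocessing
choices the simulator sidesteps.

## Experiment designs used in the headline analyses

Two analyses deliberately set `onset_delay_B = 0`:

* **Lineage-tree recovery** compares inferred trees against lineage labels
  that are defined by the branching schedule, not by expression. Under a
  global delay, species B's transcriptome at a sampled time point lags its
  labels, and the scored mismatch reflects that label/transcriptome offset
  rather than the tree builder. Zero delay isolates the step being scored.
* **Interaction-evolution recovery** injects `shifted:+6` pairs. With a
  global 3 h delay on top, the injected shift and the species-wide shift
  would be confounded; at zero delay every measured shift is attributable
  to the interaction. When a global offset does exist, the classifier
  accepts it as `global_offset_hours` and discounts it — the time-alignment
  analysis is the natural source of that estimate.

The time-alignment analysis itself keeps the default `onset_delay_B = 3`:
the delay is there precisely to be recovered.

## Problem sizes

The package-default analyses use 6 time points per species, 300 cells per
time point, 200 genes (interaction-evolution: 500 cells per time point, 5
time points for tree recovery). These sizes keep each full analysis between
seconds and about a minute on one core while leaving every recovered
quantity (tree F1, alignment offsets, interaction labels) stable across
seeds.

# Numerical and design notes

* **Degenerate inputs.** Zero-depth cells are an error in normalization,
  not a silent NaN. Empty point clouds are an error in `emd()`. Transport
  rows that lose all mass under composition are flagged
  (`zero_mass_rows`), never renormalized. Cluster labels absent from the
  homolog map cause a warning and a flagged, conservative call.
* **Tie-breaks.** Variable-gene selection breaks variance ties
  lexicographically by gene id; alignment ties go to the earliest species-B
  time point; PCA and the joint embedding fix signs by making the dominant
  loading of each component positive. All three make reruns bit-identical.
* **Determinism.** Every stochastic step takes an explicit seed
  (simulation, clustering, EMD down-sampling); `run_pipeline()` writes a
  manifest with per-output md5 checksums, and repeated runs produce
  byte-identical outputs.
* **Interface.** The pipeline is exposed as `run_pipeline()` plus the
  numbered narrative scripts under `analysis/`, not as a shell CLI: the
  intended users drive analyses from R, and each script is a thin driver
  over exported functions, so every step stays independently callable and
  testable.

# Known limitations

* Fate probabilities inherit optimal transport's core assumption that
  expression change between consecutive samples is locally small relative
  to inter-lineage distances; convergent differentiation violates it.
* The joint embedding is a shared linear basis; it aligns species whose
  ortholog expression spaces differ by rotation/scaling, not by nonlinear
  distortion.
* EMD down-sampling above `max_points` introduces sampling noise into
  individual matrix entries (not into which time point is the argmin, at
  the sizes used here).
* The interaction classifier is a rule cascade with interpretable
  thresholds, not a calibrated statistical test; its error rates are
  characterized on the simulator, not on real data.
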