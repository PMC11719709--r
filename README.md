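# devoalign

Cross-species developmental trajectory alignment by optimal transport.

## The problem

Time-series single-cell RNA-seq of two related embryos gives snapshots of
cell states, but not the links between them: which lineage will an early
blastula cell feed, do the two species run the same developmental program
on different clocks, and which regulator–target relationships have been
conserved, retimed, relocated, lost, or newly gained since the species
diverged? devoalign is for developmental and evolutionary biologists who
have such paired time courses (or want to prototype methods on realistic
synthetic ones) and need those three questions answered with quantities
they can score.

## The model

**Trajectories.** Cells at consecutive time points $t, t{+}1$ are coupled by
unbalanced entropic optimal transport: $\gamma \ge 0$ minimizing

$$\langle C,\gamma\rangle - \varepsilon H(\gamma)
 + \lambda_1\,\mathrm{KL}(\gamma\mathbf 1\,\|\,a)
 + \lambda_2\,\mathrm{KL}(\gamma^\top\mathbf 1\,\|\,b)$$

with $C$ squared Euclidean distance in a PCA embedding,
$H(\gamma) = -\sum_{ij}\gamma_{ij}(\log\gamma_{ij}-1)$, defaults
$\varepsilon = 0.05$, $\lambda_1 = 1$, $\lambda_2 = 50$. The loose source
penalty lets proliferating cells export more mass than their share;
per-cell growth rates are learned by 20 rounds of alternating transport
and marginal re-estimation. Row-normalized couplings compose into Markov
chains that give every early cell a probability distribution over terminal
fates; thresholding (0.7) yields commitment calls and aggregating flows
over clusters yields a lineage tree (nodes under 10 cells dropped, edges
under 0.15 of outgoing mass pruned).

**Alignment.** Both species are restricted to 1:1 orthologs and projected
on shared gene-space directions (SVD of the pooled standardized matrix).
Per terminal lineage, the fate-probability-weighted cell clouds of species
A at time $s$ and species B at time $t$ are compared by exact earth mover
distance — the unregularized optimal-transport cost, computed by a
transportation simplex in C++ — and each A time point is paired with its
minimal-EMD B time point. Offsets of the paired times measure heterochrony.

**Interaction evolution.** In raw UMI space, a cell co-expresses a
regulator–target pair when both genes have ≥ 1 UMI (moderate-to-high: both
≥ 2). A decision cascade over the two species' co-expression time courses
and cluster distributions labels each pair `conserved`,
`shifted_temporal`, `shifted_spatial`, `lost`, `novel`, or
`indeterminate`, and returns its evidence.

A two-species embryo simulator (`simulate_two_species()`) with branching
lineages, specification delays, differential growth, and injected
interactions provides ground truth for every step; the methods vignette
(`vignettes/comparative-trajectories.Rmd`) documents the models,
parameters, and numerical choices in full.

## Worked example

Co-expression calls on a five-cell fixture — regulator UMIs
`(0, 1, 2, 5, 1)`, target UMIs `(3, 1, 2, 0, 4)`:

```r
library(devoalign)
cm <- count_matrix(rbind(gA = c(0, 1, 2, 5, 1), gB = c(3, 1, 2, 0, 4)),
                   c("gA", "gB"), paste0("cell", 1:5), species = "A",
                   timepoint_hpf = 9)
coexpression_timecourse(list(cm), "gA", "gB")
#>   timepoint_hpf n_total_cells n_coexpressing n_low n_high proportion
#> 1             9             5              3     2      1        0.6
```

Three of five cells carry both transcripts (cells 2, 3, 5); only cell 3
has both at ≥ 2 UMIs, so one of the three is a moderate-to-high call and
the co-expressing proportion is 0.6.

End to end on the simulator — species B is generated with every lineage
program switching on 3 h later than species A:

```r
res <- run_pipeline(sim_config(seed = 1), pipeline_config(),
                    stages = c("simulate", "preprocess", "transport",
                               "fates", "align"))

# fate probabilities of 9-hpf species-A cells over the four terminal fates
res$state$fates$A[["9"]]
#> FateMatrix: 300 cells x 4 fates (ecto, endo, pigm, skel), reference 24 hpf
round(res$state$fates$A[["9"]]$probs[1:3, ], 3)
#>                 ecto  endo  pigm  skel
#> A_t009.0_c0001 0.972 0.018 0.007 0.004
#> A_t009.0_c0002 0.959 0.021 0.007 0.013
#> A_t009.0_c0003 0.991 0.007 0.001 0.001

# per-lineage median time offset (species B minus species A, hours)
sapply(res$state$align, function(ar) median(ar$offsets))
#> ecto endo pigm skel
#> -2.0  1.5  3.5  1.5
```

The first three 9-hpf cells are already near-committed ectoderm (top fate
probability > 0.95; rows sum to 1). The alignment recovers the engineered
+3 h delay in three of the four lineages to within one inter-sample
spacing (the sampling grid steps by 3–4 h, so ±1.5 h quantization around
+3 is expected); the ectoderm offset is pulled negative because early
uncommitted cells dominate that lineage's weighted clouds at coarse
sampling.

## The analysis workflow

The numbered scripts under `analysis/` run the headline analyses and write
their tables under `results/`:

1. `01_simulate.R` — generate both species; cell counts and true program
   onsets.
2. `02_qc_preprocess.R` — strict-boundary cell filtering, normalization,
   PCA, clustering (mean lineage purity 1.00 at 24 hpf).
3. `03_transport_fates.R` — growth learning and fate probabilities; the
   committed fraction rises from 0.30 (6 hpf) to 0.99–1.00 (20 hpf).
4. `04_lineage_trees.R` — transport-derived lineage trees; edge F1 = 1.0
   against the generating tree for both species.
5. `05_time_alignment.R` — EMD time alignment; per-lineage median offsets
   as above.
6. `06_interaction_evolution.R` — a nine-interaction panel (conserved /
   lost / shifted +6 h); 9/9 labels recovered.

Each is run from the repository root, e.g.
`Rscript analysis/05_time_alignment.R`.

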