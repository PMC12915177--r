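# myeloTraj

Kidney-allograft rejection is driven in large part by recipient-derived
monocytes that infiltrate the graft and differentiate into pro-inflammatory
macrophages. `myeloTraj` is an R package that reimplements, as a tested and
reusable pipeline, the computational chain used to identify the lineage
markers of such a rejection-driving macrophage population and to quantify
its clinical consequences:

1. **Lineage construction** — minimum spanning tree over cluster centroids
   in a 2-D embedding, root-to-leaf lineages from a chosen starting cluster
   (classical monocytes in the motivating study), per-cell pseudotime by
   projection onto piecewise-linear principal curves, and a shared grid of
   K = 5 knots on pooled pseudotime.
2. **Trajectory differential expression** — for each gene, one
   negative-binomial regression with a block cubic B-spline basis per
   lineage (offset = log library size, per-gene method-of-moments
   dispersion). Two lineages are contrasted over the segment between knots
   3 and 4 with a Wald statistic `W = d' pinv(Sigma_d) d`, where `d` is the
   vector of fitted log-mean differences on a pseudotime grid in the
   segment; per-point log2 fold changes are summarized by mean and median,
   and p-values are Benjamini–Hochberg adjusted.
3. **Marker selection** — per comparison, the rank score
   `R = sqrt(rank(W)^2 + rank(log2FC)^2)` (ties randomly broken under a
   seed), genes at or above the 90th percentile of `R`, and the
   intersection of the selections across all comparisons against the focal
   lineage.
4. **Origin assignment** — rank-based module scores (a Mann–Whitney
   U-statistic score with rank cap 1500) for X-linked (XIST, JPX, FTX) and
   Y-linked (DDX3Y, KDM5D, USP9Y) signatures, turned into donor/recipient
   labels for sex-mismatched transplants by a score-margin rule.
5. **Deconvolution benchmarking** — 5% stratified training split, CPM
   signature matrix with per-type marker selection (minimum expression
   0.25 CPM), 100 pseudobulk mixtures with known Dirichlet proportions,
   non-negative least squares estimation, and per-type Pearson validation.
6. **Cohort statistics** — time-dependent ROC at 365 days
   (cumulative/dynamic, Kaplan–Meier estimator), Youden index
   `J = sensitivity + specificity - 1` and its optimal cutoff, Kaplan–Meier
   curves right-censored at 1825 days with the log-rank test, univariate and
   multivariate Cox models (Efron ties) with Schoenfeld diagnostics, an
   infiltration score (per-type proportion ratio between outcomes), Banff
   lesion-sum correlation (g + ptc + i + t), and Mann–Whitney /
   Kruskal–Wallis + Dunn group tests.

Every stage is exercisable without any download: the package bundles
synthetic-data generators (`simulate_trajectory_dataset()`,
`simulate_celltype_experiment()`, `simulate_origin_labels()`,
`simulate_bulk_cohort()`) that produce branching negative-binomial count
trajectories with planted knot-3–4 markers, distinct annotated cell types,
sex-mismatch origin labels, and proportional-hazards survival cohorts —
each with full ground truth.

## Worked example

```r
library(myeloTraj)

cfg <- trajectory_sim_config(n_lineages = 3, cells_per_lineage = 300,
                             n_genes = 400, n_planted_markers = 10,
                             planted_log2fc = 2, seed = 7)
sim  <- simulate_trajectory_dataset(cfg)
lin  <- fit_pseudotime(sim$experiment,
                       infer_lineages(build_cluster_graph(sim$experiment),
                                      root_cluster = "root_b1"))
knots <- place_knots(lin, K = 5)
fits  <- fit_nb_smoothers(sim$experiment, lin, knots)

focal  <- grep("^lin_L1_", names(lin$paths), value = TRUE)
others <- setdiff(names(lin$paths), focal)
sets <- lapply(others, function(ol) {
  de <- rank_score(early_de_test(fits, c(ol, focal)))
  top_quantile(setNames(de$rank_score, de$gene), q = 0.9)$genes
})
core <- intersect_comparisons(sets)$core
mean(sim$truth$planted_marker_ids %in% core)
#> [1] 1
length(core)
#> [1] 15
```

All 10 planted markers are recovered in a 15-gene core set: the selection
chain finds the genes whose smoothers rise specifically on the focal
lineage between knots 3 and 4. (With only two comparisons the intersection
also admits a handful of noise genes; see the methods vignette for why the
intersection count matters.)

`run_pipeline(pipeline_config(...), dir)` executes the whole chain —
simulation, QC, lineages, trajectory DE, marker selection, origin
assignment, deconvolution benchmark, survival stratification — and writes
per-stage TSV outputs plus a reproducibility manifest into `dir`.

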