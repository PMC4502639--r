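# stagenet

Stage-associated gene coexpression network analysis and classification for
tumor expression data.

## The problem

Clinical stage (early, I–II, versus late, III–IV) is the strongest
prognostic factor in solid tumors such as oral squamous cell carcinoma,
but single-gene differential expression rarely yields stage markers that
replicate. A network view helps: genes work in coexpressed modules, and a
module whose collective expression tracks stage is a better place to look
for markers than a ranked gene list. `stagenet` packages that strategy as
a tested, seeded pipeline for anyone with a multi-batch gene-by-sample
expression matrix and a tumor/normal + stage phenotype table:

1. **Preprocess** — empirical-Bayes location/scale batch adjustment,
   SVD steady-state eigenfeature filtering, variance filtering.
2. **Differential expression** — moderated t (empirical-Bayes variance
   shrinkage), genes kept when |log2 FC| ≥ 1 *and* BH q < 0.05.
3. **Network** — signed weighted adjacency
   `a_ij = ((1 + cor_ij)/2)^β` (default β = 18) on tumor samples,
   topological overlap `TOM_ij = (Σ_u a_iu a_uj + a_ij)/(min(k_i,k_j) + 1 − a_ij)`,
   average-linkage clustering with a static modularity-guided cut.
4. **Module–trait gating** — module eigengenes (first PC of each module),
   Pearson r against the binary stage trait, candidates at |r| ≥ 0.3;
   gene significance `GS_i = |cor(x_i, stage)|` and scaled intramodular
   connectivity `K_i = k_i / k_max`.
5. **Module credibility** — permutation Z-summary preservation
   (bands: <2 none, 2–10 moderate, >10 strong) over resampled test sets,
   and attack robustness: remove nodes in decreasing centrality order
   (degree / betweenness / closeness / eigenvector / random), track the
   largest-component fraction σ(ρ), report `R = mean σ` and
   `V = 1/2 − R`.
6. **Signature selection** — hubs (`GS > 0.2`, `K > 0.3`), then a
   1000-bootstrap elastic-net logistic regression; genes with inclusion
   frequency `f > 0.675 × n_boot` (= 675 at 1000 bootstraps, the
   90th-percentile cut of the fourth quartile) are the **key hubs**.
7. **Classification** — stratified 70/30 split, 5-fold cross-validated
   elastic net on the key hubs, rank-based ROC/AUC, held-out evaluation.

A seeded synthetic-data generator (`sim_config()` / `simulate_dataset()`)
reproduces the statistical structure this analysis assumes — multiple
batches, tumor/normal differential expression, planted coexpression
modules with hubs, one module correlated with stage — so every stage of
the pipeline is testable against known ground truth.

## Worked example

```r
library(stagenet)

cfg <- pipeline_config(
  simulate = sim_config(n_genes = 400, n_normal = 40, n_tumor_early = 60,
                        n_tumor_late = 60, n_batches = 3, n_modules = 3,
                        module_sizes = c(80, 60, 50), stage_module_index = 2,
                        stage_effect = 0.6, n_de_genes = 220, seed = 42),
  n_boot = 100, preserve_n_samples = 10, n_perm = 100, seed = 42)
report <- run_pipeline(cfg)
report
#> <pipeline_report> status: complete
#>   DEGs: 178 (91 up / 87 down)
#>   modules: 3 (beta=18, scale-free R2=0.45)
#>   stage module: module_2 (50 genes, r=0.57)
#>   hubs: 27
#>   key hubs: 12 (f > 68)
#>   mean CV AUC: 0.851  holdout AUC: 0.846  accuracy: 0.806
```

Reading the output: of 400 simulated genes, 178 pass the twofold/FDR
gate; the network over the 120 tumor samples splits into 3 modules; the
second module (50 genes) correlates with stage at r = 0.57 and is the
candidate; 27 of its genes pass the GS/K hub gates, and 12 of those are
included in more than 67.5% of 100 bootstrap elastic-net fits (f > 68).
The 12-gene classifier reaches a mean cross-validated AUC of 0.85 and an
AUC of 0.85 on the held-out 30% — here the planted stage module carried
correlation 0.6 with stage, so this is the expected range. `glance()`,
`tidy()` and the `plot_*()` / `autoplot()` helpers give tabular and
graphical views of the same report, and every individual stage
(`batch_adjust()`, `moderated_t()`, `build_network()`, `zsummary()`,
`attack_curve()`, `bootstrap_elasticnet()`, `cv_train()`, ...) is exported
for standalone use. A command-line front end with per-stage subcommands
lives at `inst/cli/stagenet.R`.

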