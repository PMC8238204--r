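# prer — pairwise relative expression ranks over PPI neighborhoods

`prer` is an R package for survival analysis on targeted proteomics panels
(RPPA-style, ~100–200 proteins per tumor sample). Instead of feeding
per-protein expression values to a survival model, it encodes each patient
by **pairwise relative expression ranks**: for selected protein pairs
(i, j), the feature

    x_ij = +1  if  x_i > x_j,   −1 otherwise

records which of the two proteins is more abundant in that patient. The
pair universe is restricted to **protein–protein interaction network
neighborhoods**, sampled with node2vec-style second-order biased random
walks (p = q = 0.25, 18 walks of length 100 per source protein; a node
joins the neighborhood when it appears in at least two distinct walks).
Because only orderings enter the representation, it is invariant to any
strictly increasing transform of a patient's profile — no rescaling, no
platform dependence.

On top of the representation the package provides the complete analysis
pipeline:

- confidence-filtered TSV edge-list loading, phospho-form → base-node
  mapping, edge-density summaries;
- univariate Cox screening (Wald p ≤ 0.05 per training fold), random
  survival forests (1000 trees, 10 random log-rank splits per candidate
  feature, via `ranger`), Harrell's C-index on held-out folds;
- paired repeated holdout (100× 80/20 by default) with one-sided Wilcoxon
  signed-rank comparisons across representations and Benjamini–Hochberg
  correction (win/tie/loss verdicts);
- permutation feature importance summed across models, per-protein scores
  (mean over containing pairs), rank differences r_q − r_p between
  individual and pairwise representations, top-k pair networks, and
  Kaplan–Meier log-rank grouping by a single pair feature;
- a network-propagation baseline (insulated diffusion, α = 0.5) and a
  ternary encoding variant with a 10% zero band;
- a synthetic-data generator that plants *order-based* survival signal
  (hazard depends only on whether x_i > x_j), the designed separation that
  makes every pipeline stage testable without external data.

## Worked example

```r
library(prer)

# a synthetic cohort: 120-protein network, 30 measured, 200 patients,
# 3 planted pairs whose ordering drives the hazard (beta = 1.5)
cfg    <- sim_config(n_patients = 200L, seed = 7)
net    <- simulate_network(cfg)
cohort <- simulate_cohort(net, cfg)
net
#> <ppi_network> 120 nodes, 237 edges, density 0.03319
cohort
#> <prer_cohort> 200 patients x 30 proteins; 3 planted pair(s); 31% censored

# walk neighborhoods -> pair features
nbhd  <- sample_neighborhoods(net, cohort$measured, walk_config(seed = 7))
pairs <- build_feature_pairs(nbhd, colnames(cohort$expression))
feats <- encode_binary(cohort$expression, pairs)   # 200 x 435, entries ±1

# paired repeated holdout: identical splits for both representations
res <- list(
  prer       = repeated_holdout(feats, cohort$survival, repeats = 20,
                                seed = 7, n_trees = 200),
  individual = repeated_holdout(cohort$expression, cohort$survival,
                                repeats = 20, seed = 7, n_trees = 200)
)
res$prer
#> <model_result> 20 repeats; test C-index median 0.676 (IQR 0.649-0.708)
res$individual
#> <model_result> 20 repeats; test C-index median 0.587 (IQR 0.560-0.629)

compare_representations(res)[, c("rep_a", "rep_b", "p_a_gt_b", "verdict")]
#>   rep_a      rep_b     p_a_gt_b verdict
#> 1  prer individual 6.496305e-05     win
```

The pairwise-rank representation sees the planted orderings directly and
beats the individual-expression arm on the same splits (one-sided
signed-rank p = 6.5e-05): the held-out median C-index rises from 0.587 to
0.676. `run_prer_pipeline()` wires the same stages behind a single YAML
config and writes a manifest, per-split C-indices, comparison verdicts and
importance tables to a run directory; `inst/cli/prer.R` exposes
`simulate | walk | encode | evaluate | run` subcommands for shell use.

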