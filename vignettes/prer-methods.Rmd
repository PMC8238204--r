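---
title: "Pairwise relative expression ranks over interaction neighborhoods: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pairwise relative expression ranks over interaction neighborhoods: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prer)
```

## The representation

Most survival models built on targeted proteomics (RPPA-style panels of
100–200 proteins) feed the per-protein expression values to the model
directly. `prer` instead represents each patient by *pairwise relative
expression ranks*: for selected protein pairs $(i, j)$ the feature is

$$
x_{i,j}^{(k)} =
\begin{cases}
+1 & \text{if } x_i^{(k)} > x_j^{(k)} \\
-1 & \text{otherwise,}
\end{cases}
$$

i.e. whether protein $i$ is more abundant than protein $j$ in patient $k$.
Ties fall in the "otherwise" branch. Because only orderings enter, the
representation is invariant to any strictly increasing per-patient transform
of the expression profile — it needs no rescaling and is robust across
measurement platforms, in the same spirit as rank statistics such as
Kendall's $\tau$ or top-scoring-pair classifiers.

Comparing all $\binom{|U|}{2}$ pairs would square the dimensionality with
mostly irrelevant comparisons. The pair set is therefore restricted to
*network neighborhoods*: protein $i$ is only compared against measured
proteins found near it in a protein–protein interaction (PPI) network.

## Neighborhoods by second-order biased random walks

Given an undirected PPI graph $G = (V, E)$ (confidence-filtered; edges with
confidence below 0.1 are discarded, scores exactly at the threshold kept)
and the measured node set $U \subseteq V$, the neighborhood $N_u$ of each
source $u \in U$ is sampled with node2vec-style second-order walks. From
current node $v$ with previous node $t$, the probability of stepping to a
neighbor $x$ of $v$ is proportional to $\alpha_{pq}(t,x)\, w_{vx}$ with

$$
\alpha_{pq}(t, x) =
\begin{cases}
1/p & d_{tx} = 0 \\
1 & d_{tx} = 1 \\
1/q & d_{tx} = 2,
\end{cases}
$$

where $d_{tx}$ is the shortest-path distance between $t$ and $x$ (within a
single step it can only be 0, 1 or 2). The first step of each walk has no
previous node and is uniform over the source's neighbors — the standard
convention for second-order walks. The network is treated as unweighted
($w_{vx} = 1$); a flag switches to confidence weights.

Defaults, used throughout: $p = q = 0.25$, walk length $l = 100$, $r = 18$
walks per source. Small $p$ and $q$ jointly bias the walks toward the
community surrounding the source. A node joins $N_u$ when it appears in at
least two *distinct* walks (`min_walks = 2`, exposed as a knob); repeated
visits within one walk do not count. The measured neighborhood is
$M_i = N_i \cap U$, and features are built for every $\{i, j\}$ with
$j \in M_i$, deduplicated as unordered pairs in lexicographic orientation —
the ordered mirror feature is the exact negation and carries no extra
information for tree ensembles, which is why we emit each pair once.

Phosphorylated forms (e.g. `STAT3PY705`) have no separate network node;
they inherit the neighbors of the unphosphorylated base node and are
additionally compared with the base protein itself and with any other
measured forms of the same base. An explicit measured-id-to-node mapping
table is preferred; without one, a `"<base>P<residues>"` suffix heuristic is
applied, and only when the stripped name is an actual network node.

Walks are seeded per source from the global seed and a hash of the source
id, so neighborhoods do not depend on the order in which proteins are
processed, and any subset of sources can be recomputed independently.

### Ternary variant

An alternative encoding adds a zero band: the feature is 0 when the two
values differ by less than 10% of the compared neighbor,
$|x_i - x_j| < 0.10\,|x_j|$, and otherwise takes the sign as before. The
absolute value in the denominator keeps the band meaningful for normalized
expression values that can be negative. The band is open: a difference of
exactly 10% is a sign call. With threshold 0 the ternary encoding collapses
to the binary one.

## Survival modelling and evaluation

The dataset is $D = \{(\mathbf{x}^{(k)}, S^{(k)}, \delta^{(k)})\}_{k=1}^n$
with observed time $S$ and event indicator $\delta$ (1 = death observed,
0 = censored). Evaluation follows a repeated-holdout design:

1. randomly split patients 80/20 into train and test (no stratification);
2. on the training fold only, screen features with univariate Cox
   proportional-hazards models (Efron ties) and keep those with Wald
   $p \le 0.05$ (boundary included); constant or degenerate features are
   skipped, and if nothing passes, the model falls back to all non-constant
   features (logged);
3. fit a random survival forest on the retained features — 1000 trees by
   default, 10 random candidate split points per feature evaluated with the
   log-rank statistic (delegated to `ranger` with
   `splitrule = "extratrees"`, `num.random.splits = 10`, which reproduces
   the classic random-split log-rank forest);
4. score the held-out fold with Harrell's concordance index, using the
   summed ensemble cumulative hazard as the risk score. Comparable pairs
   are those with $S_a < S_b$ and $\delta_a = 1$; risk ties credit 0.5;
   time-tied pairs are not comparable.

This is repeated 100 times (by default). Splits are a deterministic
function of the global seed and the repeat number only, so different
representations of the *same* cohort are evaluated on identical splits —
the paired design required by the one-sided Wilcoxon signed-rank test used
to compare representations. Benjamini–Hochberg correction is applied across
all one-sided tests in a report (e.g. across cohorts); a representation
"wins" when its adjusted one-sided p-value is below 0.05, "loses" when the
reverse test is, and ties otherwise. Two one-sided tests cannot both pass.

A network-propagation baseline is included: per patient, expression is
diffused over the measured subnetwork by iterating
$F \leftarrow \alpha F S + (1-\alpha) F_0$ with
$S = D^{-1/2} A D^{-1/2}$, $\alpha = 0.5$, tolerance $10^{-6}$, iteration
cap 1000 (the closed-form fixed point
$F^* = (1-\alpha) F_0 (I - \alpha S)^{-1}$ is used as the test oracle).

## Feature and protein importance

Per fitted model, a feature's importance is the drop in held-out
concordance when its test-fold column is permuted (`n_perm` permutations,
default 1). Across the repeated-holdout models the importances are
*summed*; a normalized variant (divided by the maximum) is provided for
display. A protein's score is the mean importance over all pair features
containing it,

$$ s_i = \frac{1}{\lVert \mathcal{P}_i \rVert} \sum_{(i,j) \in \mathcal{P}_i} f_{i,j}, $$

and proteins are ranked by descending score (rank 1 = most important; score
ties broken lexicographically by protein id, which makes the ranking
deterministic). The difference $r_q - r_p$ between a protein's
individual-expression rank $r_q$ and its pairwise-rank-representation rank
$r_p$ highlights proteins whose *relative* expression against their
neighborhood is prognostic even when their absolute level is not.
Phospho-forms and their base protein are ranked as separate entities. The
top-$k$ ($k = 50$ by default) pair features can be exported as a small
network — one edge per pair — and any single binary pair feature can be
used to split the cohort into two groups compared with a Kaplan–Meier
log-rank test.

## The synthetic-data generator

Real RPPA cohorts and curated interactomes cannot be redistributed with the
package, so every claim is validated on synthetic data whose generative
process matches the method's assumptions:

- **Network**: preferential attachment (120 nodes, $m = 2$) for a
  heavy-tailed degree distribution, or a two-block stochastic block model;
  components are bridged so the graph is connected; edge confidences are
  uniform on $[0, 1]$ so the 0.1 filter is exercisable.
- **Expression**: each protein mixes its own standard-normal latent score
  with the mean of its neighbors' scores (mixing weight 0.8, then
  standardized), giving interacting proteins a correlation of roughly 0.4 —
  a crude but serviceable stand-in for co-expression of interacting
  proteins.
- **Survival**: the hazard is
  $h^{(k)} = h_0 \exp\!\big(\beta \sum_{(i,j) \in \text{planted}} \mathbb{1}[x_i^{(k)} > x_j^{(k)}]\big)$
  with $h_0 = 0.1$; times are exponential given the hazard; censoring times
  are uniform on $[0, c_{\max}]$ with $c_{\max}$ calibrated by root finding
  so the expected censored fraction hits the target (30% by default).
  Planted pairs are drawn from network-adjacent measured pairs (widened to
  two hops if adjacency offers too few).

The essential design point: the hazard depends *only on orderings*, so
multiplying a patient's expression vector by any positive scalar changes
neither the true risk nor any pairwise-rank feature, while it changes every
individual-expression feature. This is the separation the studies probe.

What the generator does **not** emulate: antibody-level measurement noise,
batch structure, tissue-specific network rewiring, non-proportional
hazards, or informative censoring. Passing studies therefore demonstrate
that the pipeline recovers order-based signal under its own assumptions —
not that such signal dominates any particular clinical cohort.

## Study designs and problem sizes

Three canned studies (`planted_signal_study()`,
`importance_recovery_study()`, `null_tie_study()`) back the package's
acceptance checks; their sizes were fixed once, as a balance of statistical
resolution and desk-scale runtime:

- *Planted-signal study*: 300 patients, 30-protein panel on a 120-node
  network, 3 planted pairs at $\beta = 1.5$, 50 paired 80/20 splits,
  200 trees. Reports the one-sided signed-rank p-value for pairwise-rank
  features beating individual expression.
- *Importance recovery*: 20 independent simulations of the same design,
  5 models each (150 trees), permutation importance on the held-out folds
  summed across models; a run succeeds when all 3 planted pairs land in the
  top 10 features.
- *Null control*: 20 scenarios with $\beta = 0$, 20 paired splits each
  (100 trees), compared in a single report (BH across all scenarios); the
  expected outcome is a tie nearly everywhere. One caveat is worth knowing:
  repeated holdout resamples *splits*, not cohorts, so a spurious
  cohort-level association between a noise feature and survival generalizes
  from every training fold to its test fold and can make one arm beat the
  other consistently within that cohort. Occasional non-tie verdicts on
  null cohorts are therefore an inherent property of split-resampling
  designs (the two arms differ in how many noise features they expose to
  this effect), not evidence of leakage.

Forest sizes below the 1000-tree default are used in the studies because
the feature spaces are small (a few hundred binary features) and the
C-index distribution across splits is already stable; the 1000-tree default
remains for real analyses.

## Numerical choices and degenerate inputs

- Duplicate edges collapse to the maximum confidence; self-loops are
  dropped; after loading, the node set is the endpoints of retained edges,
  which makes load–write–load an exact round trip.
- Tie handling: expression ties encode as $-1$ (the "otherwise" branch; a
  `tie_value` knob exists); Cox fits use Efron ties; risk ties credit 0.5
  concordance; score ties in rankings break lexicographically.
- Univariate screening uses the exported `survival::coxph.fit` fast path;
  fits with non-finite or extreme coefficients (monotone-likelihood
  separation) are skipped with a warning.
- Walks cannot dead-end on a connected undirected graph once started, but a
  guard keeps truncated walks if a degree-zero node is ever reached; an
  isolated source yields degenerate single-node walks and a warning.
- Propagation aborts with the residual if the iteration cap is reached
  (spectral radius of $\alpha S$ is below 1, so this indicates a
  misconfigured $\alpha$).

## Known limitations

- The pair universe of the original 131-protein RPPA analysis (1909
  features) depends on the specific interactome release; with a different
  network or panel the dimensionality will differ, and the package makes no
  attempt to reproduce a particular count.
- Whether permutation importance should use out-of-bag or held-out data is
  a genuine choice; the package defaults to held-out test folds (matching
  how the models are scored) — out-of-bag importance is not implemented.
- Covariate-adjusted survival curves (age, sex) are out of scope; only
  plain Kaplan–Meier with the log-rank test is provided.
- The Cox screen is refit on every training fold (never globally), which is
  the leakage-safe reading of per-model feature selection.
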