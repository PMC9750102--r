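---
title: "Methods: scoring omics quantification tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring omics quantification tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`omicsqc` compares candidate feature-by-sample quantification tables for
the same study on six quality axes. This vignette documents the models
and procedures behind each metric, the tunable parameters with their
defaults and units, the synthetic-study generator used throughout the
test suite, and the numerical and design choices made where the
methodology is genuinely open.

## Data model and alignment

A table is a features × samples numeric matrix with explicit missing
values and a declared scale (`raw` or `log2`). The scale is never sniffed
from the data: declarations are the user's responsibility, though a
log2-declared table with a maximum above 50 triggers a warning. Missing
tokens on input are the empty string, `NA` and `NaN` (case-insensitive);
`0` is a measured value, because quantification pipelines routinely
distinguish a zero estimate from an unobserved feature.

When several tables are evaluated together they are restricted to the
*intersection* of their sample sets, ordered by the annotation. The
intersection (rather than a union with induced missingness) keeps every
pairwise metric comparable across tables; below 3 common samples the
correlation-based metrics are meaningless, so alignment fails there.
Feature sets are deliberately *not* intersected — the depth metrics must
see each table's own features. Feature IDs are compared case-sensitively
and no identifier mapping is attempted.

## Group 1 — depth

A feature is *identified* if it has at least one non-missing value and
*quantifiable* if it is observed in at least `quantifiable_min_fraction`
of samples (default 0.5, a common proteomics convention; the term has no
single agreed definition, so ours is explicit and configurable).
Cross-table overlap uses exclusive membership patterns (UpSet
semantics) over identified features, so all-missing placeholder rows
cannot inflate the overlap; pattern counts always sum to the size of the
union.

## Group 2 — distribution similarity

Whether samples were normalized onto a common distribution is scored
without assuming any parametric form. For samples $i, j$ with observed
values $x_i, x_j$, the tie-aware rank AUROC

$$A_{ij} = \Pr(X_j > X_i) + \tfrac12 \Pr(X_j = X_i)$$

is computed from ranks (the Mann–Whitney construction), which is exact
and deterministic — no classifier is fitted. $A_{ij} = \tfrac12$ means
the two distributions are indistinguishable by thresholding. Pair
similarity is defined as $1 - 2\,|A_{ij} - \tfrac12| \in [0, 1]$ and the
table's score is the unweighted mean over unordered pairs; the mean (as
opposed to a minimum or median) was chosen so that a single outlying
sample degrades the score proportionally rather than dominating it. A
perfectly quantile-normalized table attains exactly 1. Quartiles and
five-number summaries use linear interpolation between order statistics
(the default "type 7" rule of `quantile()`), stated here so hand checks
reproduce.

## Group 3 — batch effect

Samples are embedded by PCA: features with missing values are imputed by
their feature median *for the embedding only*, zero-variance features
dropped, features centered. Component signs are fixed so each
component's largest-magnitude loading is positive, making coordinates
deterministic across platforms.

Two complementary scalars quantify batch structure:

- **Average silhouette width** of the batch labels, with Euclidean
  distance on the leading `n_pca_components` (default 2) principal
  components: $s(i) = (b_i - a_i)/\max(a_i, b_i)$ with $a_i$ the mean
  within-batch distance and $b_i$ the smallest mean distance to another
  batch; singleton batches score 0. Computing it in PCA space rather
  than on the raw matrix matches the PCA visualization it accompanies
  and is robust to imputation noise in sparse features.
- **Principal-component regression**: per leading component, the
  one-way ANOVA $R^2$ (between-batch over total sum of squares) of the
  component scores on the batch factor, averaged with variance-fraction
  weights over the components covering ≥ 80 % of variance (capped at
  10). This mirrors principal-variance-component-analysis practice.

Both are ≈ 0 in the absence of batch structure — for a random $g$-level
grouping of $n$ i.i.d. scores the expected ANOVA $R^2$ is
$(g-1)/(n-1)$ — and approach 1 when batches separate. Higher therefore
means *worse*; the report inverts them (below). Sample–sample Pearson
correlations for the heatmap use pairwise-complete observations, with
pairs sharing fewer than 3 complete features reported as missing —
imputed values are never used outside the embedding.

## Group 4 — biological signal

**Complex co-expression.** Members of the same protein complex should
co-express. Within the "complex universe" (features present in the table
and annotated to ≥ 1 complex) the engine samples up to `n_complex_pairs`
(default 200) intra-complex pairs and equally many inter-complex pairs —
both members annotated but sharing no complex, so the null is matched on
annotation coverage, a stricter and better-controlled reading than
pairing against arbitrary features. Pearson $r$ per pair uses
pairwise-complete observations (≥ 6 required), and the scalar summary is
the AUROC with which $r$ separates intra from inter pairs.

**Network pathway prediction.** A co-expression network connects each
quantifiable feature to its `network_top_k` (default 10) highest-$|r|$
partners, symmetrized by union, edge weight $|r|$. A random walk with
restart
$$p \leftarrow (1 - r)\,W^\top p + r\,p_0$$
with $W$ the row-normalized adjacency (so $W^\top$ is column-stochastic
and each step conserves probability mass; mass reaching isolated nodes
is returned to $p_0$), restart $r = 0.5$, L1 tolerance $10^{-6}$,
propagates from a seed set $p_0$ uniform on the seeds. Per pathway with
at least $\max(5, \text{cv\_folds})$ members in the network, members are
split into folds, the walk is seeded from the training members, held-out
members are ranked against all non-members, and fold-pooled scores give
one AUROC per pathway; the table metric is the median over pathways.

**Class prediction.** For a two-level sample classification the engine
fits an L2-regularized (ridge) logistic model — a deliberately plain,
deterministic stand-in for "a machine-learning model", with fixed
penalty $\lambda = 0.1$ — on the 500 most variable quantifiable
features, median-imputed and standardized *inside each training fold*,
under stratified `cv_folds`-fold (default 5) cross-validation; the
metric is the AUROC of pooled out-of-fold scores. Multi-class problems
are out of scope.

**Clustering concordance.** Samples are clustered hierarchically with
distance $1 - r$ (Pearson, pairwise-complete) and average linkage, the
tree cut at $k$ = number of class levels, and the partition compared to
class labels and to batch labels by adjusted Rand index. High agreement
with class indicates biology-driven structure; high agreement with batch
indicates batch effect. Note that correlation distance is invariant to
whole-sample shifts, so it sees class signatures only when they are
feature-specific.

QC replicate samples carry their own class label and are excluded from
the class-label metrics (class prediction, clustering concordance) —
otherwise a QC-bearing study could never satisfy the two-level
precondition.

## Group 5 — QC reproducibility

Per feature, the coefficient of variation SD/mean (sample SD, $n-1$
denominator) across the replicated QC samples, computed on the *linear*
scale: log2-declared tables are back-transformed with
`log_base_for_cv` (default 2) first, since CV of log intensities is not
the conventional platform-reproducibility measure. Features with fewer
than 2 QC observations or non-positive mean are excluded and counted.
The summary is the fraction of features with CV below `cv_threshold`
(default 0.30, i.e. "percent of features with CV < 30 %").

## Group 6 — paired-omics concordance

Gene-wise (per shared feature, across shared samples) and sample-wise
(per shared sample, across shared features) correlations against a
paired table from another omics layer, requiring ≥ 10 shared features,
≥ 6 shared samples, and ≥ 6 complete pairs per correlation. Spearman
rather than Pearson, because cross-omics relationships (e.g.
mRNA–protein) are expected to be monotone but not linear. The summary is
the median gene-wise $r$.

## Radar scores

The per-group score mapping (recorded in the report's
`mapping_record`) is implementation-defined and fixed: depth =
quantifiable count relative to the best table; normalization = the
similarity score; batch = mean of $1 - \text{clamp}(ASW, 0, 1)$ and
$1 - R^2_{PCR}$ (inverted: higher batch metrics mean worse quality);
signal = mean of the available AUROCs rescaled from their chance level
$[0.5, 1]$ onto $[0, 1]$; reproducibility = the CV fraction; concordance
= median gene-wise $r$ clamped to $[0, 1]$. Groups that could not be
computed are reported as absent, never as zero, so a skipped group
cannot drag a table's profile down.

## The synthetic-study generator

`generate_fixture()` emulates a two-class, multi-batch quantification
study on the log2 scale:

- feature baselines $\mu_f \sim N(20, 2^2)$ log2 units — typical MS
  intensity magnitudes;
- `n_modules` (default 5) co-expression modules of `module_size`
  (default 20) features at the tail of the feature vector, each driven
  by a per-sample latent factor $N(0, \text{module\_latent\_sd}^2)$
  (default SD 1) plus i.i.d. noise (default SD 0.5); the expected
  intra-module correlation is the closed form
  $\sigma_L^2 / (\sigma_L^2 + \sigma_e^2) = 0.8$ at the defaults, and
  the complex/pathway collections are exactly the modules;
- a class effect (default 1 log2 unit = twice the noise SD) on the
  first 20 features for class B — kept disjoint from the modules so
  class signal and co-expression signal are independently controllable;
- an additive `batch_shift` (default 0) on all features of
  non-reference-batch samples, batches interleaved across the class
  blocks so class and batch are not confounded;
- `n_qc` (default 5) QC replicates: noisy copies of the pooled
  reference profile, flagged `is_qc`, class label `QC`;
- completely-at-random missingness at `missing_rate` (default 0.05) —
  MCAR only, so closed-form expectations stay valid; and
- a paired table = table + independent noise at the noise SD.

Defaults were chosen once to represent a modest but realistic study
(300 features, 60 study samples) on which every metric is exercised;
`degrade_table()` adds noise and/or batch shift to model a worse
processing pipeline for the same study. The generator reproduces the
statistical assumptions each metric tests — latent-factor co-expression,
additive batch shifts, MCAR missingness — and *not* the features of real
data those assumptions idealize: intensity-dependent missingness,
heavy-tailed and correlated noise, ratio compression, shared peptides,
library-size artifacts. Passing tests therefore demonstrate correctness
of the metrics under their stated models, not performance claims on any
real dataset. The test suite runs the generator at 30–150 features and
10–65 samples for unit checks and at the full defaults for the
end-to-end and ordering checks; these sizes are the package's choice of
smallest conditions under which the expected effects are comfortably
detectable.

## Numerical choices and determinism

- Tie handling in every AUROC is exact (half-weight), via ranks.
- Quantiles: type 7 throughout.
- PCA signs fixed by the largest-magnitude loading; zero-variance
  components are excluded from PCR.
- RWR stops at L1 change < `rwr_tol` (default $10^{-6}$) or 1000
  iterations and always returns a probability vector.
- All sampling (complex pairs, CV folds) derives from
  `random_seed` in the configuration; RNG state of the caller is saved
  and restored. Identical configuration + seed yields byte-identical
  TSV outputs (numbers are written with 15 significant digits).
- Degenerate inputs degrade explicitly: samples with < 2 observations
  are excluded with a warning, a single batch level skips the batch
  metrics (absent, not zero), missing QC replicates skip Group 5, and
  thin correlation pairs become missing entries rather than numbers.

## Known limitations

- No identifier mapping: tables must share feature ID conventions with
  the gene-set files and the paired table.
- Class prediction is restricted to two classes.
- The silhouette/PCR pairing quantifies *linear* batch structure;
  non-linear batch effects may be under-estimated.
- The radar normalization is implementation-defined; scores are
  comparable within a report, not across tools.
- Missingness is treated as completely at random wherever imputation is
  needed (embedding only); informative missingness is not modelled.
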