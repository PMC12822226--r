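---
title: "sDCFE: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{sDCFE: model, parameters, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdcfe)
```

This vignette is the package's own account of the method: the score it
computes, the assumptions behind it, what every tunable parameter does and
why its default is what it is, the numerical conventions, and what the
synthetic-data generator does and does not emulate.

## The model

The object of study is a samples × features matrix of continuous omics
measurements (log-scale expression, methylation fractions) with a class
label per sample. The task is a *filter*: rank genes by how well they
separate the classes, robustly, and keep a short panel.

### Discriminative variance with MAD regularization

For gene $i$, with classes $c = 1..C$ of sizes $n_c$, $N = \sum_c n_c$,
class weights $w_c = n_c/N$, class means $\mu_{ic}$, grand mean $\mu_i$, and
population class variances $\sigma_c^2(i)$:

$$
\mathrm{DCFE}_i \;=\;
\frac{\sum_c w_c\, (\mu_{ic} - \mu_i)^2}
     {\sum_c w_c\, \sigma_c^2(i) \;+\; \lambda\,\mathrm{MAD}_i \;+\; \varepsilon}
$$

The numerator is the variance of the class means around the grand mean under
the class-size mixture; the first denominator term is the matching
within-class variance. At $\lambda = 0$ this is the weighted Fisher-like
variance ratio, and the test suite holds the implementation to a brute-force
oracle of that quantity at $10^{-9}$. The $\lambda\,\mathrm{MAD}_i$ term adds
the gene's median absolute deviation (unscaled: the median of absolute
deviations from the median, with no normal-consistency constant — it is a
penalty, not a variance estimate) so that genes whose between-class spread
comes packaged with enormous overall dispersion are damped. The
regularization deliberately breaks scale invariance: scaling a gene by $s>0$
multiplies numerator and variance terms by $s^2$ but the MAD term only by
$s$, which is why scoring is meant to run on comparably scaled (log2,
optionally z-scored) data.

Implicit assumptions: classes differ in gene-wise *means* (location shifts,
not dispersion or shape differences); every class has at least two samples
so a class variance exists; the matrix is imputed.

### Cluster separation

Real cohorts carry structure the labels do not — latent subtypes, label
noise. The unsupervised component clusters the samples with K-means and
scores each gene by the one-way ANOVA F-statistic of its values across the
$K'$ non-empty clusters:

$$
\mathrm{CS}_i \;=\;
\frac{\sum_k n_k (m_k - m)^2 / (K'-1)}
     {\sum_k \sum_j (x_{jk} - m_k)^2 / (N-K') \;+\; \varepsilon}
$$

A gene that separates the discovered clusters gets a large F even if it is
useless for the given labels.

Two clustering readings are implemented because "cluster structure" is
genuinely ambiguous for a gene score:

* `clustering_mode = "global"` (default): one K-means on the z-scored full
  matrix — clusters are *sample subtypes*, shared by all genes. This is the
  reading under which CS captures hidden cohort heterogeneity, and it makes
  CS independent of the class labels by construction.
* `clustering_mode = "per_gene"`: an independent 1-D K-means per gene —
  CS then measures each gene's own multimodality.

Neither is asserted as the only correct reading; the default is the one that
matches the subtype motivation.

### The synergy

$$
\mathrm{sDCFE}_i = \alpha\,\mathrm{DCFE}_i + (1-\alpha)\,\mathrm{CS}_i
$$

DCFE (a regularized variance ratio, typically O(1)) and CS (an ANOVA F,
easily O(10²)) live on incommensurate scales, so combining raw values would
let CS dominate at any $\alpha$. By default
(`component_norm = "minmax"`) each component is min–max rescaled to $[0,1]$
across genes before blending; a constant component maps to all zeros.
`component_norm = "raw"` applies the formula literally for users who have
already put the components on a common scale. The min–max choice keeps
$\alpha$ interpretable as a true mixing weight; its cost is that the
normalization depends on the gene set being scored.

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `alpha` | 0.7 | synergy weight; emphasizes supervised discrimination while keeping a 0.3 share for cluster separation. At 1 the score is pure DCFE, at 0 pure CS. |
| `lam` | 0.1 | MAD penalty weight (unitless, same scale as a variance/MAD ratio); large enough to demote high-dispersion genes, small enough not to swamp the within-class variance. |
| `K` | number of classes | cluster count; aligning K with the class count makes the partition interpretable (e.g. 2 for a binary staging task, 10 for a ten-type cohort). Any `K >= 2` up to the sample count is accepted. |
| `seed` | 42 | K-means initialization seed; fixed so scoring is deterministic. |
| `n_init` | 10 | random K-means restarts (Hartigan–Wong, best of 10); restarts are the guard against bad local optima. |
| `component_norm` | `"minmax"` | see above. |
| `clustering_mode` | `"global"` | see above. |

Preprocessing defaults: KNN imputation with `k = 5` neighbours; features
with more than 50% missing cells dropped before imputation (imputing a
mostly-missing feature from 5 neighbours is noise amplification); log2 with
offset +1 so zero stays zero; z-scoring with *population* standard
deviation, constant features mapping to 0. Neighbour distances are root mean
squared differences over mutually observed features, so pairs with different
observation overlap remain comparable; only samples observing the target
feature are eligible neighbours.

## Choosing the panel size

`select_top_fraction()` keeps `ceiling(fraction × n)` genes — ceiling so a
50% cut of an odd-sized table (921 → 461) keeps the extra gene.
`stability_cutoff()` automates the size choice: over a grid of candidate
sizes $k$ it computes (a) ranking stability — the mean pairwise Jaccard
similarity of top-$k$ sets across `B` stratified 50% subsample rescoring
runs — and (b) nearest-centroid accuracy under stratified cross-validation on
the top-$k$ features of the full-data ranking. The chosen $k$ is the
smallest grid value whose next step improves *both* curves by less than 1%
relative (falling back to the largest grid value when no plateau appears).
The 1% threshold encodes "minimal gains beyond the plateau"; it is a
convention, not an estimate.

## Numerical conventions

* $\varepsilon = 10^{-12}$ in both denominators guards genes constant within
  every class (and with zero MAD); any gene with zero between-class variance
  scores exactly 0 regardless of the denominator.
* CS is capped at $10^{12}$ for genes with zero within-cluster variance.
* Ranking sorts by descending sDCFE with ties broken by ascending feature
  id — an arbitrary but deterministic rule, so reruns and platforms agree.
* K-means is `stats::kmeans` (Hartigan–Wong) with `n_init` restarts under a
  fixed seed. When the data have at most `K` distinct points the saturated
  optimum (each distinct point its own cluster) is assigned directly;
  constant data yield a single cluster and CS 0.
* Nearest-centroid prediction breaks exact distance ties by the stored class
  order.
* Zero-variance filtering uses an exact `variance > 0` test (population
  variance over observed values), no tolerance: the rule is "zero variance",
  and near-constant features are legitimately informative for some assays.

## Evaluation metrics

`multiclass_metrics()` reports accuracy; per-class and macro
precision/recall/F1 (one-vs-rest reductions of the confusion matrix, zero
denominators reported as 0 with a warning); balanced accuracy (mean
per-class recall); the multiclass MCC in covariance form,
$(cs - \sum_k p_k t_k)\,/\,\sqrt{(s^2-\sum p_k^2)(s^2-\sum t_k^2)}$; macro
one-vs-rest AUC via the Mann–Whitney rank statistic with ties averaged
(invariant to monotone score transforms); and a macro expected calibration
error: per class, probabilities are binned into 10 equal-width bins and the
count-weighted mean absolute gap between mean predicted probability and
observed frequency is averaged over classes, empty bins skipped. Ten
equal-width one-vs-rest bins is a convention choice; with few samples per
class the ECE estimate is coarse.

## Biomarker novelty tiering

Candidate genes are tiered from a user-supplied binary evidence table over
four curated biomarker/driver databases (COSMIC, OncoKB, CIViC, ONGene) and
two cancer-association resources (HPA, DisGeNET). The categorical rule has
precedence: any curated presence ⇒ *established*; otherwise any presence
(necessarily association-only) ⇒ *emerging*; absence everywhere ⇒ *novel*.
The mean presence score over the six indicators is reported alongside and
agrees with the categories at the boundaries that matter (mean 0 ⇔ novel;
any curated hit forces mean ≥ 1/6). A score-band formulation of the same
tiers is ambiguous exactly at 0.5 — a gene present in three of six
resources can be curated-backed or not — which is why the categorical rule,
not the band, is normative here. Database screening is not automated: the
evidence table is an input, keeping the module deterministic and offline.

## The synthetic-data generator

`simulate_expression()` draws baseline values $\mathcal N(6, \sigma^2)$ per
cell — the regime of log2-transformed expression — and plants two disjoint
gene blocks: *informative* genes receive a $+\,\text{effect} \times \sigma$
mean shift in one randomly chosen class (a marker-gene design), and, when
`n_subtypes > 0`, a *subtype* block receives the analogous shift tied to
latent subtype labels drawn independently of the class. The second block is
what gives the CS component something to find that DCFE cannot.
`simulate_paired_omics()` adds a second, methylation-like assay (logistic
transform of latent Gaussians, hence values in (0,1)) on a partially
overlapping patient set with consistent labels, for exercising late fusion.
`inject_missing()` masks cells completely at random. Everything is
deterministic given the seed.

What the generator does **not** emulate: negative-binomial count noise and
mean–variance coupling of raw RNA-seq, gene–gene correlation, batch
effects, informative missingness, or class-dependent dispersion. Passing
tests on this generator demonstrate that the scoring machinery recovers
location-shift signal under independent Gaussian noise and latent subtype
structure — not that it is robust to the full messiness of real cohorts.

The default configuration (4 classes × 50 samples, 1000 genes, 30
informative at a 2-sd effect) is the parameter-recovery condition the test
suite verifies: mean top-30 recall of the planted genes across five seeds of
at least 0.90, with the supervised component's recall collapsing to chance
(≈ 30/1000) under label shuffling. The shuffled-label null is evaluated on
the DCFE component: in global mode the clustering, and hence CS, does not
depend on the labels at all, so the combined score retains its unsupervised
share under shuffling by design — the null that *should* collapse is the
supervised one. Test problem sizes (matrices around 200 × 1000, five seeds,
subsampling with B = 4–10) were chosen to make the statistical properties
visible while keeping the whole suite quick to run.

## Known limitations

* DCFE sees only mean shifts; a gene separating classes by variance or shape
  scores near zero.
* Min–max normalization ties each gene's combined score to the cohort of
  genes scored with it; scores are comparable within a run, not across runs.
* The global clustering is computed once on all genes; in very noisy
  matrices the partition may reflect no real structure, in which case CS
  adds noise (set `alpha = 1` to disable it).
* KNN imputation is O(n² p) in the worst case and aimed at moderate
  missingness; it is not a substitute for assay-specific imputation.
* The importance adapter reports xgboost total gain; gain-based importance
  is known to be unstable across reruns with different seeds — which is
  precisely why the package combines it with, rather than replaces, the
  statistical score.
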