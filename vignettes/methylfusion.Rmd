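---
title: "Models and methods in methylfusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in methylfusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylfusion)
```

`methylfusion` analyzes single-nucleus experiments in which DNA methylation,
RNA expression and optionally GpC-labelled chromatin accessibility are
measured in the same cells. This vignette explains the statistical models
behind each stage, the defaults and their rationale, and the numerical
conventions — including the places where the underlying methodology leaves a
genuine design choice, and what we chose.

## Read partitioning

When cDNA is synthesized with 5-methyl-dCTP, every cytosine in an RNA-derived
read survives bisulfite conversion, so its per-read non-CG methylation (mCH)
ratio sits near 1. Genomic reads carry the endogenous background: even in
adult neurons, where mCH is comparatively abundant, read-level mCH stays well
below one half. A read with at least `min_cytosines = 3` CH calls is
classified DNA if mch/ch < 0.5 and RNA if mch/ch > 0.9.

Conventions: ratios exactly at a threshold are *ambiguous* because the
inequalities are strict, and a read with `ch = 0` is ambiguous rather than a
division by zero. Classification is monotone in `mch` at fixed `ch`, and the
partition is exhaustive and exclusive. The asymmetric thresholds make
DNA→RNA errors rarer than RNA→DNA errors, since the lower threshold sits
about ten background standard deviations above the genomic mCH level while
the upper threshold is only a few points below the cDNA level.

## Beta-binomial normalization of methylation rates

Raw rates mc/cov are noisy at low coverage and undefined at zero coverage.
Per cell and per context we fit a beta prior by the method of moments from
the raw rates of covered features (mean $m$, variance $v$):

$$\alpha = m\left(\frac{m(1-m)}{v} - 1\right),\qquad
  \beta = (1-m)\left(\frac{m(1-m)}{v} - 1\right),$$

then report the posterior rate $(\alpha + mc)/(\alpha + \beta + cov)$
divided by the prior mean $m = \alpha/(\alpha+\beta)$. Cells with noisier raw
rates get weaker priors. A zero-coverage feature equals exactly 1 after
normalization, low-coverage features shrink toward 1, and at high coverage
the value tends to $(mc/cov)/m$ — the prior washes out. The method of
moments is invalid when $v \ge m(1-m)$ (α would be non-positive) or $v = 0$;
both raise classed errors rather than returning garbage.

Two choices the methodology leaves open, and ours: prior fitting uses only
features with coverage (zero-coverage features carry no rate information),
and priors are fitted *after* feature filtering, so blacklisted or
extreme-coverage bins do not perturb $m$ and $v$.

## Highly variable features

Dispersion (variance/mean of the normalized rate) depends on both the mean
methylation level and the coverage of a feature, so features are assigned to
a 2-D grid of (mean rate × mean coverage) bins — default 20 × 5, a grid the
source methodology does not specify — and dispersions are z-scored within
each bin. Bins with a single feature contribute z = 0 (a z-score over one
value is undefined). The top 3000 features by normalized dispersion are kept
by default; ties break by ascending feature index for determinism. Selected
features are z-scored per feature and embedded by PCA; the component count
is an explicit parameter (default 20) because elbow inspection of the
variance ratio is inherently manual.

## NOMe-seq binarization and LSA

GpC methyltransferase marks accessible chromatin, so a 5-kb bin's GmCY count
in one cell is modelled as Binomial(cov, global) under the null of no
enrichment, with `global` the cell's genome-wide GmCY level. We compute the
probability of *equal or greater* methylated calls than observed — the
survival function evaluated at observed − 1, an inclusive tail, so zero
observed calls give p = 1 — and call the bin open when p < 0.05. With the
open rate equal to the global rate the marginal open fraction stays at or
below the nominal level (binomial discreteness makes the test conservative).

The binary matrix is embedded by latent semantic analysis with log term
frequency: keep bins open in more than 10 cells, drop bins with z-scored
column sum ≥ 2 (z computed after the min-cells filter; the order of the two
filters is a design choice), row-normalize to B, transform
$C_{ij} = \log(B_{ij}+1)\,\log(1 + N/\mathrm{colsum}_j)$, and take the first
15 left singular vectors. Sign convention: each singular vector's
largest-magnitude element is made positive. Vectors are returned unscaled by
default with a σ-scaling option.

## Consensus clustering

Leiden clustering is stochastic, so we run it `n_runs = 200` times (seeds
seed..seed+n_runs−1) on one KNN graph (k = 25 by default; the methodology
uses 20–25 depending on the dataset) and summarize disagreement as a
Hamming distance: the fraction of runs in which two cells get different
labels. This distance is label-permutation-safe and a pseudometric in [0,1].
Outlier-aware density clustering (DBSCAN, min_samples = 5 — a default the
methodology does not state) over an epsilon grid (50 values in (0,1])
produces candidate consensus versions spanning coarse to fine.

Each version is scored by a supervised reproducibility contract: hold out a
stratified 10%, run recursive component elimination under 10-fold
cross-validation with a class-imbalance-aware random forest (inverse
class-size case weights), and report balanced accuracy on the untouched
holdout. Any conforming class-balanced classifier would do; the random
forest is our choice. Outliers are then assigned their predicted class when
the maximum class probability exceeds 0.5. The final resolution is the
*maximum* satisfying: outliers < 5%, score > 0.95, and mean cells/cluster
≥ 30 (the floor that keeps pseudobulk methylome analyses adequately
covered).

Markers use a one-vs-rest rank-sum test with BH adjustment: RNA markers need
adjusted p < 0.01, log2 fold-change > 1 and AUROC > 0.8; methylation markers
reverse the direction (hypomethylation) with delta < −0.3, where delta is
the cluster mean minus the mean of the other clusters' per-cluster means.
Clusters with fewer than 10 markers are merged into their nearest centroid
(Euclidean, in the clustering embedding; ties merge into the larger
cluster), and markers are recomputed until all clusters are supported.

## Cross-modal validation

**Co-embedding.** Cells from the two modalities are placed in one space via
the SVD of $XY^\top$ after z-scoring gene columns (genes with zero variance
in either matrix are dropped from both; whether to standardize is not
specified by the methodology, we do). Two further conventions matter in
practice and are ours: (1) methylation is oriented against expression
(max − X) before the decomposition — gene-body mCH is anti-correlated with
transcription, and without the reversal the two cell clouds land
point-symmetrically opposite each other; (2) components are weighted by the
square root of their singular values, so that distances are dominated by
directions of strong cross-modal covariation rather than by noise
components, which all carry equal weight in an orthonormal basis. Both are
defaults with switches.

**Over-splitting.** For cluster $C$, every member's $|C|$ nearest cells in
the other modality (its k-partners) are inspected:
$S_{over}(C) = 1 - |C|^{-2}\sum_{i\in C}\sum_{j\in P_i(|C|)}
\mathbf 1[\mathrm{label}_j = C]$. 0 means the cluster is cross-modally
stable; a homogeneous cluster randomly split in half scores ≈ 0.5 because
partners distribute themselves over both halves by exchangeability.

**Under-splitting.** A cell's self-radius $r_i$ counts cross-modal cells
strictly closer to its X-profile than its own Y-profile. In a homogeneous
cluster, normalized radii $r_i/|C|$ are uniform on [0,1];
$S_{under}(C) = P(r/|C| \le q)/q$ with $q = 0.25$ is the CDF slope there —
1 for an ideal cluster, > 1 when the cluster hides substructure. The printed
form of this score in the source methodology divides by $|C|/4$ directly,
which is inconsistent with its stated ideal value of one; we use the
normalized-radius reading, which reconciles the formula with the text. The
ideal reference is built by permuting each gene column independently within
each cluster and modality: per-gene cluster marginals are preserved exactly
while per-cell cross-modal coupling is destroyed.

**Cluster number by cross-validation.** Cells are clustered on one modality
(Leiden on top-20 PCs) at several resolutions; centroids of the *other*
modality are estimated on training folds and held-out cells are scored by
MSE against their centroid. Training error decreases monotonically with
granularity; test error is minimized near the true population count. The
default protocol is 5 clustering seeds × 5-fold CV (a 10 × 3 variant is a
parameter change away). AIC and BIC come from a Gaussian cell-around-centroid
model: $\mathrm{AIC} = \mathrm{mse} + 2d\sigma^2/N$,
$\mathrm{BIC} = \mathrm{mse} + \ln(N)\,d\sigma^2/N$, with $d$ the cluster
count and $\sigma^2$ the dataset variance under a single-cluster assumption,
estimated as the mean per-feature variance (the methodology says only
"variance of the dataset"). Because $\ln N > 2$ for $N > e^2$, BIC's optimum
never exceeds AIC's on a convex error curve.

## Fusion

Within-modality smoothing builds
$W = pI + (1-p)\,\tilde A$ where $\tilde A$ row-normalizes the additively
symmetrized Gaussian-kernel KNN matrix
($A_{ij} = \exp(-d_{ij}^2/\sigma_i^2)$, $\sigma_i$ = distance to the
ka-th neighbor; k = 30, ka = 5). $p$ = 0.9 for methylation (sparser, needs
more self-weight) and 0.7 for RNA. Duplicate points ($\sigma_i = 0$) fall
back to the smallest positive neighbor distance with a warning.

Restricted k-partners avoids hub cells: in each of $k$ rounds, source cells
are visited in a fresh seeded random order and greedily take their nearest
*eligible* target; a target that reaches
$k' = \lceil z\,k\,N_{src}/N_{tgt}\rceil$ partners leaves the pool. With
z = 1 every target ends with $k'$ or $k'-1$ partners; the default z = 3
allows a target at most three times the average load. Distance ties break by
ascending target index, sources never reuse a target, and the lazily
advancing preference pointers are exact (verified against a brute-force
rescan oracle in the tests). Imputation is the unweighted partner mean.

`fuse_datasets` chains the steps: shared genes → orientation → smoothing →
CCA (50 components) → RKP → imputation → PCA (50 components) of the stacked
measured + imputed target-modality features → Leiden. The imputation
direction defaults to imputing into the larger modality (ties make the
methylome the target). Fusion quality uses the rank self-radius: the rank
$d$ of a cell's second profile among all $2N$ joint rows (self excluded,
ranks from 1, ties counted optimistically), normalized as $d/2N$; cells
above 0.3 count as mis-fused. Co-cluster accuracy bisects the Leiden
resolution (20 iterations, geometric midpoint) to hit a target cluster
count and reports the fraction of cells with both profiles co-clustered.
Label transfer gives a source cell the label carried by at least half of its
partners, with exact ties broken by global partner support then
lexicographically.

## Coupling

Per gene, Spearman correlation between normalized gene-body mCH (rate over
the cell's global mCH) and log₁₀(TPM+1) expression across cells. The null
shuffles the *cell correspondence* between the modalities (one permutation
per shuffle, shared across genes), which preserves each modality's
gene–gene structure. The empirical FDR of threshold $t$ (negative
direction) is the mean null count of genes with ρ ≤ t over the observed
count; per-gene q-values are monotonized across thresholds (the estimator
itself is a design choice — the methodology states only "empirical FDR"),
which guarantees that the significant set at FDR 0.01 nests inside the set
at 0.05. Defaults: 100 shuffles, one-sided negative. η² per gene is
SS_between/SS_total with size-weighted cluster means; genes with zero total
variance report 0 with a flag.

## The synthetic generator

`generate_multimodal` emulates the statistical structure the toolkit
assumes: cells in `n_clusters` balanced populations; RNA counts
negative-binomial (dispersion 0.5) around cluster-specific log-normal means;
methylation counts beta-binomial (concentration 100) around
(per-cell global mCH × cluster-specific gene factor) with globals uniform
on [0.02, 0.06] — the range typical of neuronal non-CG methylation — and
Poisson coverage (mean 100, comfortably above the > 20 coverage filter the
coupling analysis applies). For a `coupled_fraction` of genes the
methylation factor is a decreasing logistic transform of the standardized
per-cluster log-expression effect, bounded in [0.1, 1.9] so that fractions
stay in (0,1) and the marginal methylation rate stays at the cell's global
level; at these defaults the median planted Spearman correlation is about
−0.4. A further 30% of uncoupled genes receive *independent* cluster
structure in each modality, so clusterings exist in both modalities even
with no cross-modal signal. `generate_reads` draws per-read mCH ratios from
Beta(50, 1) (RNA) and Beta(2, 48) (DNA) — safely on either side of the
0.5/0.9 thresholds — with a `hard` mode (Beta(19, 2) vs Beta(5, 5)) that
narrows the gap to stress the classifier, and Poisson cytosine counts
(mean 15). `generate_nome_counts` plants disjoint per-cluster open-bin sets
with a five-fold elevated GmCY rate.

What the generator does *not* emulate: genomic sequence context and
bisulfite conversion chemistry, coverage that varies systematically along
the genome, batch effects, doublets, or the deep cluster hierarchies of real
brain atlases. Passing tests therefore demonstrate correctness of the
algorithms under the stated models, not robustness to every artifact of
real data.

## Problem sizes and determinism

The test suite and the acceptance script run on simulations of 200–600 cells
and 400–1000 genes with reduced ensemble sizes (25–50 Leiden runs, 30–100
null shuffles) — sizes at which every behavior under test is already
unambiguous, chosen so the whole suite completes in well under a minute.
All stochastic steps take explicit integer seeds and restore the caller's
RNG state; identical seeds give bitwise-identical results.

## Known limitations

* Dense distance matrices bound practical problem sizes to a few thousand
  cells per modality; the algorithms themselves are not the bottleneck.
* The supervised evaluator is one conforming implementation of the
  evaluation contract; absolute scores can shift slightly with a different
  classifier even though the selection logic is unchanged.
* Empirical FDR resolution is limited by the number of shuffles (1/100 at
  the default); raise `n_shuffles` for small gene sets.
* `eta_squared` is the plain one-way variance fraction; it is biased upward
  at small cluster sizes (null expectation (k−1)/(n−1), which the tests
  verify rather than correct).
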