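---
title: "Spatial information gain for survey subgroup discovery: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial information gain for survey subgroup discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigroi)
```

# The problem

Vaccination-attitude surveys measure perceptions — hesitancy toward the
vaccine itself, trust in doctors, pharmacists, and public health
authorities — on batteries of Likert items, alongside an ordinal outcome
(the number of vaccine doses received, 0 through 5 with the open-ended top
category capped) and demographics. Aggregate models answer *which
perceptions predict doses on average*. The question this package targets is
different: *where in the population do specific perceptions sharply separate
vaccinated from unvaccinated respondents*? Respondents who share a
perception profile with highly vaccinated peers, yet report few or no
doses, are the natural audience for targeted outreach, and the factor that
separates them from those peers names the concern an intervention should
address.

The pipeline has six stages: (1) ingestion with reverse scoring; (2)
correlation-based factor extraction per scale; (3) a 2D latent projection
of respondents from their factor scores; (4) a per-grid-cell spatial
information gain (SIG) signal with Gaussian interpolation and
region-of-interest (ROI) extraction; (5) per-ROI profiling by factor–dose
correlation and chi-square demographic disparity; (6) a regression
benchmark with feature-importance and Shapley attribution. A seeded
synthetic-survey generator with planted ground truth makes every stage
testable without access to any particular cohort.

# Factor extraction

Items are first reflected onto a common direction (`reverse_score()`:
`v -> min + max - v` per scale; an involution). For each scale the pairwise
Pearson correlation (PCC) matrix is computed and items are agglomerated by
Ward's minimum-variance linkage on the dissimilarity

$$d(i,j) = 1 - \mathrm{pcc}(i,j).$$

The `1 - pcc` transform is the standard choice for correlation matrices and
keeps $d \in [0, 2]$; the linkage is the Lance–Williams recursion on squared
dissimilarities (`hclust` method `ward.D2`, the convention of the common
Python implementations), and the tests pin it to an independent hand
recursion.

**Cluster quality.** Two families of statistics grade a candidate partition
at each cluster count $k \in \{2, \dots, 8\}$:

* a *centroid silhouette*: each item is represented by its row of the
  dissimilarity matrix (so that cluster centroids are well defined in a
  space items actually inhabit; a classical-MDS embedding is available as
  an alternative via `coords = "cmdscale"`), and
  $$s(i) = \frac{b(i) - a(i)}{\max\{a(i), b(i)\}},$$
  with $a(i)$ the Euclidean distance to the item's own cluster centroid
  and $b(i)$ the smallest distance to another centroid. Items in singleton
  clusters are assigned $s(i) = 0$ — the centroid of a singleton is the
  item itself, and the naive value $s = 1$ would reward fragmentation.
* *within-cluster PCC statistics*: per cluster, the mean, minimum, and
  variance of the off-diagonal within-cluster correlations.

**Choosing k.** A candidate $k$ is *admissible* when the mean silhouette
reaches `sc_min` (default 0.25, the customary "weak structure" cutoff) and
every cluster's within-cluster PCC statistic reaches the scale's
`pcc_floor`. The floor applies to the per-cluster *mean* pairwise
correlation by default; `floor_stat = "min"` switches to the minimum
pairwise correlation, since published summaries of this criterion are
ambiguous between the two readings. Among admissible $k$ the package
selects the one *maximizing the mean silhouette* — the cluster-wise score
is defined as the maximum over $k$ of the mean item silhouette — with ties
broken by the smaller within-cluster PCC variance summed over clusters,
then by the smaller $k$. The silhouette, not the variance, must lead this
choice: splitting a genuine item block leaves the sub-blocks' centroids
nearly coincident, which drags the silhouette down at over-fragmented $k$,
whereas the within-cluster variance keeps *decreasing* past the true $k$
(sub-clusters of a homogeneous block are, if anything, slightly more
homogeneous). In simulation the silhouette peaks exactly at the planted
cluster count while a variance-minimizing rule systematically inflates $k$.
When no $k$ is admissible the scale is reported as such, with the full
per-$k$ quality table, and the pipeline continues without its items.

Factor scores aggregate each cluster's (reverse-scored) item responses per
respondent. The default aggregator is the mean, which is invariant to
cluster size and keeps 4-point and 5-point scales on their native ranges;
`"sum"` is available. Factor identifiers are scale-prefixed cluster indices
(`C-c1`, …); a user-supplied label map can annotate them (the package does
not attempt automated annotation — labels are the analyst's call).

# Latent projection and grid

Respondents are projected to 2D from their factor-score profiles,
z-scoring the columns first (default on) so 4-point and 5-point scales
contribute comparably. The default method is UMAP run single-threaded
under a fixed seed (15 neighbors, minimum distance 0.1, Euclidean metric,
seed 42) — the source publications of this family of methods rarely state
these hyperparameters, and results on real data do depend on them, so all
are exposed in the configuration and recorded in outputs. The projection
is pluggable: `method = "pca"` gives a deterministic, closed-form
projection that the validation suite uses for speed and reproducibility of
its geometric arguments.

A square grid with step 0.5 (embedding units) spans the exact coordinate
extrema. Cells are half-open `[edge, edge + step)` except the last in each
axis, which is closed at the top; a coordinate exactly on an interior edge
belongs to the higher cell. Every respondent therefore lands in exactly
one cell.

# Spatial information gain

Within one cell with member set $I$, conditioning a factor at its
cell-local median (ties to the low group, deterministically) defines a
binary variable $A$; the signal is the expected Kullback–Leibler
divergence of the conditional dose distribution from the cell's marginal
dose distribution,

$$\mathrm{SIG} = \sum_{a} P(a)\, D_{\mathrm{KL}}\!\left(P(X \mid a)\,\Vert\, P(X \mid I)\right) = I(X; A),$$

in nats — the plug-in mutual information between the dose $X$ and the
binarized factor over the cell's members. The choice of conditioning
variable is the central interpretive decision of the spatial stage: a
KL-based gain needs *some* conditioning event, and the cell-local median
split of one factor yields one signal map per factor (matching the
observation that each factor's spatial signal is heterogeneous), whose
expectation form is exactly plug-in mutual information — nonnegative, and
zero under independence or a constant dose. The prior is the *cell-local*
dose distribution, so the posterior's support is contained in the prior's
and the divergence is always finite (a global-prior variant would risk
infinities for cells containing dose values rare elsewhere).

**Occupancy floor.** Plug-in mutual information is upward-biased in small
samples — roughly $(r-1)(c-1)/(2n)$ nats for an $r \times c$ table with
$n$ members — and the per-factor maps are *summed* over all factors, which
multiplies the bias by the factor count. Cells below `min_cell_members`
(default 5) are therefore assigned zero signal. The default floor is
deliberately permissive; for cohorts of a few thousand respondents the
validation suite uses a floor of 75, chosen so that the worst-case
aggregate bias ($16 \times (c-1)/150$ nats) stays well below the
$\ln 2 \approx 0.693$ ceiling of a genuine perfect split. Analysts should
scale the floor with their cohort density.

Per-factor maps are aggregated by an unweighted element-wise sum (weights
are exposed), and the aggregated surface is interpolated with an
unnormalized Gaussian kernel,

$$h(p) = \sum_{v} h_v \, \frac{1}{\sqrt{2\pi}\,\sigma} \exp\!\left(-\frac{\lVert p - v\rVert^2}{2\sigma^2}\right),$$

with $\lVert p - v \rVert$ the Euclidean distance between cell centers in
embedding units and $\sigma = 1$ by default (so the kernel reaches across
two cells at the default step). The operation is linear in the raw signal.

**ROI extraction.** The smoothed surface is thresholded at
$c = 0.34 \cdot \max h$; contour levels at 0%, 17%, 34%, and 51% of the
maximum are reported for the functional contour map. Supra-threshold cells
are labeled by 8-connected components; every component holding at least
`min_roi_members` respondents (default 10, to avoid singleton subgroups)
becomes an ROI with its dose mean ± SD. ROIs are numbered by decreasing
peak smoothed signal — subgroup *strength*, not size. The cutoff is
applied to the smoothed surface (it is defined on the interpolated
signal), while the permutation diagnostic below is computed on the
aggregated, unsmoothed matrix, whose maximum is the quantity the null
actually perturbs; smoothing sums small biases over contiguous regions and
would conflate extent with strength.

# ROI profiling

Within each ROI, every factor is screened by the Pearson correlation of
its scores with the dose over ROI members; $|\mathrm{pcc}| \ge 0.2$ (the
customary "at least weak correlation" threshold) flags a factor. Constant
factors or a constant dose make the correlation non-computable; such
factors are reported but never flagged.

Demographic disparity uses the chi-square goodness-of-fit test: expected
counts are the whole-cohort category proportions (including the ROI's own
members) times the ROI size; categories with expected count below 5 are
pooled into an "other" bucket until all expectations reach 5 — the
standard validity condition for the chi-square approximation; if fewer
than two categories survive, the variable is untestable for that ROI. The
statistic is $\chi^2 = \sum_i (O_i - E_i)^2 / E_i$ with $k - 1$ degrees of
freedom over the $k$ post-pooling categories. Significance is raw
$p < 0.05$ by default, matching the practice of screening a dozen
variables across a handful of ROIs without correction; a
Benjamini–Hochberg adjustment is available (`p.adjust`) for analysts who
prefer it. Stars follow the usual convention: `-`, `*`, `**`, `***` at
$p \ge 0.05$, $< 0.05$, $< 0.01$, $< 0.001$. Profiles bundle the dose
mean ± SD, flagged factors, and ROI-vs-cohort category proportions
(pie-chart data) for the significant variables.

# Dose regression benchmark

The suite treats the dose as a numeric target (0–5) — the regression
framing is deliberate; no ordinal link is fitted. Respondents are split
70/30; tunable settings (penalized-regression $\lambda$, tree pruning) use
10-fold cross-validation within the training split; all six metrics are
computed on the held-out test set; a mean-prediction dummy baseline is
always included (its test $R^2$ is nonpositive by construction). The
default model list covers the six conventional families available in this
environment: linear, ridge/lasso/elastic net, a Huber M-estimator, a
pruned decision tree, k-nearest-neighbors, a random forest, extremely
randomized trees, and gradient boosting. The list is configuration-driven,
so an environment lacking a given learner simply runs without it (a fitted
model that errors is skipped with a warning).

Two metric conventions deserve attention:

* **RMSLE** requires nonnegative predictions; predictions are clipped at 0
  before `log1p`.
* **MAPE** is undefined at dose 0 — typically a large share of a hesitant
  cohort. The default computes the mean absolute percentage error over
  respondents with dose ≥ 1 only, which *materially affects comparability*
  with reports using other conventions; a symmetric variant over all
  respondents is available (`mape_symmetric = TRUE`).

Predictor ranking fits a random forest per resampling seed (ten seeds by
default) and ranks factors by (a) impurity-reduction feature importance
and (b) mean absolute Shapley attribution over a sample of test rows,
estimated by the permutation-sampling Monte-Carlo method (unrevealed
features imputed from training rows; all model evaluations batched).
Stability is each factor's frequency in the top five across seeds.

# The synthetic-survey generator

The generator emulates the structure the pipeline is designed to detect,
with full ground truth:

* **Item clusters.** Each scale is a set of planted clusters; each item is
  `loading × cluster latent + independent noise`, discretized at
  equiprobable normal cutpoints into the scale's Likert range. Because
  discretization attenuates correlations, the configured `within_pcc` and
  `between_pcc` are *post-discretization* targets: loadings are calibrated
  by numerically inverting the exact discretized-bivariate-normal
  correlation map (`likert_corr()` / `calibrate_latent_corr()`, a 1D
  quadrature plus root-finding), which lands realized correlations within
  about ±0.005 of target at large n. Between-cluster correlation within a
  scale comes from a shared scale-level component. A configurable fraction
  of items per scale is stored reflected, so `reverse_score()` genuinely
  has work to do.
* **Dose.** A clipped, rounded linear combination of the latent factors
  plus Gaussian noise, capped to 0–5.
* **Planted subgroups.** Each subgroup is compact in factor space
  (a center profile plus small spread, optionally with *radial* scatter —
  members sharing the profile direction but differing in its intensity —
  so the subgroup spreads along its own offset axis in the embedding
  rather than along any single factor). Its dose rule overrides the
  background: members above the subgroup median of the designated driving
  factor receive dose 5, the rest dose 0, with probability `strength`.
  A `driver_gap` makes the driving factor bimodal within the subgroup,
  which keeps the split observable in the discretized items.
* **Demographics.** Categorical variables drawn from cohort distributions,
  with per-subgroup overrides (e.g., an older, differently affiliated
  subgroup) — a distribution-shift model, sufficient for validating the
  disparity stage, not a causal one.

The default configuration mirrors the study conditions the package was
built around: 1020 respondents; four scales of 25/30/15/15 items with
4/5/3/4 planted clusters (16 factors over 85 items); 5-point ranges except
a 4-point final scale; within-cluster correlation targets 0.75/0.65/0.55/
0.65 sitting above the pipeline's default per-scale floors of
0.7/0.6/0.5/0.6 with sampling margin; between-cluster correlation 0.15; a
dose model yielding a cohort mean near 1.5; and one planted subgroup (12%)
enriched for older and differently affiliated respondents.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: real item wording and its semantics,
respondent-level response styles (acquiescence, straight-lining),
missingness and attention-check failures, quota sampling, cluster overlap
(each item loads on exactly one latent), and any causal demographic
structure. Recovery results certify the machinery, not the
substantive findings on any particular cohort.

# Validation design and problem sizes

The test suite validates each stage against independent oracles (a
brute-force mutual-information double sum; the textbook chi-square formula
plus distribution tail; a hand Lance–Williams recursion; hand-computed
metric formulas) and analytic limits (a perfect within-cell split gives
exactly $\ln 2$; a unit impulse smooths to $1/\sqrt{2\pi}$ at the source
and $e^{-1/2}/\sqrt{2\pi}$ at unit distance; smoothing is linear to
$10^{-9}$).

Recovery and calibration use these problem sizes, chosen to make the
statistical claims sharp at desk scale:

* *Item-structure recovery*: the default 85-item, 16-cluster layout at 600
  respondents, 25 seeds; the combined partition must reach ARI ≥ 0.9.
* *ROI recovery*: `roi_benchmark_config()` — 3000 respondents, a 12%
  planted subgroup, near-constant background dose (the planted contrast is
  precisely "high dose variance inside, low outside"), analyzed with the
  PCA projection and a cell floor of 75; the top ROI must reach Jaccard
  ≥ 0.8 against the planted membership with the driving factor flagged, in
  ≥ 80% of 25 seeds. The benchmark's geometry is deliberate: the subgroup
  is offset on every factor *except* its driver, because variation in the
  driver necessarily leaks into the embedding position, and a large
  driver gap would sort the two perception modes into different grid
  cells, destroying the very signal the method measures. The modest gap
  (0.5 latent units) keeps both modes within each occupied cell while the
  discretized items still separate them.
* *Calibration*: the disparity test's type-I rate over 1000 null ROIs
  (80 of 2000) must lie in 0.05 ± 0.02; globally permuting doses must at
  least halve the maximum aggregated signal (median over 25 permutations).
* *Regression sanity*: with dose linear in three of sixteen factors plus
  small noise, the linear model must reach test $R^2 \ge 0.9$ and the
  dummy $R^2 \le 0$, and the three planted factors must occupy the Shapley
  top five in at least 8 of 10 resampling seeds. These checks run on the
  generator's *latent factor values*, isolating the regression stage:
  through the full item chain the linear $R^2$ plateaus near 0.85–0.89
  regardless of signal strength, because dose rounding/clipping and
  factor-score measurement attenuation (score–latent correlation ≈ 0.95)
  cap it — an attenuation statement about Likert measurement, not about
  the regression code. The item-to-score chain is certified separately by
  the recovery criteria.

# Numerical choices and degenerate inputs

* Logarithms are natural (nats) throughout the information-theoretic code,
  with the $0 \log(0/q) = 0$ convention.
* Median ties in the factor binarization go to the low group.
* A degenerate split (all members on one side) or a constant dose yields a
  signal of exactly 0, not an error; an all-zero surface yields an empty
  ROI list.
* Grid construction guards exact-multiple ranges with a $10^{-9}$ slack so
  the top edge closes rather than opening a spurious empty cell.
* PCA projections fix component signs (largest-magnitude loading positive)
  so coordinates are reproducible across item orderings.
* The smoothing kernel measures distances between cell centers in
  embedding units, not cell indices: $\sigma = 1$ spans two cells at the
  default step of 0.5.
* All randomness flows from configuration seeds (generator seed, embedding
  seed, split seed, ranking seeds); two runs with equal configurations
  produce identical outputs, and the run manifest records every seed.

# Known limitations

* The spatial signal inherits plug-in-MI small-sample bias; the occupancy
  floor controls but does not remove it, and dense low-signal regions can
  accumulate smoothed bias. Inspect the aggregated (unsmoothed) surface
  alongside the smoothed one.
* The 34% cutoff and the smoothing scale jointly determine ROI extent;
  neither has an inferential justification — they are screening
  conventions, and downstream profiling (not the cutoff) carries the
  statistical weight.
* Embedding hyperparameters materially shape ROIs on real data and are
  not identifiable from any published convention; treat ROI geometry as
  exploratory unless it survives seed and hyperparameter perturbation.
* MAPE's dose ≥ 1 convention, and the regression framing of an ordinal
  outcome, limit comparability with other reports.
* The disparity tests are unadjusted for multiplicity by default.
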