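---
title: "Embedding dynamic connectivity networks on a 2D manifold: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Embedding dynamic connectivity networks on a 2D manifold: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the pipeline

A dynamic functional connectivity analysis turns each subject's scan into a
*series* of networks: a window of `W` consecutive volumes slides across the
ROI time series in steps of `shift`, and within each window the Pearson
correlation between every pair of ROI signals defines one weighted, fully
connected network. A study with dozens of subjects, several conditions and
>100 windows per scan therefore produces thousands of networks with tens of
thousands of edges each. `netmanifold` implements a manifold-embedding
approach to this data volume:

1. **Vectorize and stack.** Each symmetric `n x n` network is reduced to its
   strict upper triangle (length `n(n-1)/2`; 35,778 edges for the 268-node
   atlas geometry) and all networks of all subjects are stacked row-wise
   into one matrix, subjects in manifest order and windows in temporal
   order.
2. **Reduce.** PCA on this stack yields component weights per network.
3. **Embed in 2D** by one of three methods: the first two component weights
   plotted directly (`pca2`), t-SNE on the first two weights (`tsne2`), or
   t-SNE on all weights needed to capture 99% of the variance (`tsne99`).
4. **Analyse** the embedded points: RBF-SVM classification of conditions or
   groups with subject-grouped subsampling and majority voting; spatial
   clustering ratios with permutation tests; and one-to-one back-mapping
   from any embedded point to its full network for thresholded display and
   graph summaries.

Every stacked row keeps its (subject, condition, window) identity, so the
map between a 2D point and its high-dimensional network is exact and
bit-reproducible — this is the property that distinguishes the approach
from density- or state-clustering methods.

## Window arithmetic

`count_windows(T, W, shift)` returns `floor((T - W) / shift)`. This
convention reproduces the reference geometry (187 volumes, a 60-volume
window and shift 1 give 127 networks) and is therefore adopted throughout,
although the count of *possible* start positions would be `T - W + 1`. The
last start position is deliberately unused; with `T < W + shift` the series
is rejected by name. Censored series are windowed over their retained
volumes as a contiguous sequence — a 120 s window absorbs isolated dropped
volumes without creating gaps — and the surviving original volume indices
remain in the series metadata.

The upper-triangle ordering is fixed to row-major (`(1,2), (1,3), ...,
(1,n), (2,3), ...`). PCA and t-SNE are invariant to this choice (tested via
the variance spectrum under column permutation), but back-mapping requires
one canonical order, so it is part of the contract.

## The synthetic cohort generator

Real multi-subject fMRI of this kind is shared only on request, so the
package carries a first-class generator whose ground truth is known by
construction. It emulates, at desk scale, the features the pipeline is
sensitive to:

- **Block covariance.** ROIs are partitioned into `n_blocks` contiguous
  communities; within-block correlation defaults to 0.5 and between-block
  baseline to 0.1 — values in the range typically reported for band-passed
  BOLD parcel signals.
- **Condition and group effects.** The condition effect is added to all
  edges between blocks 1 and 2, the group effect to the (disjoint) edges
  between blocks 1 and 3. Effects are graded by label order (with
  conditions `c_1..c_K`, condition `c_j` adds `(j-1)/(K-1)` of the effect),
  emulating a graded task load. The placement is a stipulation — the
  distributional structure of real task effects is not characterised — but
  it is fixed and documented so tests are reproducible.
- **Subject heterogeneity.** Each subject x condition target receives a
  symmetric Gaussian perturbation (`subject_sd`, default 0.05) of all
  off-diagonal entries, then is repaired to the nearest correlation matrix
  by eigenvalue clipping at zero and diagonal re-standardisation. One
  clipping pass suffices because the diagonal congruence of a PSD matrix is
  PSD; alternating projections would be overkill at this scale.
- **Temporal autocorrelation.** Series are stationary Gaussian AR(1)
  processes with the target cross-correlation and per-ROI lag-1
  autocorrelation `ar_coeff` (default 0.6, a documented stand-in for
  0.009–0.08 Hz band-passed signal at a 2 s sampling interval — not a
  haemodynamic simulator). Innovations are scaled so marginal variances are
  exactly 1; correctness is checked by Monte-Carlo at `T = 50,000`.
- **Volume censoring.** `floor(censor_fraction * T)` volumes are dropped
  uniformly at random per series, mimicking motion scrubbing.

Per-series seeds are derived by a string hash of
`(seed, group, condition, subject index)`, so adding subjects or conditions
never changes existing subjects' data, and the whole cohort is a pure
function of its spec (asserted bit-identically in the tests).

What the generator does **not** emulate: haemodynamic response shape,
scanner noise spectra, motion artefacts correlated with the task, spatial
autocorrelation of parcels, or non-stationarity of the "true" connectivity
within a scan. Passing recovery tests on this generator therefore shows
that the pipeline's statistics behave correctly when their assumptions
hold; it does not certify performance on real BOLD data.

## Embedding

PCA is computed once on the full stack, by eigendecomposition of the
smaller Gram matrix (`X X'` when edges outnumber networks — the intended
route at 35,778 edges — otherwise `X'X`). Component signs are fixed by
making each component's largest-magnitude loading positive. Centring uses
the full stack *before* any train/test split: unsupervised dimension
reduction prior to partitioning does not leak label information into
held-out subjects, and the classification stage relies on this documented
contract.

t-SNE minimises the KL divergence between perplexity-calibrated Gaussian
affinities and the 2D Student-t kernel. The optimiser is the exact
(`theta = 0`) implementation from the Rtsne package; hyperparameters
default to perplexity 30 and 1,000 iterations — the common practice for
the algorithm, since no values are dictated by the method itself — and
both are exposed. Initialisation is from the standardised first two
component weights scaled to sd `1e-4`, plus seeded Gaussian jitter of sd
`1e-6`: the PCA start stabilises replicates, the jitter keeps replicate
seeds meaningful and separates exact duplicates, and a fixed seed gives
bit-identical coordinates. Replicate `r` of `run_replicates()` uses seed
`base_seed + r - 1`; downstream reports average over replicates because
t-SNE is stochastic by design.

`embed_linear()` refuses effectively rank-1 input, and `embed_tsne()`
enforces `N > 3 * perplexity` with the bound in the error message.

## Classification protocol

Splits are drawn at the *subject* level (68% train by default), so all
points of a subject — both condition series in a task contrast — are on one
side; stratification by group keeps class proportions on both sides. Train
size per class is rounded to the nearest integer with ties toward train.
Within each training set, `(cost, gamma)` are chosen by subject-grouped
5-fold cross-validation over a grid, ties broken toward smaller cost then
smaller gamma; the default grids are the canonical libsvm recommendations
(`2^-5..2^15`, `2^-15..2^3`). Class weights default to
`n_total / (2 * n_c)`, up-weighting the minority class. Each test series is
labelled by majority vote over its points; an exact tie falls back to the
sign of the mean decision value, a rule the bare ">half" criterion leaves
open. Sensitivity treats the first-listed class as positive. Splits are
re-randomised across t-SNE replicates rather than reused — the protocol
does not pin this down, and independent splits give the more honest spread
estimate.

Coordinates are z-scored per axis before the SVM. Embedding scale is
arbitrary (t-SNE output units mean nothing), and standardising makes one
gamma grid meaningful across embedding methods; like the PCA, this is an
unsupervised transform computed before any split.

Boundary maps label every cell of a grid (default 100 x 100 with a 5%
margin) with each split's trained model; a cell is a boundary cell for a
split when any 4-neighbour has the opposite label, and the map reports the
fraction of splits marking each cell.

## Clustering statistics

The distance between two embedded series is the mean Euclidean distance
over all cross pairs of their points; within a series, the mean over
unordered pairs. The task/group ratio divides the mean within-label series
distance by the mean between-label distance; pairs of series from the same
subject are excluded from the within average (in a paired design the two
conditions of one subject would otherwise leak into "within task"). The
individual ratio divides mean within-series distance by the mean
between-series distance. Both ratios are scale-invariant (tested).

Permutation tests are one-sided (smaller ratio = stronger clustering) with
`p = (1 + #{permuted <= observed}) / (1 + n_perm)`; the +1 correction
avoids p = 0. At the task/group level, labels are permuted across series.
At the individual level, points are reassigned to series within label
strata, preserving every series size so only the assignment, not the
geometry, is randomised. The permutation scheme and count (default 1,000
in the shipped analyses; the functions accept any `n_perm >= 99`) are
package stipulations, flagged here because the underlying protocol leaves
them open. Calibration is tested: under exchangeability the p-values are
uniform (KS check over 200 null repetitions).

For replicate embeddings, ratios are computed per replicate and reported
as mean ± SD; the linear embedding is deterministic and reports no SD. The
reported p-value for a replicate set is the mean of per-replicate
permutation p-values. Method comparisons use two-sample t-tests between
replicate samples and one-sample t-tests against scalar (linear) ratios,
Bonferroni-corrected over the comparisons performed.

## Back-mapping and graph summaries

`lookup_network()` inverts the stack row of any embedded point exactly.
For display and summaries, `threshold_top_edges()` keeps the
`ceiling(fraction * m)` strongest edges — by *signed* value by default
(the hub-display convention; `mode = "absolute"` is available), 537 edges
at 1.5% of the 268-node geometry. Graph metrics are computed on the
thresholded nonnegative graph:

- **Global efficiency**: mean inverse shortest-path length over ordered
  pairs, edge length `1/weight`, disconnected pairs contributing 0.
- **Local efficiency**: mean over nodes of the global efficiency of the
  open neighbourhood subgraph; nodes with < 2 neighbours contribute 0.
- **Assortativity**: Pearson correlation of binary endpoint degrees over
  edges (both orientations); undefined on regular topologies and reported
  as `NA` with a reason.

Whether published summary tables of this kind use thresholded or fully
weighted signed networks is generally unstated; both the threshold fraction
and the ranking mode are therefore explicit arguments, and series averages
record the per-window values they aggregate. Shortest paths are delegated
to igraph; the metric formulas are implemented here and verified against
brute-force Floyd–Warshall and per-node enumeration oracles on all fixture
graphs with <= 10 nodes.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run the full pipeline on a
positive-control cohort of 2 conditions x 20 subjects, 30 ROIs in 3
blocks, `T = 180`, `W = 60`, shift 2 (2,400 networks, 435 edges), with
condition effect 0.4 — a separation a task-vs-rest contrast of the strong
kind plausibly produces — and a null cohort with the effect set to 0
(windowed at shift 10). These sizes keep a complete run in minutes on one
CPU while leaving every stage nontrivially exercised; they were chosen
once, before the recovery tests were written, and are not tuned to them.
SVM tuning in these runs uses the reduced grids cost {1, 10, 100} x gamma
{0.1, 0.5, 2} on standardised coordinates; the full canonical grids remain
the function defaults.

Other numerical conventions: symmetry tolerance `1e-8` for vectorization;
eigenvalue clipping at 0 with re-standardisation for PSD repair (minimum
eigenvalue after repair asserted >= -1e-8); correlation values clamped to
[-1, 1] against floating-point overshoot; PCA keeps `min(N - 1, m)`
components and fixes signs as above; subject-noise draws clamped to
±0.999 before repair so targets stay inside the open interval.

## Known limitations

- The generator's effect placement and AR(1) temporal model are
  stipulations; real task effects are spatially richer and BOLD noise is
  not AR(1).
- Exact t-SNE is `O(N^2)` per iteration; beyond ~10^4 networks the
  Barnes–Hut approximation (`theta > 0`) should be used.
- Majority voting and the implemented metrics assume binary contrasts;
  multiclass problems are out of scope.
- The clustering p-value aggregation across replicates (mean of
  per-replicate p) is a pragmatic summary, not a combined test.
- Graph metrics on thresholded graphs depend on the threshold fraction;
  values are comparable only at a fixed fraction.
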