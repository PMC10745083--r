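---
title: "Estimating cell-class-specific mesoscale connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cell-class-specific mesoscale connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesoconn)
```

## The estimation problem

Anterograde tracing experiments label the axonal projections of neurons at an
injection site and quantify fluorescence on a 100 μm voxel grid registered to
a common template. Each experiment `i` is reduced to an injection centroid
$c(i) \in \mathbb R^3$, a cell-class label $v_i$ (the transgenic line ×
transgene combination that restricts which neurons express the tracer), and a
regionalized projection vector $y_{\mathcal T}(i) \in \mathbb R_{\ge 0}^T$ —
the projection signal summed within each target leaf of a hierarchical
parcellation, ipsilateral and contralateral instances counted separately.

The quantity of interest is the class-specific regionalized connectivity
$\mathcal C(v, s, t)$ from every source leaf $s$ (one hemisphere) to every
target $t$. Its structural assumptions, which both the estimators and the
synthetic generator embody, are:

1. within a leaf, projections vary *smoothly* with source position;
2. across leaf boundaries, and across cell classes, projections may change
   *sharply*.

Because no survey covers every class in every leaf, estimation must share
information — spatially between nearby injections, and between classes with
similar projection behaviour.

## The cell-class space

`build_class_space()` embeds each class by its averaged regionalized
projection pattern. Rows are unit-sum normalized before averaging regardless
of how the dataset itself is normalized, so the embedding reflects projection
*shape* rather than tracer efficiency or injection size. The class distance
$d_V$ is one minus the cosine similarity of the global class embeddings
(Euclidean distance is available as an option); it is zero between identical
patterns and at most 2. A class left without experiments by a leave-one-out
exclusion is assigned the largest observed distance — a conservative
"maximally dissimilar" default that only matters in degenerate refits.

## Estimators

Four predictor families are provided (`estimator_model()`), differing in what
data they use for a prediction at location $x$ in leaf $l$ of major
division $m$:

| kind | prediction | support |
|------|-----------|---------|
| `nnls` | linear NNLS response to the indicator injection | experiments in $m$ |
| `nw` | Gaussian-kernel average, bandwidth $\sigma_x$ | experiments in $m$ |
| `cre_nw` | Gaussian-kernel average | same-class experiments in $l$ |
| `el` | $\alpha\, m(v,l) + (1-\alpha)\, g(x,v,l)$ | all experiments in $l$ |

The EL blend combines the class-leaf mean projection $m(v, l)$ with a
product-kernel Nadaraya-Watson term
$g = \sum_i K(\|x - c(i)\|/\sigma_x) K(d_V(v, v_i)/\sigma_c)\, y_i / \sum_i(\cdot)$
over all classes in the leaf. Both kernels are Gaussian — the standard
choice for Nadaraya-Watson smoothing, smooth in both arguments. Limiting
behaviour is tested explicitly: $\alpha = 1$ returns the class mean;
$\sigma_c \to \infty$ recovers class-agnostic spatial smoothing;
$\sigma_c \to 0$ concentrates on the same class; $\sigma_x \to \infty$
returns unweighted means. When the class has no centroid in the leaf,
$m(v, l)$ falls back to the global class mean, then to the all-class leaf
mean, so a prediction exists wherever the leaf holds any data — the point of
the estimator is precisely to fill class gaps.

Kernel weights are computed from log-weights shifted by their maximum before
exponentiation, so distant supports and tiny bandwidths underflow gracefully
to a nearest-neighbour limit instead of producing 0/0. Coincident centroids
are used as given; no jitter is added.

## Evaluation and model selection

`loocv_weighted_loss()` scores a model by leave-one-out cross-validation
restricted to (leaf, class) cells with at least two experiments — the
smallest cells for which held-out prediction is defined for every estimator.
For each held-out experiment all data-dependent quantities (class space,
class means, NNLS fits) are recomputed without it. The overall loss

$$\mathcal L = \frac{1}{|\mathcal{SV}|}\sum_{(s,v)}
  \frac{1}{|I_s \cap I_v|}\sum_i \ell_i$$

weights every cell equally, deliberately up-weighting rare (leaf, class)
combinations relative to a per-experiment average. A missing held-out
prediction is replaced by the class-mean fallback chain and counted, never
silently dropped — dropping would flatter models with narrow coverage. If
even the fallback chain is empty the prediction is the zero vector (floored
by the detection limit when one is configured).

`select_hyperparameters()` minimizes this loss over a grid, independently
per major division (predictions in a leaf only ever use data from its major
division, but the class space is global, so selection restricts the
*evaluation cells*, not the data). Ties are broken toward the smoother
model: larger $\sigma_x$, then larger $\sigma_c$, then larger $\alpha$.
Default grids are $\sigma_x \in 10^2\ldots10^4$ μm (7 log-spaced points),
$\sigma_c \in 10^{-2}\ldots10^1$ (7 points, spanning "effectively
class-restricted" to "effectively class-blind" on the cosine scale), and
$\alpha \in \{0, 0.1, \ldots, 1\}$.

One identifiability caveat is worth knowing: with $\sigma_c$ at the bottom
of its grid and $\sigma_x$ at the top, the kernel term $g$ degenerates to
the class-leaf mean, making $\alpha$ only weakly identified exactly when
class structure dominates. The selected $\alpha$ still leans toward 1 in
class-dominated data (the smoother-model tie-break resolves exact
plateaus), and the blend's *predictions* are unaffected by which corner of
the plateau is chosen.

The default detection limit, when enabled, is the 5th percentile of the
positive normalized projection entries of the training data
(`fit_detection_limit()`), configurable to a fixed value.

## Connectivity matrices

`build_connectivity()` assembles the S × T matrix for one class. In
`structure` mode (default) the model is evaluated once per leaf at the leaf
centroid and scaled by the voxel count, $|s|\,\hat f(s)$; `voxel` mode sums
per-voxel predictions and is available where within-leaf gradients matter
(it is checked against an explicit voxel-loop oracle in the tests). The
NNLS baseline's row is its indicator-injection response directly. Three
variants are derived by fixed normalizations: strength $\mathcal C$,
normalized strength $\mathcal C_N = \mathcal C / |s|$, and density
$\mathcal C_D = \mathcal C / (|s||t|)$ with $|s|, |t|$ the source and
target voxel counts.

Rows of source leafs in which the class has no injection centroid are
*missing*, not zero: "not estimated for lack of data" and "no detected
projection" are different statements, and the writers keep them distinct
(empty CSV fields, an explicit `missing` column in the long format). A
class-averaged matrix (`cre_average_matrix()`) ignores missing entries; a
log transform exists only as a display option in the writer and is never
applied to stored values.

`distal_mask()` marks source-target pairs to keep for distal analyses:
pairs strictly closer than the threshold (1,500 μm by default) are removed,
since short-range entries are dominated by injection-site signal and
traveling fibers rather than synaptic targeting. The distance is the
minimum voxel-centre distance by default — border proximity, not centroid
proximity, is what creates those artifacts — with centroid distance
available as an option.

## Masked sparse NMF and stable archetypes

`masked_sparse_nmf()` minimizes
$\tfrac12\|M \odot (C - WH)\|_2^2 + \lambda(\|W\|_1 + \|H\|_1)$ over
nonnegative factors. The mask applies to the *residual*: masked entries of
`C` have zero influence on the fit (asserted in the tests by perturbing
them), rather than being fit toward zero. The solver uses mask-aware
multiplicative updates with the L1 penalty added to the update denominators
— the majorization-minimization form, chosen over subtractive-update
variants because it provably keeps the penalized objective non-increasing
at every iteration, a property the test suite asserts on every fit.
Numerical guards: $10^{-12}$ denominators, `max_iter = 2000`, relative
objective tolerance $10^{-6}$. On output the rows of `H` are
unit-L2-normalized with scale absorbed into `W`; scale/permutation
non-identifiability is handled in all recovery checks by optimal assignment
(`match_archetypes()`) before comparison. The default penalty
$\lambda = 0.002$ favours sparse, interpretable components.

The rank is chosen by unsupervised cross-validation (`select_rank()`):
random subsets of unmasked entries are hidden during fitting and scored by
held-out squared error; ties go to the smaller rank. Because the objective
is non-convex and initialization-sensitive, `stability_archetypes()` pools
unit-normalized components from many random restarts, clusters them by
average-linkage agglomeration under cosine distance (cut at 0.3), ranks
clusters by the number of distinct replicates represented, and reports the
element-wise median of each cluster — the *archetypes* — keeping the top 15
by default.

## The synthetic generator

`make_brain()` builds a block parcellation: each major division is a row of
axis-aligned leaf blocks, mirrored across the lattice midline into two
hemispheres, with a two-level structure graph and annotation volume that
round-trip through the package's JSON/NRRD readers. `sample_ground_truth()`
draws, per leaf, a sparse nonnegative base pattern (gamma draws on a
Bernoulli support, unit-sum) perturbed per class by entrywise log-normal
factors of scale `class_effect`; within-leaf spatial variation is a smooth
positive scalar field (a sinusoid of amplitude `1/smoothness_scale` on the
log scale, wavelength twice the leaf extent). `simulate_experiments()`
draws centroids uniformly in the leaf interior, builds unit-mass Gaussian
injection blobs (sd 1.5 voxels, truncated at the leaf boundary so the
centroid's leaf is unambiguous and blob mass does not confound projection
scale), and emits $y_{\mathcal T}(i)$ as the true projection at the
centroid under entrywise log-normal noise — multiplicative noise matching
the variability of fluorescence intensities. The default noise sd is 0.2.

Because the spatial modulation is a *scalar* field, unit-sum normalization
removes all within-leaf spatial signal from a simulated experiment; studies
of spatial smoothing therefore run on unnormalized strengths. This is a
known simplification: the generator's spatial variation lives in overall
magnitude, not in pattern rotation, so passing tests demonstrate correct
information sharing and bookkeeping, not that real within-leaf pattern
gradients are recovered. The generator also does not emulate imaging
artifacts, traveling-fiber contamination, or segmentation error.

Three canned study conditions (`synthetic_study()`) fix the regimes used in
validation, chosen once to make each regime's structure unambiguous at
desk-scale problem sizes:

* **class_dominated** — 2 majors × 2 leafs (4³ voxels per leaf per
  hemisphere), 3 classes with `class_effect = 3` (strongly divergent
  patterns), `smoothness_scale = 1000` (negligible spatial variation),
  noise sd 0.2, 3 experiments per (class, leaf): 36 experiments. Here
  class-restricted and class-blending estimators should beat class-agnostic
  smoothing decisively.
* **space_dominated** — 4 majors × 1 leaf, `class_effect = 0` (identical
  class patterns), `smoothness_scale = 2` (strong gradients), noise sd 0.1,
  2 experiments per cell: 24 experiments. Here pooling all classes
  spatially should win, since class restriction only discards data.
* **recovery** — 2 majors × 2 leafs, noiseless, `smoothness_scale = 100`
  (gentle gradients) and 6 experiments per cell, dense enough that a
  structure-level estimate should match the true tensor to within a couple
  of percent.

These sizes keep the full validation suite (10 seeds per regime, full
hyperparameter grids) at around a minute of computation while leaving each
effect far above its noise floor.

## Pipeline and reproducibility

`run_pipeline()` chains simulate → regionalize → select/evaluate →
build-connectome → factorize. Configuration is a single YAML file with
defaults for every key and rejection of unknown keys; all randomness flows
from one seed, outputs are byte-identical across reruns, and every text
artifact is stamped with the MD5 hash of the resolved configuration
(recorded alongside seeds and package version in `provenance.json`). The
pipeline's default distal-mask threshold is 150 μm rather than the
atlas-scale 1,500 μm default of `distal_mask()`, because adjacent leaf
blocks of the synthetic brain sit 100 μm apart — at atlas scale the
configuration should set it back to 1,500 μm.

## Known limitations

* Registration, segmentation and template construction are upstream of the
  data model: the package starts from centroids, volumes and an annotation.
* Structure-level connectivity assembly evaluates kernel models at the leaf
  centroid; for strongly asymmetric within-leaf designs the voxel mode is
  the safer (slower) choice.
* The EL blend weight is weakly identified when class structure dominates
  and the class bandwidth grid reaches its class-restricted limit (see
  above); interpret selected $\alpha$ values as one point on a plateau of
  equivalent predictors, not as a sharp estimate.
* Exhaustive archetype matching is intended for the small ranks used in
  recovery checks (≤ 8 reference components).
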