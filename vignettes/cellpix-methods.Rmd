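---
title: "Annotating single-cell RNA-seq by turning cells into images: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating single-cell RNA-seq by turning cells into images: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Supervised cell-type annotation transfers labels from a well-annotated
reference scRNA-seq dataset to new query datasets. cellpix does this by a
tabular-to-image route: genes are embedded in two dimensions by the
similarity of their expression profiles, assigned to pixels of a fixed grid,
and every cell's expression vector becomes a grayscale image that a small
convolutional network classifies. Because the gene-to-pixel map is fixed by
the reference, query cells render into directly comparable images, and
network attributions over pixels translate back into statements about genes.

This vignette records the model, the tunable parameters and their defaults,
and the design decisions taken where reasonable alternatives existed.

# Pipeline stages

## Quality control

Cells are filtered on three per-cell statistics: the number of detected
genes (`n_feature`), the total UMI count (`n_count`) and the percentage of
mitochondrial UMIs (`pct_mt`, identified by the configurable gene-name
prefix `MT-`). Defaults keep cells with `300 <= n_feature <= 4000` and
`pct_mt <= 15`; both bounds are inclusive, the least-surprise reading when
a range is quoted without open/closed qualification. `n_count` is computed
and reported but not filtered on by default — the lower and upper
`n_feature` bounds already remove empty droplets and likely doublets — and
optional `min_count`/`max_count` arguments exist for datasets that need
them. These thresholds are sensible for typical 10x-style experiments but
should be revisited per dataset (the droplet-based defaults are too strict
for plate-based protocols with much deeper per-cell coverage).

## Depth normalization

UMI counts scale with per-cell sequencing depth. The default normalization
removes this with analytic regularized Pearson residuals under a
negative-binomial model: for gene $g$ in cell $c$ with depth
$d_c = \sum_g x_{cg}$, the depth-proportional expectation is
$\mu_{cg} = d_c \pi_g$ with $\pi_g$ the gene's share of all UMIs, and

$$ r_{cg} = \frac{x_{cg} - \mu_{cg}}{\sqrt{\mu_{cg} + \mu_{cg}^2 / \theta_g}} $$

with the per-gene dispersion $\theta_g$ estimated by method of moments.
Because the per-cell means vary with depth, the marginal variance
decomposes as $\mathrm{Var}(x) = E[\mu] + \mathrm{Var}(\mu) +
E[\mu^2]/\theta$, so the estimator removes the depth-driven component
before attributing anything to dispersion:
$\theta_g = \pi_g^2 E[d^2] / (s_g^2 - \bar x_g - \pi_g^2 \mathrm{Var}(d))$,
set to $\infty$ when the denominator is not positive (no excess beyond
Poisson), and floored at `theta_min = 0.01`. Ignoring the
$\mathrm{Var}(\mu)$ term deflates the residual variance of highly
expressed genes well below 1 — a bug the calibration test caught.

The per-gene estimates are then *regularized across genes*: each gene's
dispersion is floored by the pooled median of the finite estimates. The
pooled value captures the technical overdispersion most genes share; a
gene whose variance exceeds it — a cell-type marker — keeps that excess in
its residuals. Without this pooling the per-gene estimator quietly
standardizes biological variation away (marker genes' residual variance
collapses to ~1 and variance-based HVG selection stops working), which is
exactly why regularization is part of the reference approach this
normalization emulates. Residuals are clipped to $\pm\sqrt{n_\text{cells}}$,
the conventional guard against single-cell outliers dominating a gene's
scale. Under pure depth-proportional Poisson noise these residuals have
mean 0 and variance 1 per gene, which the test suite checks at
$n = 2000$ simulated cells. A `log_cpm` alternative
(`log1p(1e4 x / d)`) is provided for comparison. The closed form was chosen
over an iterative regularized GLM fit because it is dependency-free,
fast, and testable against exact expectations; it shares the GLM
approach's stated goal (removing depth-driven variance) without claiming
numerical equivalence to any specific implementation.

## Highly variable genes, alignment, batch correction, scaling

Highly variable genes are the `n_hvg = 2000` genes with the largest
residual variance (ties broken toward the lexicographically smaller name so
selection is deterministic). Query matrices are reindexed to the reference
panel; genes missing from the query become zero columns (the residual value
of an uninformative gene), and an error is raised if fewer than half the
reference genes are found, since that pattern usually means a species or
annotation-version mismatch rather than a sparse panel.

In the paired workflow (`preprocess_pair()`) the normalization model — gene
shares and dispersions — is *fitted on the reference and applied to the
query*, exactly as the scaling stage is. This matters for batch effects: a
multiplicative shift that is uniform across a query would be silently
absorbed by the query's own gene-share estimates and become invisible,
leaving nothing for batch correction to fix while still distorting the
residual scale. Normalizing the query against the reference's expectations
keeps such shifts visible in the residuals, where the correction stage
removes them. (`normalize_counts()` without a model is self-contained and
unchanged.)

Batch correction is per-gene location/scale matching: within each query
batch, every gene is affinely transformed so its mean and standard
deviation equal the reference's. Genes with zero within-batch variance are
shifted only. This deliberately simple correction satisfies the contract
that matters downstream — after correction, query images are drawn on the
same intensity scale the network was trained on — and is trivially
verifiable (the suite checks moment agreement to 1e-6). It does not model
nonlinear or cell-state-dependent batch structure the way anchor-based
integration does; for strongly confounded designs a dedicated integration
tool should replace this stage upstream.

Scaling to $[0,1]$ is per gene, using the **reference** minimum and maximum
only; query values outside that range clip. The image intensity scale must
be fixed by the training distribution, otherwise a single extreme query
cell would recalibrate every pixel. Constant genes map to 0. Per-gene
(rather than global) min-max scaling keeps lowly expressed genes visible
instead of letting a few highly expressed genes compress everything else
toward black.

## The gene-to-pixel map

Genes are the embedded points; cells are the feature dimensions. t-SNE is
the default embedding (perplexity 30, seed mandatory and serialized), with
PCA and UMAP as alternatives. The embedding is wrapped in its convex hull,
the minimum-area enclosing rectangle is found by rotating calipers (an
optimal rectangle has a side collinear with a hull edge; the suite checks
agreement with an exhaustive 0.01-degree angle scan to 1e-6 relative
area), and the rotation that axis-aligns that rectangle is applied before
discretization. Each rectangle axis is scaled independently onto
`[0, P-1]` — independent rather than isotropic scaling uses the full pixel
budget of both axes, at the cost of distorting aspect ratio, which is
irrelevant to a classifier that never compares the two axes metrically.
Coordinates round to the nearest pixel; pixel rows are 0-based with row 0
at the image top (the Cartesian y axis is flipped).

Several genes may share a pixel. The default intensity of a shared pixel is
the **mean** of its genes' scaled values (`max` is available); the choice
is recorded in the map so images are reproducible from the serialized JSON.
With the canonical fixture (1000 genes, P = 64) about 15% of genes share a
pixel. Collisions shrink as P grows (a tested monotone property);
the default P = 64 keeps the network small while holding the collision rate
in an acceptable range for the gene panels used here. For larger HVG panels
(or to resolve individual marker genes) P should grow accordingly.

## The classifier

The backbone is a small three-block CNN — each block conv(3x3, stride 1,
same padding), batch normalization, ReLU, 2x2 max pooling, with channel
widths 8/16/32 — followed by a **flattened** linear head. A global-average-
pool head was evaluated first and rejected on measurement: GAP makes the
network nearly translation invariant, but under a gene-to-pixel map the
classes differ almost exclusively in *which* pixels are bright, not in
their intensity histograms, so pooling away position erased the signal
(training barely exceeded chance at desk scale). Flattening preserves
pixel identity and trains in a few epochs. The `pretrained_b3` backbone
name is recognized for interface compatibility but refuses to run, because
pretrained weights are not distributed with the package.

Training minimizes label-smoothed cross-entropy (smoothing
$\varepsilon = 0.2$: the target puts $1-\varepsilon$ on the true class and
$\varepsilon/K$ everywhere) with Adam at a peak learning rate of 3e-3
decayed to zero on a half-cosine over the 30-epoch budget, batch 64, an
85:15 stratified train/validation split, early stopping on validation loss
with patience 5, and restoration of the best-validation-loss weights.
Per-sample loss can never fall below the entropy of the smoothed target;
the suite asserts this floor. The peak rate is deliberately higher than the
usual 1e-3, and the batch deliberately small, because the budget is on the
order of a thousand optimizer steps, not tens of thousands; the cosine
decay then settles the optimizer into a sharp minimum, which matters
doubly here because the unknown-cell threshold is a low quantile of
validation confidence — a sloppily fitted validation tail makes open-set
detection erratic. Four regularizers matter beyond the usual overfitting
control, because they shape the *probability calibration* on which
open-set detection depends:

- **Dropout 0.5** on the flattened head features. The head otherwise puts
  weight on background pixels whose noise happens to correlate with class
  labels; those weights inject spurious confidence into cells of types the
  network has never seen.
- **Label smoothing 0.2.** Caps peak confidence and keeps the logit scale
  moderate, which keeps the maximum softmax probability informative as an
  uncertainty score.
- **Brightness jitter 0.5** (each training image scaled by
  $e^{U(-0.5, 0.5)}$, clipped at 1). Low-depth cells render as dim images;
  without this augmentation they dominate the low tail of validation
  confidence, and since the unknown-cell threshold is a low quantile of
  exactly that distribution, an unstable tail makes open-set detection
  unstable.
- **Outlier exposure 0.25** (a quarter of each minibatch appended as
  pixel-permuted copies of training images with uniform targets). A
  permuted image has bright pixels at positions never active in the
  reference — exactly the signature of a cell type absent from the
  reference — so the network is explicitly taught to answer "uniform" off
  the training manifold. This uses only the training data itself; no
  knowledge of any particular novel type is involved.

All randomness (initialization, the split, shuffling, augmentation masks)
derives from the single configured seed, and single-threaded kernels keep
training bitwise reproducible.

## Annotation and open-set detection

Each query cell receives the full softmax row; the call is the argmax class
(ties broken toward the lexicographically smaller name), and a cell is
flagged *unknown* when its maximum probability falls below a threshold.
The threshold is the 0.01 empirical quantile (lower interpolation) of the
maximum probability over **reference validation** cells — the held-out part
of the reference, not the query. Calibrating on the query would entangle
the threshold with the unknown-cell fraction of each dataset, whereas the
reference validation set is an i.i.d. sample of "cells the model should
recognize", making "filter the lowest 1%" a statement about the model's own
confidence distribution. Flagged cells keep their argmax class in a
separate audit column. The maximum softmax probability summarizes "the
predicted probability for all cell-types is low" in a single per-cell
number; alternatives (entropy, margin) were not pursued.

## Marker genes from class-activation maps

Per class, a gradient-weighted class-activation map is computed on a
convolutional block: activations are weighted element-wise by the rectified
gradient of the class logit with respect to them, summed over channels,
rectified, averaged over up to 256 sampled cells of the class, bilinearly
upsampled to the pixel grid and max-normalized. The gradients are exact and
cheap — the class column of the head weights propagated back through the
deeper blocks with batch norm treated as the fixed affine map it is at
inference. Two design points were settled by measurement rather than
convention. First, the element-wise (rather than channel-averaged)
gradient weighting: with a flatten head the gradients are spatially
localized, and collapsing them to one scalar per channel erases exactly the
localization the head uses, yielding maps unrelated to the markers. Second,
the block: maps on the final block (16x16 cells of 4x4 pixels at P = 64)
proved too coarse — co-expressed markers of one type embed to a single
pixel, different types' marker pixels sit in the same corner of the grid,
and neighbouring classes' evidence blurred together — while full-resolution
first-block maps intermittently missed evidence whose exact-pixel gradient
is negative (the next convolution reads it through off-centre taps). The
default is therefore the *second* block, whose 2x2-pixel cells resolve
individual marker pixels with one convolution of context; blocks 1 and 3
remain available. A gene's
relevance is the map value at its pixel — genes sharing a pixel share a
score and cannot be attributed below pixel resolution; ranked lists break
ties by gene name. A radius-0 readout (no neighborhood pooling) keeps the
gene-level claim conservative.

# The synthetic-data generator

Every stage is tested against simulated data with known structure, because
no real dataset ships with the package. Counts follow
$\text{NB}(\text{mean} = d_c \cdot \mu_0 \cdot f_{gt} \cdot b_g,\
\text{size} = \phi)$: log-normal depth factors $d_c$
($\sigma = 0.25$), background mean $\mu_0 = 2$, dispersion $\phi = 2$,
fold $f_{gt} = 8$ for the 5 planted markers of the cell's own type,
and a multiplicative batch factor $b_g = 2$ on a random 20% of genes in
the query only. QC violators are planted in deterministic number (5% of
cells): half forced below 300 detected genes, half pushed to roughly 30%
mitochondrial UMIs — both constructions guarantee threshold violations so
the QC test can demand exact removal. The novel type appears only in the
query with its own disjoint marker set and all reference-type markers
suppressed by the inverse fold, making it out-of-distribution rather than a
blend of known types. The canonical fixture is 5 types x 400 reference
cells, a query of 5 x 200 known plus 100 novel cells, and 1000 genes (10
mitochondrial), chosen as the smallest sizes at which per-class image
statistics are stable and training converges reliably on a single CPU.

What the generator does **not** emulate: gene-gene correlation within a
type (markers are independent), ambient RNA, empty droplets, nonlinear or
cell-state-dependent batch effects, and continuous differentiation
trajectories. Passing tests therefore demonstrate that the machinery is
correct and well-calibrated under its own model assumptions — planted
markers are recovered, planted violators are removed, planted batch shifts
are corrected — not that any particular accuracy will be attained on real
tissue.

# Numerical choices and degenerate inputs

- Dispersion floor `theta_min = 0.01`; genes whose variance does not exceed
  their mean get $\theta = \infty$ (Poisson denominator).
- Residual clipping at $\sqrt{n_\text{cells}}$; scaled values clip to
  $[0,1]$; constant genes scale to 0.
- All-zero cells: rejected by normalization (zero depth) with a pointer to
  QC; all-zero genes get zero residuals.
- Collinear embeddings produce a degenerate (zero-height) bounding
  rectangle; a single-point embedding maps every gene to the grid center.
- Empty pixels are exactly 0 in every image; an all-zero cell renders as an
  all-zero image.
- Ties: HVG selection, argmax calls and marker rankings all break ties
  lexicographically, so every ranking is deterministic.
- Quantile thresholds use lower interpolation (`type = 1`), so "filter the
  lowest 1%" never flags more than 1% of the calibration cells.

# Problem sizes used by the test suite

The suite trains the small CNN three times (seeds 101/202/303) on the
canonical fixture (about 1900 reference cells after QC, 64x64 images, at
most 30 epochs each) and once more on tiny two-class stacks; the whole run
is sized for a single CPU. The acceptance script repeats the full pipeline
once end to end, from count simulation through marker extraction, with all
stochastic stages seeded from its `--seed` argument; the fixture itself is
pinned so that the data conditions are identical across runs.

# Known limitations

- The location/scale batch correction cannot fix batch effects that change
  the *shape* of a gene's distribution or that differ by cell type.
- Open-set detection rests on softmax confidence; a novel type that mimics
  a known type's marker profile will not be flagged.
- Marker attribution is pixel-limited: genes sharing a pixel are
  indistinguishable to the CAM, and colliding markers dilute under mean
  aggregation.
- The small CNN is sized for thousands of cells and ~1000-gene panels; for
  atlas-scale references both the backbone and P should grow, and training
  would benefit from GPU-backed infrastructure outside this package's
  scope.
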