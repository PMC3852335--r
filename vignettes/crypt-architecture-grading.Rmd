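---
title: "Quantitative grading of crypt architectural distortion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative grading of crypt architectural distortion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryptArch)
```

## The problem and the model

Chronic inflammatory bowel disease (IBD) leaves a durable architectural
signature in the colonic mucosa: crypts that are normally straight, tubular,
densely and evenly packed, and anchored on the muscularis mucosa become
distorted in outline, depleted in number, irregularly spaced, and lifted off
the muscularis. Pathologists grade this distortion as Normal or IBD grade
I--III (mild/moderate/severe), with considerable inter-observer variability.
`cryptArch` implements an automated morphometric grading pipeline for single
well-oriented microscopy fields:

1. **Segmentation.** The field is cleaned (background subtraction, median
   filter) and crypt outlines are localized with an active-contour
   ("snake") procedure; the muscularis mucosa is extracted as the upper edge
   of the dark band along the image bottom.
2. **Shape block (9 features).** Each crypt outline is parameterized in
   polar form $r(\theta)$ about its centroid and transformed with the DFT
   convention $z_u = \frac{1}{K}\sum_k r_k e^{-2\pi i u k/K}$. After
   nullifying $z_0$ (position), dividing by $|z_1|$ (size) and keeping
   magnitudes only (rotation), the nine magnitudes $|z_1|\dots|z_9|$ are
   averaged over the crypts of the image.
3. **Density (1 feature).** Crypt centroids come from the moments of the
   filled outline masks ($\bar x = M_{10}/M_{00}$, $\bar y = M_{01}/M_{00}$);
   the minimum spanning tree over the centroids (Kruskal) yields the mean
   tree edge length, normalized by the maximum tree edge length.
4. **Basal gap (1 feature).** Lines are fitted (ordinary least squares,
   $\mathrm{MSE} = \frac1n\sum_i (y_i - a x_i - b)^2$) to the muscularis
   polyline and to the base points of the first row of crypts;
   perpendicular norms from the muscularis vertices to the crypt line are
   averaged and normalized.
5. **Classification.** The 11 features feed a probabilistic neural network
   (PNN): a Parzen-window Bayes classifier that assigns $V$ to class $C_i$
   iff $p_i L_i f_i(V) > p_j L_j f_j(V)$ for all $j \ne i$, with
   $f_i(V) = \frac{1}{n_i}\sum_{w \in C_i} e^{-\|V - w\|^2 / 2\sigma^2}$
   over the stored (min-max scaled) training patterns. The network has 11
   input nodes, one hidden node per training pattern, 4 class nodes, and a
   decision node.

No clinical images ship with the package. A synthetic-field generator with
exact ground truth stands in for them, so every stage is testable end to
end.

## The synthetic generator: what it emulates, and what it does not

`generateBiopsyImage()` renders dark, star-shaped crypt lumina over lighter
stroma with a dark muscularis band along the bottom, additive Gaussian
noise (5 gray levels) and a smooth low-order polynomial illumination field
with amplitude ±10% of the stroma intensity. The field enters additively —
the regime in which subtracting a paired blank-slide exposure, the
correction this pipeline uses, is exact (a multiplicative field would call
for flat-field division instead). Crypt outlines are harmonic perturbations of circles,
$r(\theta) = R(1 + d\sum_h c_h \cos(h\theta + \phi_h))$, with the
coefficient amplitudes rescaled to sum to 0.8 so the radius stays positive
and the polygon simple. Harmonics start at order 2 because a first-order
radial harmonic is, to first order, a translation rather than a shape
change. Grade severity enters through `gradeParams()` defaults, chosen once
to mirror the qualitative ordering of the histology:

| grade | distortion $d$ | crypts/field | basal gap (px) | spacing jitter |
|-------|---------------|--------------|----------------|----------------|
| Normal | 0.03 | 18--24 | 15 | 0.10 |
| I      | 0.15 | 12--18 | 25 | 0.18 |
| II     | 0.35 | 8--12  | 40 | 0.28 |
| III    | 0.60 | 4--8   | 60 | 0.40 |

Distortion, basal gap and spacing irregularity increase with grade; crypt
density decreases. Spacing jitter is made grade-increasing deliberately:
irregular inter-crypt spacing is part of what "architectural distortion"
means, and it is what gives the mean/max spanning-tree ratio its grade
signal (on a perfectly regular grid that ratio is scale-free and nearly
grade-constant). The default canvas is 800×600 px with a crypt radius of
3.5% of the width; feature definitions are scale-normalized, so tests use
smaller canvases freely.

The generator does **not** attempt photorealistic H&E rendering, stain
color, inflammatory cells, crypt branching as a topological event, or
rotated/misoriented specimens. Passing tests on synthetic cohorts therefore
demonstrate that the algorithmic chain recovers known geometry and known
grade structure — not that the pipeline is clinically validated on real
slides.

## Numerical and design choices

**Snake discretization.** The active contour is a greedy discrete snake:
each of 64 vertices in turn moves to the best position in a 7×7 window
under the energy
$E = \sum_i \alpha E_{cont} + \beta E_{curv} + \gamma E_{img} + \kappa E_{con}$
(tension and curvature normalized by the initial mean vertex spacing, image
energy the negative normalized gradient magnitude of the smoothed image,
containment a quadratic penalty beyond twice the initial mean radius).
Defaults $\alpha=0.4$, $\beta=0.2$, $\gamma=1.0$, $\kappa=0.1$, move
tolerance 0.5 px, at most 500 sweeps. A move is accepted only if it
strictly lowers the energy terms it touches, which makes the total energy
non-increasing, the procedure deterministic (ties keep the current
position), and convergence finite. Initialization is one dilated convex
hull per Otsu-thresholded, hole-filled, size-filtered dark component;
components touching the bottom border are the muscularis candidate, not
crypts. Crypts are assumed darker than stroma; a polarity flag inverts
this. Without an explicit background image, the illumination estimate is a
grayscale *closing* with a structuring element much larger than a crypt —
closing (not opening) is the estimator that removes dark objects on a
light background; the roles swap with the polarity flag.

**Descriptor normalization.** The size normalization divides by $|z_1|$,
as stated for this feature set. For a boundary parameterized about its own
centroid this is an unusual choice: the centroid cancels the first-order
harmonic to first order, so $|z_1|$ is a *second-order* quantity that grows
roughly quadratically with distortion amplitude. Two consequences are
worth knowing. First, a perfect circle has $|z_1| = 0$; an
$\varepsilon$-guard ($10^{-12}|z_0|$) flags such maximally regular crypts
as degenerate and excludes them from the per-image average (the all-zero
vector is the regularity extreme). Second, the normalized magnitudes
$|z_m|/|z_1|$ *decrease* as distortion increases — higher distortion
inflates the denominator faster than the numerators. The shape features
therefore separate grades with a falling, then saturating profile rather
than a rising one; classification is unaffected (the classifier needs
consistent class clusters, not a direction), and the test suite asserts
the ordering that actually holds. Per-crypt normalization happens before
averaging; $K = 64$ angular samples (a power of two, seven times the
highest retained harmonic).

**Spanning-tree normalization.** "Maximum distance encountered" is read as
the maximum MST edge weight — the distances the algorithm encounters in
the tree — keeping the feature in $(0, 1]$ and sensitive to spacing
irregularity rather than image extent. The maximum pairwise distance is
available as `denominator = "pairwise"`. Kruskal ties break by stable
(weight, i, j) ordering. With ≤ 1 centroid the feature saturates at 1.0
(crypt loss is the severe-disease direction) rather than going undefined.

**Basal-gap normalization.** The mean/max ratio of the muscularis-to-crypt
norms is ≈ 1 for near-parallel fitted lines and carries almost no signal;
the feature reported is the mean norm divided by the image diagonal (the
gap magnitude itself, scale-normalized), with the literal mean/max reading
behind `distanceMode = "ratio"`. Norms are perpendicular point-to-line
distances, robust to small tilt. First-row membership uses a 1.5× threshold
on the minimum centroid-to-muscularis distance. A missing muscularis or
fewer than two crypts yields the sentinel 1.0, mirroring the density
feature.

**PNN.** Gaussian kernel with a single shared $\sigma$ (default 0.1 on the
min-max scale; `selectSigma()` picks it by leave-one-out accuracy, ties to
the smallest). Priors default to empirical class frequencies, losses to 1.
Test vectors are clipped to $[-0.5, 1.5]$ after scaling to bound
extrapolation. Exact score ties break toward the lower grade — the
conservative direction for a screening aid. When every class score
underflows (σ far below the query distances) the decision falls back to
the nearest stored pattern with a warning, which is also the analytic
$\sigma \to 0$ limit of the rule under empirical priors.

**Evaluation conventions.** Per-class precision uses the classifier-column
denominator (correct over all cases *classified into* the class) and recall
the reference-row denominator; overall precision is the micro-average
trace/total. These are the only readings under which the shipped
training/testing reference tables (79 + 39 expert-graded biopsies,
`referenceConfusion()`) reproduce their published per-class values, e.g.
grade II testing precision 90% (9 correct of 10 classified as II) alongside
grade II recall 100%. The stratified splitter uses per-class
`round(fraction * n)` with largest-remainder adjustment, which reproduces
that study's 79/39 partition from its (43, 39, 26, 10) grade counts.

## A worked end-to-end run

```{r example, eval = FALSE}
coh <- generateCohort(30, seed = 1201)        # 120 fields, 30 per grade
ft  <- cohortFeatures(coh)                    # segment + 11 features each
sp  <- splitDataset(ft$grade, 2/3, seed = 1201)
X   <- as.matrix(ft[, c(paste0("fd", 1:9), "mst_spacing", "musc_distance")])
sg  <- selectSigma(X[sp$train, ], ft$grade[sp$train],
                   grid = c(0.02, 0.05, 0.1, 0.2, 0.4))
m   <- trainPNN(X[sp$train, ], ft$grade[sp$train], sigma = sg)
pred <- apply(X[sp$test, ], 1, function(q) classifyPNN(m, q)$grade)
evaluateGrading(pred, ft$grade[sp$test])
```

This is the configuration exercised by the acceptance test: 120 images at
the default canvas, a stratified 2/3--1/3 split, LOO-selected σ. The suite
requires held-out overall precision of at least 85%; runs at the seeds
used in the tests land in the 90--98% range, with residual confusions
between adjacent grades. Problem sizes throughout the tests (120-field cohorts,
50-field initialization cohorts at 400×300, 20-boundary descriptor
cohorts) were chosen as the smallest sizes at which the cohort-level
assertions are stable.

## Known limitations

* The snake is a local optimizer: it refines initialization, so heavily
  merged or extremely faint crypts that thresholding misses stay missed.
* Muscularis extraction assumes a well-oriented field with the band along
  the image bottom; rotated specimens are out of scope.
* The $|z_1|$ normalization makes the shape block noisy for nearly
  circular crypts (small, noise-dominated denominator); the degeneracy
  guard and per-image averaging mitigate but do not remove this.
* Grading is per field; multi-field aggregation per patient is out of
  scope, as are inflammatory (non-architectural) features.
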