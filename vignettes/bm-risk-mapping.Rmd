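---
title: "Methods: atlas-space spatial risk mapping of brain metastases"
author: "bmatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: atlas-space spatial risk mapping of brain metastases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmatlas)
```

## The model

All analyses operate on a single voxel grid in a common (atlas) space.
Patient-to-atlas registration is assumed to have happened upstream; inputs
are binary lesion masks, tissue masks, label atlases and a perfusion map on
one grid. The coordinate convention is voxel-center throughout: voxel
$(i,j,k)$ (1-based) sits at $\mathrm{origin} + (i-\tfrac12, j-\tfrac12,
k-\tfrac12)\cdot\mathrm{spacing}$, and a voxel belongs to a geometric shape
iff its center does. Both the lesion simulator and the contour rasterizer
use this same inclusion rule, so simulated and rasterized inputs are
interchangeable.

The central object is the cumulative risk map
$$C(\vec x) \;=\; \sum_{i=1}^{N}\sum_{l=1}^{L_i} \big[\vec x \in
\mathrm{lesion}_{il}\big] \quad \text{[counts per voxel]},$$
an integer volume whose total equals the number of lesion voxels in the
cohort exactly — an invariant the tests assert at cohort scale. Regional
statistics assign each lesion to exactly one region by the atlas label at
its centroid (with a 5 mm nearest-label rescue for centroids on
background), so percentages over assigned lesions sum to 100 by
construction.

**Density enrichment.** A region's "density" is its share of lesions
divided by its share of *parenchymal* (gray + white) volume: a
dimensionless ratio equal to 1 under uniform seeding, which makes regions
of very different sizes comparable. Two choices are deliberate here.
First, the denominator is the parenchymal share, not the total-volume
share: lesions arise in parenchyma, so a CSF-filled region (the
ventricles) would otherwise carry volume that can never host a centroid
and every ratio would be biased. Regions with zero parenchymal volume are
excluded from the 100% denominator and reported as excluded rather than
silently dropped. Second, normalization is by volume *share* rather than
absolute volume, keeping the ratio scale-free across grids; this is one of
the places where an absolute-volume convention would have been equally
defensible, and the choice is stated rather than hidden.

**Cross-site uncertainty.** Every regional percentage is also computed per
site, and the reported interval is the $t$ interval
$\bar x \pm t_{0.975,\,n-1}\, s/\sqrt n$ over sites. With four sites a
normal interval would be anti-conservative; the $t$ form is the defensible
default at $n=4$. Group comparisons (laterality, between-histology) use
the two-tailed Welch test on the per-site values; no multiplicity
correction is applied by default (a Benjamini–Hochberg option exists),
since the outputs are descriptive tables of raw p-values.

## The interface null test

Proximity of lesions to the gray–white interface could be an artifact of
tissue geometry: convoluted cortex means most parenchyma is near the
interface anyway. The null model is therefore the distribution of
interface distances over parenchymal *volume*, binned at 0.5 mm, and the
observed distribution is the same binning of lesion-centroid distances.
The interface itself is defined combinatorially — gray voxels 6-adjacent
to white plus white voxels 6-adjacent to gray — because a sub-voxel
surface would be irreproducible across implementations; distances are an
exact Euclidean distance transform to that voxel set. Histograms are
truncated at the 99.5th percentile of parenchymal distances (the long,
nearly empty deep-white tail otherwise dominates bin pairing); distances
beyond the last edge are clamped into the final bin so both series still
sum to 1.

Three read-outs compare the two distributions:

* the 1-D Wasserstein distance, $\sum_b |F_{\mathrm{obs}}(b) -
  F_{\mathrm{null}}(b)|\cdot \Delta$ in mm;
* the over-representation at the 5 mm landmark, i.e. the difference of
  cumulative fractions within 5 mm, in percentage points;
* a two-sided Wilcoxon signed-rank test.

The Wilcoxon pairing deserves its own paragraph, because the obvious
construction is wrong. Pairing the per-bin fractions (observed − null)
looks natural, but the per-bin deviations of a multinomial sample from its
expectation are negatively correlated and sum to zero; the signed-rank
null distribution assumes independent symmetric differences and is far
wider than the truth. Measured over hundreds of uniform-seeding
replicates, that construction rejects at a rate of 0.000 at nominal
$\alpha = 0.05$ — it cannot be calibrated by binning choices (we tried
exact and sampled nulls and coarser bins). The default pairing is
therefore per *lesion*: each observed centroid distance (at its bin
center) is paired with one seeded draw from the null distribution. Under
uniform seeding both members of a pair are draws from the same
distribution, so the differences are iid and symmetric about zero and the
test holds its nominal size (measured type-I 0.048 over 1000 replicates)
while retaining full power against a 3 mm interface bias. The per-bin
variant is kept as a descriptive option. The signed-rank p itself is exact
(full null distribution over sign assignments, mid-ranked ties, zeros
dropped) up to $n = 25$ nonzero differences and a tie-corrected,
continuity-corrected normal approximation above.

## Lesion morphometrics

Sphericity is the Wadell index $\psi = \pi^{1/3}(6V)^{2/3}/A$. The volume
is exact (voxel count × voxel volume); everything interesting is in the
surface area. Two estimators are provided:

* `voxel_faces` counts exposed voxel faces. It is exactly testable (a
  single voxel gives $\psi = (\pi/6)^{1/3} \approx 0.806$) but
  overestimates the area of smooth shapes by a factor approaching 1.5,
  biasing $\psi$ low.
* `mesh` (default) triangulates the 0.5-isosurface of a Gaussian-smoothed
  indicator field by marching tetrahedra (six tetrahedra per cell, linear
  interpolation along edges) and sums triangle areas. Smoothing removes
  the voxel staircase; without it the tetrahedral mesh overestimates area
  by ~30%. The smoothing scale adapts to lesion size,
  $\sigma = \min(0.7,\ r_{\mathrm{eq}}/6)$ voxels with $r_{\mathrm{eq}}$
  the volume-equivalent radius: a fixed $\sigma$ of order one voxel
  erodes lesions smaller than a few voxels below their own curvature
  scale and drives $\psi$ above 1, while the bounded form keeps a
  radius-10 digitized sphere within 1.2% of $\psi = 1$ and small lesions
  finite. Mesh values are clipped at 1; sphericity is scale-invariant
  because smoothing acts in voxel units and the mesh in physical units.

A single-voxel lesion cannot be meshed and falls back to face counting
with a warning. Lesion-to-interface distance uses the centroid, sampled
at the containing voxel (nearest-voxel, no interpolation), consistent
with the centroid-based region accounting; a boundary-minimum variant
would systematically read lower for large lesions and is intentionally
not the default.

## The phantom and the generator

The phantom is a deterministic (seeded) digital head: ellipsoidal
cerebrum, cerebellum and brainstem; a cortical gray shell over a white
interior; six paired deep gray nuclei and paired lateral ventricles; a
coarse anatomical atlas (8 lobes, cerebellum × 2, brainstem, 12 nuclei,
2 ventricles) that tiles the brain exactly, plus finer, functional and
vascular-territory subdivisions; and a perfusion field with
tissue-dependent baselines, a smooth seeded texture, and masked Gaussian
smoothing that mimics the partial-volume blurring of arterial
spin labeling. Structure positions scale with grid extent, so the same
anatomy exists at any resolution; the default working grid is 2 mm
isotropic (1 mm is supported, just slower).

Two deliberately unanatomical choices keep the statistics realistic. The
gray shell is 8 mm thick — thicker than cortex — because the phantom has
no folding: a thick shell restores a realistic gray share of parenchyma
(~40%) and a tissue-to-interface distance distribution whose bulk lies
within ~13 mm. And perfusion is smoothed at σ = 6 mm so the
gray/white contrast is a gradient rather than a step, as in real ASL.

The simulator draws, per patient, a zero-truncated negative-binomial
lesion count (size 0.5, mean 2.0 before truncation: median 2, mean ≈ 3.6,
occasional patients approaching 50 — the shape of multi-institutional
radiosurgery cohorts), log-normal lesion volumes (meanlog log 0.08,
sdlog 1.6: right-skewed, spanning roughly 0.002–60 cc), and places lesion
centers by an inhomogeneous point process restricted to parenchyma with
intensity
$$\lambda(\vec x) \;\propto\; m_{\mathrm{region}(\vec x)} \cdot
e^{-d_{\mathrm{interface}}(\vec x)/\tau} \cdot
p_{\mathrm{norm}}(\vec x)^{\gamma}.$$
This minimal factorized form makes each bias independently tunable and —
the property the test suite exploits — independently recoverable. Each
lesion is rendered as a randomly oriented, mildly anisotropic digitized
ellipsoid of the drawn volume, clipped to the brain; within a patient a
center is re-drawn (budget 25) if its rendering would overlap an existing
lesion of the same patient, since clinical delineations are distinct;
overlap across patients is what the risk map accumulates. Patients go
round-robin to sites so four-site confidence intervals are well defined
at small n. Cohorts are pure functions of (phantom, config) including the
seed.

Defaults were fixed once, before the analysis suite was finalized, and
are reported rather than re-tuned: $\gamma = 1$; $\tau = 20$ mm, chosen by
a closed-form calculation on the default phantom's weight field so the
expected within-5 mm lesion share is ≈ 0.73, the concentration reported
for real cohorts. (On this phantom the within-5 mm share and the
over-representation cannot both match real-brain values — the unfolded
cortex gives a tissue null of ~0.58 within 5 mm versus ~0.62 in a real
brain — so the headline share was chosen as the anchor and the
over-representation is simply reported.) The per-primary presets add
subcortical sparing (multiplier 0.3 on the deep nuclei and brainstem) and
calibrate a cerebellar multiplier in closed form so the *expected*
cerebellar density enrichment is 2.8× (lung) and 4× (breast) the melanoma
baseline; the calibration inverts
$m = d\,(v_r/V)\,Z_{\mathrm{rest}}\,/\,\big(W_r (1 - d\, v_r/V)\big)$
on the actual weight field, so it remains exact under the interface and
perfusion biases.

What the generator does *not* emulate: cortical folding (so interface
geometry is smoother than reality), MR signal formation and segmentation
error, registration error (the ~5 mm centroid mapping accuracy of real
pipelines), longitudinal growth, and histology-specific morphology beyond
the cerebellar and subcortical weights. Passing tests therefore
demonstrate internal correctness and statistical calibration of the
*analysis machinery*, not that real cohorts obey the generative form.

## Sparing targets and coverage

Target construction is Boolean: the union of spared labels is dilated by
an exact Euclidean margin (distance transform thresholded at the margin,
in mm — spacing-independent, no structuring-element iteration) and
subtracted from the brain. Presets: whole-brain (nothing spared),
hippocampal avoidance (hippocampi + 5 mm), and the deep-structure
"PROTECT" set (hippocampi, amygdalae, thalami, pallidi, caudates,
putamina, brainstem, ventricles + 3 mm). Expected coverage is by centroid
by default (consistent with the centroid-based ROI accounting; the
volume-weighted variant is provided because either reading is plausible),
reported overall and per primary. Coverage along genuinely nested plans
is monotone non-increasing; the preset sequence WBRT → HA → PROTECT is
*not* strictly nested (HA's 5 mm hippocampal margin is not contained in
PROTECT's 3 mm expansion), so `tradeoff_curve()` checks nesting and warns
rather than asserting monotonicity when it does not hold.

## Numerical and engineering choices

* Distance transforms use the separable lower-envelope (parabola)
  algorithm in C++ — exact for anisotropic spacings, with nearest-feature
  tracking reused for label expansion (overlapping margin expansions
  resolve to the nearest original region) and background rescue. Tests
  compare against an $O(n^2)$ exhaustive oracle on crops up to $20^3$.
* Connected components are 26-connected flood fill in C++, tested against
  an independent R-level BFS.
* The 1-D Wasserstein distance is the CDF-difference sum, tested against
  a full linear-program transport oracle on 12-bin histograms.
* Histogram edges are half-open $[a, b)$ with the last bin closed by
  clamping; ties in ranks are mid-ranked; degenerate inputs (empty masks,
  all-zero differences, fewer than 6 nonzero pairs, constant perfusion,
  empty targets) raise errors or warnings rather than returning silent
  numbers.
* The tabular store is a directory of relational CSV tables (patients /
  lesions / runs) keyed by a config hash, so re-running an identical
  configuration is idempotent.

**Problem sizes.** The test suite and acceptance analyses run on the
default 96³ × 2 mm phantom (72³ for unit fixtures) with cohorts of
60–500 patients; calibration properties (test size, power, uniformity,
parameter recovery) use centroid-only rendering with 200–500 patients and
200–500 replicates, sizes at which each asserted tolerance is several
standard errors wide. These are the package's chosen operating points for
a single-workstation run.

## Known limitations

The phantom's smooth cortex understates interface area and overstates
deep white matter, so absolute values of interface statistics differ from
real-brain values even under faithful seeding; the perfusion field is
bimodal-with-noise rather than a full hemodynamic model, so the
perfusion–distance subspace occupancy (~60% on default simulations) is
below the ~90% seen on real data; the density "ratio" axis is the
share-based enrichment defined above and should be compared to other
conventions with care; and the Wilcoxon pairing, while calibrated, is one
of several defensible operationalizations of "observed vs null" — the
Wasserstein distance and over-representation are reported alongside it
precisely so no single test carries the conclusion.
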