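# bmatlas

Spatial risk mapping of brain metastases in a common atlas space.

Brain metastases (BM) do not seed uniformly: they concentrate near the
gray–white matter junction, in moderately-to-highly perfused tissue, and
spare the deep subcortical structures, with histology-specific quirks such
as cerebellar tropism of lung and breast primaries. Quantifying that
spatial structure — and exploiting it to design whole-brain radiotherapy
(WBRT) targets that spare low-risk, functionally critical structures — is
the job of this package. It is aimed at radiation-oncology physicists and
neuro-imaging researchers who want a fully testable, download-free version
of the atlas-space BM analysis stack: every component runs against a
built-in synthetic brain phantom and lesion simulator, and accepts real
atlas-space NIfTI volumes wherever the phantom is used.

## What it computes

* **Voxelwise risk map.** All lesions `l` of all patients `i`, already in
  atlas space, are accumulated into a cumulative count per voxel
  `C(x) = Σ_i Σ_l [x ∈ lesion_il]`, with per-site maps and the provenance
  numbers (N, L, C_max) carried along.
* **Lesion morphometrics.** 26-connected components; volume;
  Wadell sphericity `ψ = π^(1/3) (6V)^(2/3) / A` with the surface area `A`
  from a marching-tetrahedra isosurface (or exact voxel-face counting);
  centroid distance to the gray–white interface via an exact Euclidean
  distance transform; atlas membership by centroid with a 5 mm background
  rescue.
* **Regional statistics.** Percent contribution per region (sums to 100
  over assigned lesions), the density enrichment ratio (share of lesions /
  share of parenchymal volume, 1 under uniform seeding), 95% t confidence
  intervals over sites, margin-expansion sensitivity, laterality Welch
  tests.
* **Interface null test.** Observed centroid-distance histogram vs the
  tissue-volume null at 0.5 mm resolution, compared by the 1-D Wasserstein
  distance `Σ|CDF₁−CDF₂|·Δ`, a calibrated Wilcoxon signed-rank test, and
  the within-5 mm over-representation in percentage points.
* **Perfusion subspace.** Normalized perfusion (99th-percentile scaling),
  joint histograms, and the lesion-volume fraction inside a
  perfusion × interface-distance subspace.
* **Function-sparing targets.** Boolean target construction
  (brain minus an isotropically expanded union of spared structures,
  e.g. the deep-structure "PROTECT" set at 3 mm), expected lesion coverage
  by centroid or volume, and the coverage-vs-spared-volume tradeoff.
* **Simulator.** An inhomogeneous point process on the phantom,
  `λ(x) ∝ multiplier(region) · exp(−d_interface/τ) · perfusion^γ`, with
  zero-truncated negative-binomial lesion counts, log-normal volumes and
  digitized random ellipsoids — every placement bias is recoverable, which
  is what the test suite leans on.

## Worked example

```r
library(bmatlas)

ph     <- build_phantom(spacing_mm = 2, shape = c(96, 96, 96), seed = 7)
cfg    <- sim_config_primary(ph, "lung", seed = 1, n_patients = 300)
cohort <- simulate_cohort(ph, cfg)
rmap   <- accumulate(cohort)
rmap
#> <bm_riskmap> N=300 patients, L=1005 lesions, C_max=6, 32948 lesion voxels, 4 site map(s)

region_contribution(cohort, ph, atlas = "coarse") |>
  dplyr::arrange(dplyr::desc(percent))
#>   region           lesion_count percent density ci_low ci_high
#> 1 cerebellum_left           148    14.7   3.53   10.7     18.7
#> 2 frontal_right             143    14.2   0.836  10.4     17.9
#> 3 frontal_left              129    12.8   0.754   9.26    16.3
#> 4 cerebellum_right          126    12.5   3.01    8.31    16.9
#> 5 parietal_right            120    11.9   0.806   9.81    14.1
```

The lung preset enriches the cerebellum: it tops the contribution table
with a density ratio ~3 (three times more lesions than its share of
parenchymal volume would predict), while the large frontal lobes
contribute many lesions at density below 1. Error bars are 95% t
intervals of the per-site percentages across the four simulated sites.

```r
dmap  <- interface_distance_map(ph$gray_mask, ph$white_mask)
edges <- interface_bins(ph, dmap)
compare_to_null(observed_histogram(cohort, ph, dmap, edges = edges),
                null_histogram(ph, dmap, edges = edges))
#>   wasserstein_mm wilcoxon_p over_representation_pct frac_within_landmark null_within_landmark
#> 1           1.66   1.12e-16                    15.4                0.729                0.575
```

72.9% of lesion centroids lie within 5 mm of the gray–white interface
versus 57.5% of tissue volume — a 15.4 percentage-point
over-representation that the Wilcoxon test attributes to placement bias
rather than tissue geometry (p ≈ 1e−16).

```r
tradeoff_curve(cohort, list(plan_wbrt(ph), plan_protect(ph)))
#>           plan spared_volume_fraction spared_parenchyma_fraction coverage_pct
#> 1         wbrt                0.00000                    0.00000       100.00
#> 2 wbrt_protect                0.06674                    0.05976        97.31
```

Sparing the expanded deep-structure union (6.7% of brain volume) keeps
97.3% of simulated lesions covered — the quantitative basis of the
function-sparing argument. `autoplot(rmap)`, `autoplot(region_stats)`,
`plot_interface_histograms()` and `plot_tradeoff()` draw the standard
figures; `run_pipeline()` and the `inst/cli/bmatlas` script execute the
whole chain from a YAML config.

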