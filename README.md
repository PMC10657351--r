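# wingevo

Spanwise evolutionary tempo, modularity and mechanical sensitivity of bird
wing shape.

## The problem

Bird wings are built from two anatomical modules — the armwing (AW,
forearm) and the handwing (HW, wrist and hand) — but the aerodynamics of
flapping imposes a *continuous* gradient on them: under the blade-element
model, the aerodynamic force and inertial moment per unit wing area grow
as the square of the distance from the wing base, peaking at the tip. Two
very different evolutionary patterns follow, depending on what drives wing
shape evolution:

* **Gradient**: the evolutionary rate σ² of shape traits rises smoothly
  base-to-tip, tracking mechanical sensitivity and ignoring the module
  boundary.
* **Modular**: σ² is roughly flat within AW and HW with a discrete step at
  the wrist.

`wingevo` is for comparative biologists who have (or simulate) 3D wing
surface scans, a time-calibrated phylogeny, and want to run this
discrimination end to end:

* **Morphometry**: align scan point clouds, slice them spanwise (25 HW
  slices of width (tip − wrist)/25, armwing tiled at the same width),
  measure camber, chord, cross-sectional thickness (XST) and area (XSA)
  per slice, scale by body mass (M_b^1/3 for lengths, M_b^2/3 for areas),
  and summarize to species medians on a standardized 10 AW + wrist + 25 HW
  layout.
* **Comparative models** (first principles, no comparative-methods
  dependency): per-slice ML fits of BM / OU / EB with AICc selection,
  σ² profiles, Blomberg's K and Pagel's λ.
* **Modularity & disparity**: Adams' covariance ratio
  CR = ‖S₁₂‖ / √(‖S₁₁°‖‖S₂₂°‖) with a variable-permutation null, and
  per-slice disparity (variance or median distance from centroid).
* **Gradient inference**: regression-discontinuity analysis
  y = β₀ + β₁(x−c) + δ·D + β₂·D(x−c) at the wrist cutoff, clade splits,
  taxon rarefaction, posterior-tree scans (median ± MAD).
* **Mechanical sensitivity**: the r² blade-element profile and the
  gradient / modular hypothesis templates.
* **Synthetic data**: seeded generators for ultrametric trees, trait
  matrices with controlled spanwise rate gradients (optional wrist step),
  trend-plus-noise null data, and parametric wing point clouds with exact
  per-slice ground truth — the whole pipeline runs with no downloads.

## Worked example

Simulate a study in which rates follow a smooth tip-ward gradient (no
wrist step), then analyse it:

```r
library(wingevo)
study <- generate_study(synth_study_config(n_species = 64, seed = 42))
res <- run_pipeline(study$profiles[c("camber", "chord")], study$tree,
                    run_config(n_perm = 999, seed = 42))
print(res)
#> spanwise wing-shape evolution analysis
#>   traits: camber, chord
#>         trait lambda_hw k_hw lambda_aw  k_aw disparity_hw disparity_aw
#> camber camber         1 1.06     0.998 0.824     5.63e-04     0.000171
#> chord   chord         1 1.12     0.999 0.852     1.90e+01     5.291518
#>        sigma2_hw sigma2_aw    cr  cr_p disparity_rda_p sigma2_rda_p
#> camber  8.35e-04  0.000274 0.570 0.001          0.2467        0.840
#> chord   2.79e+01  8.256166 0.618 0.001          0.0496        0.427
```

Reading the table: phylogenetic signal is high everywhere (λ ≈ 1, K ≈ 1,
as expected for Brownian-type simulation); handwing disparity and σ² are
~3× the armwing values because the generating rate gradient rises toward
the tip; CR < 1 with p = 0.001 reflects the spanwise smoothness of the
profiles; and the σ² RDA p-values (0.84, 0.43) correctly find **no
discrete step** at the wrist — the gradient, not the modular, signature.

Individual stages are available directly:

```r
res$results$camber$modularity
#> covariance-ratio modularity test: CR = 0.5702, p = 0.001 (999 permutations; modules 10 | 25)
res$results$camber$sigma2_rda
#> regression discontinuity at cutoff 10.50: delta = -0.000132438 (p = 0.8398)
#>   slopes: 1.99702e-05 (below) vs 4.74979e-05 (above); n = 10 | 25
```

Measuring real scans instead: `read_pointcloud()` +
`align_pointcloud()` + `measure_wing()` per specimen (wrist position is
required metadata), `summarize_species()` for the species-median
profiles, then the same `run_pipeline()` call; `measure_manifest()` wraps
the per-specimen loop given a TSV manifest.

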