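---
title: "Spanwise evolutionary dynamics of wing shape: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spanwise evolutionary dynamics of wing shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingevo)
```

## The scientific question

A flapping wing does not experience aerodynamic load uniformly. Under the
blade-element (strip) abstraction, a section at spanwise position $r$ moves
with velocity proportional to $r$ during flapping, so both the aerodynamic
force per unit area and the inertial moment per unit area grow as $r^2$
toward the wingtip; chord taper cancels from the per-area quantity. If the
strength of the morphology-to-function mapping ("mechanical sensitivity")
drives the evolution of shape traits, the evolutionary rate $\sigma^2$ of
wing cross-sectional traits should increase base-to-tip following this
gradient. The competing expectation comes from the wing's anatomical
organization into an armwing (AW, supported by the forearm skeleton) and a
handwing (HW, supported by wrist and hand): if evolution acts on these
morphological modules, $\sigma^2$ should be roughly constant within each
region with a discrete step at the wrist.

`wingevo` implements the full chain needed to discriminate these patterns:

1. **Morphometry** — turn 3D surface-scan point clouds of spread wings into
   standardized species-by-slice trait matrices (camber, chord,
   cross-sectional thickness XST, cross-sectional area XSA).
2. **Comparative models** — per-slice maximum-likelihood fits of Brownian
   motion (BM), Ornstein–Uhlenbeck (OU) and early-burst (EB) models, AICc
   selection, per-slice $\sigma^2$, and phylogenetic signal (Blomberg's
   $K$, Pagel's $\lambda$), all from first principles.
3. **Modularity and disparity** — the covariance-ratio (CR) test with a
   variable-permutation null, and per-slice morphological disparity.
4. **Gradient inference** — regression-discontinuity analysis (RDA) at the
   wrist, clade splits, taxon rarefaction, and scans over posterior tree
   sets.
5. **Mechanical sensitivity** — the $r^2$ blade-element profile and the two
   hypothesis templates (smooth gradient vs modular step).
6. **Synthetic data** — seeded generators for every input, so the whole
   pipeline is testable without any external download.

## Measurement model

Scans are consumed as bare vertex lists (OBJ/PLY/XYZ); faces and normals
are ignored. Clouds are aligned rigidly to a common frame by principal
axes: the dominant axis of spatial variance becomes X (span), the second Y
(chord), the residual Z (thickness). Principal axes leave a fourfold sign
ambiguity, which is resolved by two anatomical facts rather than
landmarks: wings taper, so the end with the smaller chordwise spread is the
tip (fixes the X sign), and wings are cambered, so mid-chord points sit
dorsally of chord-edge points (fixes the Z sign); Y follows to keep the
rotation proper. The transform is rigid — no scaling — so all distances
are preserved exactly.

The wrist position is **required metadata**, not detected: thickness and
camber taper smoothly through the joint, so no robust landmark-free
detector exists, and mislabeling the wrist silently corrupts the module
partition downstream.

Slices are chordwise bins of width $w = (X_{max} - x_{wrist})/25$: 25
handwing bins tile wrist-to-tip, and the same width tiles the armwing
toward the base (bins half-open, proximal edge inclusive). The armwing bin
adjacent to the joint is labeled WRIST. The standardized profile keeps 10
armwing bins + the wrist bin + 25 handwing bins (36 columns); analyses
exclude the wrist bin by default, giving the 35-slice layout, with
`to_HW`/`to_AW` policies available to check that wrist assignment does not
drive the modularity verdict.

Per slice, with $Y$/$Z$ the chord/thickness coordinates:

* chord $= Y_{max} - Y_{min}$;
* camber $= (Z_{max} - Z_{min}) / (Y_{max} - Y_{min})$, slice-global
  extremes;
* XST: the chord is divided into stations (about 25 points each, at most
  100 stations). On shell scans the points of a station lie on the upper
  and lower surfaces, which share the camber arc; the station's points are
  split into the two surfaces (initial split on raw $Z$, refined once on
  residuals from the pooled within-class slope), and the thickness is the
  difference of the class means after detrending with that pooled slope,
  evaluated at the station center. XST is the maximum over a 5-station
  moving average, which suppresses the max-order-statistic inflation that
  a raw maximum over many noisy stations incurs. A slice-global
  $Z_{max}-Z_{min}$ variant is available (`xst_mode = "global"`).
* XSA: the integral of the per-station thickness over the chord. For
  solid sections (`surface = "solid"`, e.g. filled test polygons) the
  per-station extent is the range corrected by the $(n+1)/(n-1)$ uniform
  range bias. We considered tracing the section perimeter (an
  alpha-shape/spline/shoelace construction) and chose station integration
  instead: for chordwise wing sections it needs no ordering heuristic, is
  robust to scattered-point noise, and converges to the enclosed area.

Coordinates are quantized to $10^{-9}$ mm before binning so that the
discrete station assignment is stable against the $\sim 10^{-12}$ mm
round-off left by different rigid-motion histories; this is far below any
scanner's resolution.

Linear traits are scaled by $M_b^{-1/3}$ and areas by $M_b^{-2/3}$ (body
mass in grams; isometric scaling), camber is dimensionless. Analyses run
on species medians over specimens.

On synthetic parametric wings the measured profiles recover the analytic
truth to within 2% for chord, camber and XST and 5% for XSA at roughly 500
points per slice; per-slab ground truth is defined at the slab midpoint
for chord and slab means for XST/XSA, while camber truth is the
slab-proximal supremum ratio, since that is what slice-global extremes
estimate on a base-to-tip tapering wing.

## Evolutionary models and estimators

For $n$ species with tree covariance $C$ ($C_{ij}$ = shared root-to-MRCA
path length), the Gaussian trait model has mean $z_0 \mathbf{1}$ and
covariance $\sigma^2 V_0(\theta)$ with

* BM: $V_0 = C$;
* OU (fixed root, non-stationary, the convention of standard ML fitting
  on ultrametric trees):
  $V_{ij} = \frac{1}{2\alpha} e^{-\alpha d_{ij}} (1 - e^{-2\alpha s_{ij}})$,
  $s_{ij}$ shared time, $d_{ij}$ patristic distance;
* EB: $V_{ij} = (e^{r s_{ij}} - 1)/r$, $r \le 0$.

Both reduce continuously to BM as $\alpha, |r| \to 0$ (asserted to
$10^{-6}$ in the tests). $z_0$ and $\sigma^2$ are profiled analytically by
GLS ($\hat z_0 = (\mathbf{1}^T V_0^{-1}\mathbf{1})^{-1}
\mathbf{1}^T V_0^{-1} x$, $\hat\sigma^2 = Q/n$, ML divisor $n$ to match
the conventions of the standard fitting tools this replaces); $\alpha$ or
$r$ is then a bounded one-dimensional search (Brent within four log-spaced
bracketing intervals, relative tolerance $10^{-8}$, bounds
$\alpha \in [0, 50/\text{depth}]$, $r \in [-10/\text{depth}, 0]$), making
every fit deterministic. Constant data collapse to $\hat\sigma^2 = 0$; the
likelihood is evaluated at a tiny documented floor and the fit flagged
degenerate rather than returning an infinite log-likelihood. AICc is
$-2\ell + 2k + 2k(k+1)/(n-k-1)$; ties within $10^{-6}$ go to the model
with fewer parameters.

Per-slice $\sigma^2$ uses the AICc-best model at each slice by default
(`model_policy = "best_aicc"`), since the per-slice best model is what the
rate estimate conditions on; a forced-common-model policy is available for
sensitivity analysis. Whether trait values should be log-transformed
before rate fitting is left off by default: the log transform is motivated
(and applied) only for the CR test, where mean differences between regions
bias the covariance blocks.

Blomberg's $K$ standardizes the ratio of the tip variance around the
phylogenetic mean to the phylogenetically corrected variance by its BM
expectation; $K = 1$ exactly on star trees, and simulations at 128 tips
center on 1 under BM. Pagel's $\lambda$ multiplies off-diagonal entries of
$C$ and is estimated by profile ML over $[0, \lambda_{max}]$ with
$\lambda_{max}$ the largest value keeping $C(\lambda)$ positive definite
($\ge 1$ on ultrametric trees). Against an independent implementation
(`phytools::phylosig`) both statistics agree to $10^{-6}$/$10^{-3}$ on a
shared dataset; that implementation is used only as a cross-check, never
as the estimator.

A note on finite-sample behavior: ML estimates of $\alpha$ and especially
$r$ are noticeably biased at moderate sample sizes — the $r$ likelihood is
flat near 0 and a fraction of replicates collapse to the boundary. We
verified the optimizer always attains at least the likelihood of the true
parameter and that the bias shrinks with $n$ (median $\hat r$ for a true
$-2$: $-1.59$ at 128 tips, $-1.85$ at 256, $-1.94$ at 384). The recovery
tests therefore assert median-based recovery within 10% at 256 tips; this
is a property of the estimator, not of the implementation.

## Modularity, disparity and the trend-bias null

The CR statistic is
$\mathrm{CR} = \lVert S_{12}\rVert_F \big/
\sqrt{\lVert S_{11}^{\circ}\rVert_F \, \lVert S_{22}^{\circ}\rVert_F}$
from the unbiased sample covariance of species values over slices, with
within-module diagonals zeroed; values below 1 indicate modularity. The
null permutes variables (slices) across modules preserving module sizes;
$p = (1 + \#\{CR_{perm} \le CR_{obs}\})/(1 + n_{perm})$ (add-one rule, so
$p$ is never zero), one-sided for modularity, default 999 permutations.
No phylogenetic correction is applied inside CR: the test is applied to
the trait data directly, and the log10 transform is the guard against
between-region mean differences.

Because spanwise traits trend smoothly base-to-tip, nearby slices are
similar for reasons that have nothing to do with modules.
`trend_bias_check()` makes this concrete: species profiles are a shared
trend (linear, exponential or logistic) plus iid noise — no modules, no
phylogeny — and the CR rejection rate at $\alpha = 0.05$ stays at the
nominal level (the replicate loop uses 199 permutations per test, which
resolves $p = 0.05$ comfortably and keeps the 200-replicate check fast).
A trend alone does not fake modularity; spatially *correlated deviations*
around the trend, as any smooth biological profile has, are genuine
covariance and do move CR below 1 — which is why the synthetic study's CR
values sit well below 1 even without an injected module boundary.

Disparity per slice is the among-species sample variance by default;
median absolute distance from the centroid is the robust alternative. The
choice is exposed because reasonable implementations differ, and the
report records which metric produced each table.

## Regression discontinuity at the wrist

The RDA fits $y = \beta_0 + \beta_1 (x - c) + \delta D + \beta_2 D(x - c)$
by OLS over all slices (global linear fit, order 1), with
$D = \mathbf{1}[x \ge c]$, the slice index $1..35$ (base to tip) as the
$x$-axis, the cutoff at $c = 10.5$ — between armwing slice 10 and handwing
slice 1 — and the wrist bin excluded from both sides. $\delta$ is the
intercept step at the wrist and its two-sided $t$-test $p$-value is the
headline number; the slope change $\beta_2$ is reported alongside. No
multiple-testing correction is applied across traits or statistics — raw
per-trait $p$-values are reported, as is conventional for this design. On
noiseless piecewise-linear input the fit is exact; with a step of five
residual SDs at 35 slices, power exceeds 0.8 and the estimated step is
unbiased, while with no step the false-positive rate sits at the nominal
5%. A step of exactly twice the residual SD yields roughly 65% power with
34 points — worth knowing when interpreting marginal wrist effects.

## Synthetic data: what it emulates and what it does not

`synth_study_config()` fixes the study conditions: 178 species, 6
specimens per species, a unit-depth pure-birth tree, 10 AW + wrist + 25 HW
slices, four traits with smooth decreasing base-to-tip mean trends on the
scale of mass-scaled wing measurements (camber ~0.07–0.11, chord ~13–20
mm g$^{-1/3}$, XST ~0.5–2.1 mm g$^{-1/3}$, XSA ~2–17 mm$^2$ g$^{-2/3}$),
and a rate profile rising quadratically toward the tip
($\sigma^2 = 2\times10^{-4} \to 1.2\times10^{-3}$ on the camber scale,
other traits scaled to their trend magnitude), i.e. the
mechanical-sensitivity gradient with no wrist step by default
(`wrist_step` injects one). Innovations share an AR(1) correlation (0.8)
between adjacent slices so profiles are spanwise-smooth while each slice
keeps its marginal rate exactly; the cross-slice dependence is a nuisance
structure the real data surely has but the analysis never models, so it
is exposed in the config. Specimen-level measurement noise (2% of each
trait's trend range) is added and median-summarized, mirroring the
pipeline.

Parametric wing clouds have linearly tapered chord and thickness and a
parabolic camber arc with points on the two surfaces; all four per-slice
traits have closed-form truth, which is what the morphometry recovery
tests measure against.

What passing these tests shows: the estimators recover known structure of
the right magnitudes under phylogenetic and measurement noise. What they
cannot show: robustness to real-scan pathologies (holes, feather gaps,
registration artifacts), non-Gaussian trait evolution, or errors in the
wrist annotation — none of which the generators emulate.

## Problem sizes and runtime choices

The test suite and acceptance script run simulation checks at sizes chosen
to make their Monte Carlo error small relative to the asserted margins
while keeping the whole suite in a few minutes on one CPU: 128-tip trees
for rate/signal calibration (500 replicates for $K$, 100 for $\lambda$
and model selection), 256 tips for OU/EB parameter recovery, 500
replicates for RDA operating characteristics, 200 replicates for the CR
trend-bias null, and ~500 points per slice for morphometric recovery. The
full synthetic study (178 species, 4 traits, 999 permutations) runs end to
end in about a minute.

## Known limitations

* OU fits use the fixed-root non-stationary covariance (the study trees
  are ultrametric); a stationary-OU variant is not implemented.
* Multivariate (cross-slice) evolutionary models are out of scope; each
  slice is fitted marginally, which matches the per-slice reporting but
  ignores the dependence the generator itself acknowledges.
* CR is applied per trait on the slice matrix with exactly two modules;
  per-feather or multi-module hypotheses are not supported.
* The blade-element sensitivity profile is the generic $r^2$ strip model
  with the exponent exposed; unsteady aerodynamics, tip vortices and
  wing morphing are deliberately outside the abstraction.
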