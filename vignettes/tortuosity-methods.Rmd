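---
title: "From artery segmentations to curvature-based tortuosity: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From artery segmentations to curvature-based tortuosity: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tortr)
```

## The problem

Abnormal tortuosity of cerebral arteries — particularly the internal carotid
artery within the Circle of Willis — is a marker of vascular remodeling and a
risk factor for cerebrovascular events. Modern segmentation tools produce
labeled 3D masks of these arteries from time-of-flight MR angiography at
sub-millimetre resolution, but a mask is not a measurement: tortuosity
metrics need a smooth space curve with reliable first and second
derivatives, while a segmentation provides a jagged cloud of voxels. The
gap between the two is where most of the numerical difficulty lives, and
this vignette documents how `tortr` crosses it.

The pipeline is:

1. **binarize** the target label of the input NIfTI labelmap;
2. **skeletonize** the binary mask to a one-voxel-wide medial line
   (topology-preserving 3D thinning);
3. **detect endpoints** by 26-neighbourhood counting and **order** the
   skeleton voxels into a start-to-end path;
4. **recenter** the path at sub-voxel precision using the mask;
5. fit a **unit-speed cubic spline** and evaluate curvature
   $\kappa(s) = \lVert r'(s) \times r''(s)\rVert / \lVert r'(s)\rVert^3$;
6. integrate the **tortuosity metrics** and write one CSV row per vessel,
   including the spline RMSE as a fit-quality indicator.

All geometry is computed in world millimetres through the NIfTI affine
(voxel-center convention, 0-based indices), so the metrics do not depend on
the grid resolution except through quantization error.

## The metrics

For a curve of arc length $L$ with chord $C$ (distance between its
endpoints):

* **Arc over chord** $\mathrm{AOC} = L / C \ge 1$. Cheap and popular, but
  insensitive to low-amplitude, high-frequency "wiggle": a vessel can
  oscillate considerably while barely lengthening.
* **Total curvature** $\kappa_m = \int_0^L \kappa\, ds$ — dimensionless and
  scale invariant.
* **Mean squared curvature**
  $\kappa_{ms} = \frac{1}{L}\int_0^L \kappa^2\, ds$ — up-weights sharp
  bends; has units mm$^{-2}$ and is *not* scale invariant (scaling all
  lengths by $a$ divides it by $a^2$).
* **Normalized RMS curvature**
  $\kappa_{rms} = L\sqrt{\frac{1}{L}\int_0^L \kappa^2\, ds}$ —
  dimensionless and scale invariant.

On the $\kappa_{rms}$ normalization: the bare root-mean-square curvature
$\sqrt{\frac{1}{L}\int\kappa^2 ds}$ scales as $1/a$ and therefore cannot be
scale invariant. Scale invariance of the RMS-based metric — doubling a
helix's radius and pitch leaves it unchanged — only holds with the extra
factor of $L$, which is the form this package computes. The bare variant is
available as an optional CSV column (`bare_rms = TRUE`) for comparison with
implementations that omit the factor.

Integrals use the trapezoidal rule on `n_samples = 512` uniform arc-length
samples; every record recomputes the integrals at doubled sampling and
flags `integration_unstable` if any metric moves by more than 0.1%.

## Skeletonization

No R package in our dependency universe offers 3D curve thinning, so the
thinning is implemented in compiled code from first principles: a border
voxel is deleted only if it is a *simple point* — its 26 foreground
neighbours form exactly one 26-connected component and the background
6-neighbours form exactly one 6-connected component within the
18-neighbourhood — so every deletion provably preserves topology. Voxels
with a single foreground neighbour (curve endpoints) are never deleted.
Deletions are sequential, sweeping the six face directions in turn, which
keeps the line centred in the tube.

Two practical details matter:

* **Orientation canonicalization.** A naive sweep order makes the result
  depend on how the array is stored: flipping an axis (and updating the
  affine) would yield a slightly different skeleton and perturb the chord
  by a fraction of a voxel. `tortr` therefore orders both the sweep
  directions and the voxel visiting order by *world* axes, derived from the
  affine, so axis permutations and flips of the input volume produce
  identical skeletons in world space (verified to machine precision in the
  tests).
* **Spur pruning.** Thinning a tube with blunt end caps can leave 1–3-voxel
  stubs at the ends. Branches of at most `prune_spurs_vox = 4` voxels
  hanging off a junction are removed; genuine anatomy is far longer than 4
  voxels at 0.625 mm spacing, while end-cap artifacts are shorter. Longer
  spurious branches are handled downstream: with more than two endpoints
  the pair with the maximal geodesic distance is used, side branches are
  dropped, and the record carries `multiple_endpoints` / `spur_dropped`
  warnings.

Closed loops (no endpoints) raise a typed error — the target artery is an
open curve, and silently cutting a loop would hide a segmentation problem.
Multi-component masks are likewise an error by default (`keep_largest =
TRUE` opts into keeping the largest component with a warning), mirroring
the practice of fixing disconnected segmentations upstream.

## Sub-voxel recentering

An ordered skeleton path still carries quantization jitter of order half a
voxel. That jitter is nearly invisible to $\mathrm{AOC}$ and $\kappa_m$ but
inflates $\int \kappa^2$ badly, because squared curvature integrates noise
rather than averaging it away. Before spline fitting, each path point is
moved to the centroid of the mask voxels inside a thin slab perpendicular
to the local tangent (slab half-width 0.75 voxel; disc radius adapted to
the local vessel radius, estimated from the distance to the nearest
background voxel and capped at 4 mm). The correction is restricted to the
plane normal to the tangent so the path is not shortened, capped at one
voxel per pass, and applied twice. On voxelized helix phantoms this reduces
the residual point noise from ~0.3 mm to under 0.1 mm and is the main
reason the squared-curvature metrics recover their closed forms within a
few percent at 0.625 mm resolution.

## The unit-speed spline and its smoothing

The fit is two-stage:

1. Each coordinate is fit against the chord-length parameter with a cubic
   smoothing spline (penalty $\lambda$ on the integrated squared second
   derivative; $\lambda = 0$ interpolates). Because the same linear
   smoother is applied to all three coordinates, the fitted curve is
   exactly equivariant under rigid motions.
2. The cumulative arc length of the stage-1 curve is computed by dense
   trapezoidal quadrature, refined until the total changes by less than
   $10^{-6}$ relative; the curve is then resampled at uniform arc length
   (10x the input point count) and refit with interpolating natural
   cubics. The result satisfies $\lVert r'(s)\rVert = 1$ to well under 1%,
   so the parameter *is* distance along the vessel.

Curvature is evaluated with the general ratio formula rather than
$\lVert r''\rVert$, so any residual parametrization error cancels rather
than biasing the estimate. Curvature samples in the first and last 10% of
arc length are flagged: natural end conditions force $r'' \to 0$ there, a
known end bias. The metrics still integrate the full curve — truncating
would bias $L$ and the chord — but the flag is available to downstream
consumers.

**Choosing the smoothing.** The only objective the quality indicator
suggests — minimize RMSE plus RMS curvature — turns out to be degenerate as
a *selector*: for long, gently curved vessels the RMS-curvature term keeps
rewarding extra smoothing long after the fit has started flattening real
geometry, and on voxelized helix phantoms it underestimates total curvature
by ~15%. `tortr` therefore selects $\lambda$ by 10-fold cross-validation:
interleaved folds, prediction error summed over the three coordinates,
minimum over a logarithmic grid ($10^{-8}$ to $1$, half-decade steps).
Cross-validation is self-calibrating across noise scales — the same rule
handles clean analytic curves (where a guard detects that the
least-smoothed fit already reproduces the points to below $10^{-3}$ of the
point spacing and switches to exact interpolation), sub-voxel skeleton
jitter, and heavy synthetic noise — and it recovers all four metrics within
5% on voxelized phantoms. The combined-score minimizer remains available
as `smoothing = "combined"`, and any fixed $\lambda$ can be supplied
directly. The combined score itself is still reported per vessel as the
quality indicator; only its role as the selection objective changed.

One caveat is recorded rather than hidden: the fold layout of
cross-validation is defined on the point order, so `smoothing = "auto"` is
not bit-identical under path reversal (the selected $\lambda$ can move by
one grid step on noisy data). At any fixed $\lambda$ the fit is exactly
reversal- and rigid-motion-invariant, which is what the invariance tests
assert; all shipped defaults make the *metrics* reversal-stable to well
within their tolerance.

## The phantom generator

Validation needs inputs whose answer is known exactly. The generator
produces:

* **helices** $(r\cos t,\ r\sin t,\ \frac{p}{2\pi}t)$ with constant
  curvature $r/(r^2 + (p/2\pi)^2)$ and arc length
  $\mathrm{turns}\cdot\sqrt{(2\pi r)^2 + p^2}$, sampled uniformly in $t$
  (which is uniform in arc length);
* **circular arcs** (known AOC and curvature $1/R$) and **straight lines**
  (zero curvature, AOC exactly 1) as controls;
* **noisy versions**: isotropic Gaussian perturbation with
  $\sigma = \mathrm{amplitude}/\mathrm{SNR}$, where the amplitude is the
  helix radius (or the RMS deviation from the centroid for shapes without
  one). The noise model is deliberately simple — the SNR axis only needs to
  be monotone in noise power. Ground-truth fields are recorded before
  perturbation and preserved, and noise is bit-reproducible given a seed;
* **voxelized tubes**: a voxel is foreground iff its centre lies within the
  tube radius of the (densified) polyline — voxel-centre inclusion with no
  partial volume, since the pipeline consumes binary masks. The default
  0.625 mm isotropic spacing matches the resolution of the upstream
  segmentation tool.

What the phantoms do **not** emulate: MR acquisition physics, intensity
inhomogeneity, segmentation over/under-reach, variable vessel calibre, or
branching anatomy. Passing the phantom suite therefore demonstrates that
the geometry pipeline is correct and noise-robust, not that segmentations
of any particular scanner are accurate.

## Validation problem sizes

The shipped tests and the acceptance script use: 200-point analytic
helices for curvature recovery and scale invariance; 250-point helices
across pitch $\{\pi, 2\pi, 4\pi, 8\pi\}$ and turns $\{1, 2, 4\}$ for
monotonicity; 100 seeded replicates per SNR in $\{2, 5, 10, 50\}$ of a
100-point, two-turn unit helix for the noise sweep; and a helix of radius
10 mm, pitch 10 mm voxelized as a 1.5 mm tube at 0.625 mm isotropic spacing
for the end-to-end voxel run. These sizes keep each experiment in the
seconds-to-a-minute range while leaving the conclusions unchanged at larger
sizes (the convergence test doubles point counts explicitly).

## Known limitations

* Curvature near the curve ends is biased low by the natural end
  conditions; metrics on very short vessels (under ~10 skeleton voxels)
  lean heavily on those biased regions.
* $\kappa_{ms}$ and $\kappa_{rms}$ remain the most noise-sensitive outputs;
  at voxel resolutions much coarser than the vessel radius the recentering
  step loses its leverage and the squared-curvature metrics degrade first.
* Torsion — the third-order companion to curvature — is not computed; the
  metric set is deliberately the four standard curvature-based indices.
* The smoothing grid spans $\lambda \in [10^{-8}, 1]$; pathological inputs
  far outside the vessel-like regime (thousands of points, millimetre-scale
  noise on metre-scale curves) may need a custom `lambda_grid`.
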