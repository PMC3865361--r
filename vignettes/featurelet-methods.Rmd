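---
title: "Piecewise deformable registration with featurelets: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Piecewise deformable registration with featurelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(featurelet)
```

## The registration model

Deformable registration between a planning CT and a cone-beam CT (CBCT)
estimates a spatially varying displacement field that aligns the two volumes
beyond what a rigid transform can achieve, so that organ contours delineated
once on the CT can be propagated to each treatment-day CBCT. `featurelet`
implements a piecewise (block-matching) model of that field:

1. **Partitioning.** The moving image is tiled by non-overlapping
   *featurelets* (regular subvolumes, default $15^3$ voxels), anchored at
   the volume corner; the last box per axis is truncated so every voxel is
   covered exactly once.
2. **Local translation matching.** Each featurelet is registered by pure
   translation into a larger *search region* (default $30^3$ voxels)
   centered on it in the fixed image, maximizing either normalized
   correlation (NC) or mutual information (MI). The optimum is located by an
   exhaustive scan of all feasible integer translations followed by a
   regular-step gradient descent refinement (maximum step 0.05 voxels,
   minimum 0.001, step halved whenever the metric gradient reverses
   direction, at most 2000 iterations per featurelet). The scan is what
   gives the search region its meaning: a purely local descent started at
   zero displacement cannot traverse a merit landscape whose basin of
   attraction is narrower than the true displacement — for high-frequency
   texture the NC surface is essentially flat away from the peak — so the
   descent's role is subvoxel refinement, not global search. Setting
   `global_init = FALSE` in `registration_config()` recovers the
   descent-only behaviour.
3. **Merit restriction.** A featurelet is accepted only if its descent
   converged, its contents are not flat, and its final merit reaches a
   threshold (defaults NC $\ge 0.5$, MI $\ge 0.1$ nats). This keeps
   misregistered blocks — water background, noise-only patches — from
   misleading the interpolation.
4. **Interpolation.** Accepted displacements live on the lattice of
   featurelet centers; each component is interpolated trilinearly to every
   voxel. Rejected lattice nodes are infilled with the nearest valid node's
   value before interpolation; voxels outside the lattice hull take the
   clamped edge value.

The dense field follows the *resampling* (pull-back) convention: the stored
vector at fixed-image voxel $v$ points to the corresponding position
$v + u(v)$ in the moving image, so `warp_image()` and `warp_mask()` resample
the moving image and its contours onto the fixed grid without field
inversion. A featurelet's tabulated displacement `(dx, dy, dz)` is the
opposite (moving-to-fixed) translation — "where did this block go" — and
`filter_by_merit()` negates it when building the control lattice. For the
clinical workflow the planning CT is the moving image and the CBCT the fixed
one, so contours drawn on the CT are deformed toward the CBCT.

## Similarity metrics and why they differ across modalities

NC is the Pearson correlation of paired intensities: invariant under
positive affine rescaling but nothing weaker. MI is estimated from a joint
histogram (default $32\times32$ equal-width bins spanning each patch's own
range, no Parzen smoothing — the simplest estimator, which keeps the unit
tests exact): invariant under *any* monotone remapping of one patch that
preserves bin assignment. That asymmetry is the mechanistic reason MI is the
metric of choice for intermodality (CT–CBCT) registration, where the two
scanners realize different, nonlinear — and in the worst case inverted —
intensity relationships for the same tissue.

Flat patches make NC undefined; they are flagged degenerate (value 0) and
always rejected, rather than raising an error, because a water-filled
phantom background produces many of them.

## The digital phantom

The synthetic module emulates a purpose-built deformable pelvis phantom: a
water-filled box holding an inflatable bladder balloon (fill volume 200-400
cc, default 300 cc), a rigid prostate-shaped object of approximately 110 cc
attached below the bladder, a rectum tube posterior to the prostate that
neither moves nor deforms, and lateral radio-opaque bone blocks. The default
grid is $96 \times 96 \times 64$ voxels at 4 mm isotropic spacing — a
desk-scale analogue of the physical $400 \times 400 \times 290$ mm box that
preserves the featurelet-to-search-region ratio, since the algorithm's
behaviour depends on relative, not absolute, scales. Intensity levels
(water 0, bladder fill 60, prostate 100, rectum −80, bone 700) are HU-like
and pairwise distinct; additive Gaussian noise (default sd 10, a realistic
soft-tissue CT noise level relative to the 40-100 unit contrasts) is seeded
and reproducible. Structure shapes are simple parametric solids (ellipsoid,
cut ellipsoid, capped cylinder, boxes) sized by bisection so the voxelized
volumes land on their targets well within voxelization error.

Ground-truth deformations are analytic and smooth: a radial bladder
inflation with Gaussian falloff, a rigid prostate translation blended
smoothly to zero away from the organ, and an exact zero inside the rectum
dilated by one voxel (enforced by a distance ramp off the tube). The
deformed scene is *produced by resampling the baseline with this field*, so
the stored `truth_field` is exact by construction — the digital counterpart
of obtaining ground truth by careful delineation on a physical phantom. The
defaults (inflation factor 1.3, prostate shift 12 mm, smoothness 40 mm) give
a field of about 4 voxels peak amplitude, safely inside the $\pm 8$ voxel
reach of the default search region, and pre-registration prostate Dice
around 70 so improvements are measurable.

What the phantom does *not* model: CBCT scatter, beam hardening, cupping and
ring artifacts; anatomically realistic organ shapes or sliding interfaces;
intra-structure texture. Passing its benchmarks therefore demonstrates that
the pipeline recovers smooth, moderate deformations of high-contrast
structures — the regime the physical phantom probes — not clinical-grade
accuracy on soft-tissue anatomy.

## The intermodality surrogate and the constructed worst case

`simulate_cbct_appearance()` passes intensities through a strictly monotone
curve, multiplies by a smooth low-frequency shading field and adds noise.
The default curve (`cbct_remap`, $200\tanh(x/300)$) compresses the bone
range the way cone-beam reconstructions do.

`intermodality_worst_case()` freezes the seeded case used to demonstrate the
metric dissociation. Two-level image patches cannot separate the metrics by
noise alone — for a two-valued patch both the attainable correlation and the
attainable mutual information are monotone functions of the same
contrast-to-noise ratio — so the case instead uses a strictly *decreasing*
nonlinear curve ($250 e^{-x/150}$): contrast inversion, the canonical
intermodality relationship under which a linear-correlation merit fails
outright. At the true alignment every featurelet's NC is strongly negative,
all fall below the acceptance threshold, and the NC pipeline degenerates to
the identity field (reported as `succeeded = FALSE`), leaving Dice scores
unchanged; MI is indifferent to the inversion and recovers the deformation.
The baseline phantom in this case is noiseless so that background
featurelets are excluded as flat: with two independently noisy continuous
textures, the finite-sample bias of a $32 \times 32$ histogram MI estimate
($\approx (B-1)^2/2N \approx 0.14$ nats at $N = 15^3$) would exceed the 0.1
nat threshold and admit junk control points.

## Numerical choices

* **Geometry.** Voxel indices are 0-based, boxes half-open $[lo, hi)$,
  physical position $= \text{origin} + \text{index} \times \text{spacing}$.
  Only identity direction matrices are accepted at I/O time; oblique
  volumes are rejected rather than silently reoriented.
* **Sampling.** The fixed image is sampled with trilinear interpolation and
  clamp-to-edge beyond its bounds (avoiding artificial zero-intensity edges
  that would bias the merit); mask warping is nearest-neighbor so outputs
  stay binary.
* **Gradient.** Central finite differences of the merit with respect to the
  three translation components, probe 0.5 voxels.
* **Search-region placement.** Low corner $\lfloor \text{center} -
  \text{size}/2 \rfloor$, clipped to the volume and forced to contain the
  featurelet footprint; displacements are clamped so the translated patch
  stays inside the region.
* **Ties and degeneracies.** The integer scan keeps the first maximum in
  x-fastest order; nearest-valid-node infill breaks ties by lowest node
  index; zero paired differences are dropped from the signed-rank test, and
  an all-zero difference vector returns "NS" with $p = 1$.
* **Wilcoxon.** For $n \le 25$ retained pairs the exact two-sided p-value is
  computed by a generating-function convolution over doubled (mid)ranks,
  which remains exact under ties; larger samples use the normal
  approximation with tie and continuity corrections. The Dice denominator
  is the standard $(|V_d| + |V_m|)/2$.
* **Hausdorff.** Computed between surface voxels (foreground voxels with a
  face-adjacent background neighbor), Euclidean on indices by default —
  "pixels" — with a millimetre mode for anisotropic slices.

## Problem sizes used in the validation suite

The shipped tests exercise the full default benchmark
($96 \times 96 \times 64$ at 4 mm, 245 featurelets) once per metric for the
end-to-end claims, and smaller textured volumes ($\le 30^3$) for
oracle-equivalence checks, where exhaustive integer scans and $O(n^2)$
surface distances are computed independently in test code. These sizes were
chosen so the whole suite documents the method's behaviour at the scale the
phantom study prescribes while remaining comfortable to run on a laptop.

## Known limitations

* Translation-only featurelets: no per-block rotation or scaling, no
  multi-resolution pyramid, no adaptive featurelet sizes.
* The dense field is not guaranteed diffeomorphic; no inverse-consistency or
  Jacobian diagnostics are provided.
* Inputs must be rigidly pre-aligned on a shared grid;
  `pre_align_translation()` offers only a coarse global-translation start.
* The merit restriction is a hard threshold; soft weighting of control
  points is not implemented.
* DICOM series and RT-STRUCT contours are out of scope — masks in NIfTI or
  MetaImage are the exchange format.
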