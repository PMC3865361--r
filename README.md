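# featurelet

Piecewise ("featurelet") deformable image registration for 3D radiotherapy
volumes, with contour-propagation scoring and a digital deformable pelvis
phantom for validation.

## The problem

Before each irradiation fraction a cone-beam CT (CBCT) is acquired on the
treatment machine. Organs at risk and target volumes move and deform between
the planning CT and these daily scans, so contours drawn once on the CT must
be carried over — *contour propagation* — by estimating a deformable
registration between the two volumes. This package is for medical-physics
and image-analysis work that needs a transparent, fully inspectable
block-matching registration together with the standard agreement metrics
used to judge it.

## The method

The moving image is tiled by non-overlapping **featurelets** (default
15×15×15 voxels). Each featurelet is registered by pure translation into a
30×30×30 search region of the fixed image, maximizing either

* **NC** — normalized correlation, `Σ(a−ā)(b−b̄) / √(Σ(a−ā)² Σ(b−b̄)²)`, or
* **MI** — mutual information, `H(A) + H(B) − H(A,B)` from a 32×32 joint
  intensity histogram (nats),

via an exhaustive integer-translation scan refined by regular-step gradient
descent (max step 0.05 voxels, min 0.001, ≤ 2000 iterations per featurelet).
Featurelets whose final merit falls below a threshold (NC ≥ 0.5, MI ≥ 0.1
nats) are rejected so they cannot mislead the next step: trilinear
interpolation of the accepted displacements from the featurelet-center
lattice to every voxel. The resulting dense field maps fixed-image
coordinates to moving-image positions (resampling convention), so the moving
image and its structure masks are warped onto the fixed grid without field
inversion.

Contour agreement is scored with the Dice similarity coefficient
`DSC = 2|V_d ∩ V_m| / (|V_d| + |V_m|) × 100`, the surface Hausdorff distance
`H(A,B) = max(h(A,B), h(B,A))`, `h(A,B) = max_{a∈A} min_{b∈B} ‖a−b‖` (pixels
or mm), volumes, center-of-mass shifts, and paired Wilcoxon signed-rank
comparisons (exact null for n ≤ 25, ties handled exactly).

Because no public CT/CBCT phantom scans accompany the method, the package
ships a **digital deformable pelvis phantom**: bladder (200-400 cc),
~110 cc prostate, fixed rectum, bone blocks, water background, with analytic
smooth ground-truth deformation fields — so every stage of the pipeline is
verifiable against a known answer.

## A worked example

```r
library(featurelet)

pair <- make_benchmark_pair()           # baseline + deformed phantom (seeded)
ev   <- evaluate_benchmark(pair, registration_config(metric = "NC"))
ev$scores
#> # A tibble: 4 × 5
#>   structure dsc_before dsc_after hausdorff_before_px hausdorff_after_px
#>   <chr>          <dbl>     <dbl>               <dbl>              <dbl>
#> 1 bladder         77.7      88.2                3.61               2.83
#> 2 prostate        69.4      86.2                3.16               1.73
#> 3 rectum         100       100                  0                  0
#> 4 bone           100       100                  0                  0
ev$mae_vox
#> [1] 0.2232625
```

The bladder was inflated and the prostate shifted 12 mm by the ground-truth
deformation, so their pre-registration Dice scores (77.7, 69.4) measure the
residual error a rigid alignment would leave; featurelet registration raises
both (88.2, 86.2) while the deliberately static rectum and bone stay at 100.
The estimated field deviates from the analytic ground truth by 0.22 voxels
on average inside the structures. On the constructed intermodality pair
(`intermodality_worst_case()`, contrast-inverted fixed image) the same call
with `metric = "MI"` still improves the prostate Dice (69.4 → 90.4) while
`metric = "NC"` rejects every featurelet and leaves the scores unchanged —
the mechanistic reason MI is preferred for CT–CBCT registration.

A command-line interface wraps the same pipeline:

```sh
exec/featurelet phantom  --out runs/pair --seed 7
exec/featurelet register --fixed runs/pair/fixed.mha --moving runs/pair/moving.mha \
                         --metric NC --out runs/reg
exec/featurelet evaluate --reference runs/pair/ref --methods RR=runs/pair/rr \
                         --out runs/eval
```

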