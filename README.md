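# lvphase

Automatic phase selection for dynamic (4D) cardiac CT.

A 4D cardiac CT acquisition is an ordered series of co-registered 3D volumes
in Hounsfield units (HU), one per cardiac phase. Downstream perfusion
analysis — in particular automatic alignment of the heart along the
left-ventricular long axis — needs one specific phase: the one where the
contrast bolus has reached the **left ventricle (LV)** but has already washed
out of the **right ventricle (RV)**. Selecting that phase by eye costs
radiologist time during the examination; `lvphase` selects it automatically
from the time-dependent contrast distribution.

## The algorithm

Contrast agent flows RV → lungs → LV, so LV attenuation rises over the
phases while RV attenuation falls. With acquisition starting when contrast
is already high in the RV, the detector works on a simple voting rule.
For each voxel position *v*, let *I₁(v)* be its attenuation in the first
phase and *Iₘₐₓ(v) = maxₚ Iₚ(v)* its maximum over all phases (argmax ties
broken toward the earliest phase). Voxel *v* votes for the phase
*argmaxₚ Iₚ(v)* iff

1. **eligibility**: 30 HU ≤ *I₁(v)* ≤ 150 HU — blood not yet carrying
   contrast; first-phase RV voxels (already enhanced, ≫ 150 HU) are
   excluded, and
2. **increase**: *Iₘₐₓ(v)* ≥ *I₁(v)* · (1 + δ) (relative mode, default
   δ = 1) or *Iₘₐₓ(v)* ≥ *I₁(v)* + δ HU (absolute mode).

Votes accumulate in a *phase histogram* with one bin per phase; the fullest
bin (earliest on ties) is the detected phase. An all-zero histogram is an
explicit *no-detection*, a legitimate outcome rather than an error.

Before voting, every volume is shrunk by an integer-factor mean-pooling
filter: the user requests a target x-extent (the *matrix size*, default 16)
and each axis is pooled by `factor = floor(nx / matrix_size)`, each output
voxel being the mean of its `factor³` input block. This trades resolution
for speed; matrix size 16 keeps accuracy while matrix size 2 destroys the
signal (a useful negative control).

The package also ships a seedable synthetic first-pass phantom
(gamma-variate chamber enhancement over an ellipsoid geometry, with known
ground-truth peak phases) and the evaluation statistics used to score the
detector against human readers: exact Clopper–Pearson binomial confidence
intervals (`qbeta`-based), normal-approximation mean intervals, and the
Bonferroni threshold for pairwise matrix-size comparisons.

## Worked example

```r
library(lvphase)

ph  <- generate_phantom(phantom_params(seed = 3))
res <- detect_lv_phase(ph$series, detection_params(matrix_size = 16))
res
#> <lv_detection>
#>   detected phase: 10 of 20
#>   voting voxels:  122
#>   shrink factor:  4 (matrix size 16)

glance(res)
#> # A tibble: 1 x 6
#>   detected_phase n_phases eligible_voxels max_votes shrink_factor matrix_size
#>            <int>    <int>           <int>     <int>         <int>       <int>
#> 1             10       20             122       120             4          16

ph$truth$lv_peak_phase
#> [1] 10
```

The phantom's LV enhancement peaks at phase 10 of 20 by construction; the
detector recovers it from a 64×64×48 volume after shrinking to 16×16×12
(factor 4). Of the 122 voxels that passed both conditions, 120 voted for
phase 10. `tidy(res)` returns the full histogram as a tibble and
`autoplot(res)` plots it with the detected bin highlighted. At
`matrix_size = 2` the same phantom yields a no-detection: the 2×2×2 blocks
average lung, background and chamber voxels into values outside the
eligibility window.

Agreement scoring works on tabular case outcomes:

```r
oc <- case_outcomes(1:3, c(10L, 10L, NA),
                    list(c(9L, 10L), c(16L, 17L, 18L), 5L))
agreement(oc, level = 0.95)
#> # A tibble: 1 x 6
#>   successes total ratio lower upper level
#>       <int> <int> <dbl> <dbl> <dbl> <dbl>
#> 1         1     3 0.333 0.00840 0.906  0.95
```

A thin command-line wrapper lives at `inst/cli/lvphase.R` with subcommands
`detect`, `phantom` and `evaluate`; no-detection is reported as
`"detected_phase": null` in the JSON output, never via the exit status.

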