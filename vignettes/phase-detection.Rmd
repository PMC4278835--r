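---
title: "Phase detection for 4D cardiac CT: model, phantom and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase detection for 4D cardiac CT: model, phantom and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvphase)
```

## The problem

Dynamic (4D) cardiac CT records one 3D volume per RR-interval while a
contrast bolus transits the heart, plus a few late single acquisitions.
Automatic alignment of the heart along the left-ventricular long axis —
an early step of myocardial perfusion analysis — needs the phase in which
the left ventricle (LV) is strongly enhanced while the right ventricle
(RV) has already washed out. `lvphase` picks that phase from the contrast
dynamics alone, with no user interaction.

## The voting model and its assumptions

Contrast arrives in the RV first, crosses the lungs, and peaks in the LV
later. Acquisition protocols deliberately start only once contrast is
already high in the RV, to limit radiation exposure. The detector leans on
that assumption twice:

* **Eligibility.** Only voxels whose *first-phase* attenuation lies in the
  closed window 30–150 HU participate. Unenhanced blood sits in this
  range; already-enhanced RV blood (several hundred HU) does not, so the
  RV is silently excluded. Both bounds are inclusive (`detection_params()`
  exposes them as `hu_lower`, `hu_upper`).
* **Increase.** An eligible voxel votes only if its temporal maximum shows
  a sufficient rise over the first phase. The threshold has two modes:
  relative (`max >= first * (1 + increase_value)`, `increase_value` a
  fraction) and absolute (`max >= first + increase_value` in HU), both
  inclusive. The default is relative with `increase_value = 1`, i.e. at
  least a doubling — first-pass LV enhancement typically multiplies
  baseline blood attenuation severalfold, so a doubling separates genuine
  enhancement from noise and drift while remaining insensitive to the
  baseline level. The threshold is a visible parameter, never silently
  applied.

Each voting voxel contributes one count to the bin of the phase at which
its maximum occurs; the fullest bin wins. Two deterministic tie rules are
pinned because real histograms can be decided by a single voxel: the
temporal argmax takes the *earliest* phase attaining the maximum, and the
histogram argmax takes the earliest of tied bins. With a strictly
increasing time course a voxel can therefore never vote for phase 1; with
`increase_value > 0`, phase-1 votes arise only via exact ties.

An all-zero histogram returns `NA` — an explicit no-detection. This is a
first-class outcome (it genuinely occurs at extreme shrink factors), so it
is encoded in results and JSON (`null`), never as an error or exit code.

The algorithm trusts the supplied phase ordering and never re-sorts by
time stamp. It also never verifies that the RV is actually dark in the
selected phase; if acquisition starts *before* contrast reaches the RV,
first-phase RV voxels become eligible and can steal the vote (see the
phantom's `pre_rv_arrival` scenario below). Variants that detect
RV-enhanced phases, check RV contrast, or re-reference to a first local
maximum are out of scope.

## The shrink filter

Detection cost is dominated by the voxel count, so volumes are first
shrunk by integer-factor mean pooling. The user controls the factor
indirectly through the *matrix size* — the target number of voxels in x —
because inputs have square x,y-planes; `compute_shrink_factor(nx,
matrix_size)` returns `max(1, floor(nx / matrix_size))` and the same
factor applies to all three axes (a 512-voxel input at matrix size 128
gives factor 4). Contract details worth pinning:

* output extents are `ceiling(n / factor)` per axis; spacing scales by the
  factor;
* boundary blocks may be partial and are averaged over the voxels actually
  present — no zero padding, no truncation — which preserves the global
  mean as nearly as possible (exactly, on divisible grids);
* non-finite voxels are excluded from block means; an entirely non-finite
  block becomes `NaN` and is ineligible downstream;
* accumulation is in double precision (a 512³ sum overflows narrow
  integer types);
* the contract is purely functional: the output is independent of any
  execution partitioning, so results are reproducible run to run.

Factor 1 is a bitwise identity, and running at `matrix_size = nx` equals
running detection with shrinking disabled — both are pinned by tests, as
is element-wise equality with a naive nested-loop pooling oracle.

## The synthetic phantom

Patient data cannot ship with the package, so every claim is exercised on
a seedable phantom that emulates the acquisition the detector targets: a
dynamic window with one volume per RR-interval followed by late single
acquisitions, RV contrast already high at the first phase and washing out,
LV contrast peaking later.

Chamber enhancement follows a gamma-variate — the standard first-pass
bolus shape — normalised so its maximum equals `amplitude` at
`t0 + alpha * beta`:

* LV: `t0 = 1.2 s, alpha = 3, beta = 2 s, amplitude = 300` HU, peaking at
  7.2 s, which under the default protocol (17 dynamic phases at an 0.8 s
  RR-interval, then late phases 10, 20 and 35 s after the window; 20
  phases total, inside the typical 14–26 range) lands exactly on phase 10;
* RV: `t0 = -4 s, alpha = 2.5, beta = 1.6 s, amplitude = 400` HU — the
  bolus peaks at acquisition start and decays thereafter.

Geometry is two non-overlapping blood-pool ellipsoids (validated against
the grid and each other), a static myocardial shell around the LV,
lateral lung slabs and soft-tissue background. Default HU constants:
background and myocardium 50, lung −800, blood baseline 40. The baseline
of 40 HU places noiseless first-phase chamber voxels *inside* the 30–150
window, so the phantom genuinely exercises the eligibility filter, while
first-phase RV voxels (~440 HU) sit far above it. Gaussian noise
(default sigma 10 HU) is drawn from the phantom's own seed via an isolated
RNG stream: identical seeds give voxel-identical phantoms and the global
RNG is untouched. The default grid is 64×64×48 at 3 mm — small enough for
seconds-scale tests; pass `extents = c(128, 128, 120)` to mirror typical
pre-shrunk clinical inputs.

What the phantom does *not* model: anatomically realistic chamber shapes,
cardiac motion and gating artifacts, beam hardening, myocardial perfusion
enhancement, and patient-to-patient variability in curve shape. Passing
the recovery suite therefore shows the algorithm is implemented correctly
and behaves as designed under its stated assumptions — not that clinical
accuracy on real scanners is guaranteed.

The `pre_rv_arrival = TRUE` flag shifts the RV bolus to arrive after
acquisition start, reproducing the known failure mode: first-phase RV
voxels become eligible and the detector reports the RV peak phase instead
of the LV one. It exists for testing the limitation, not as a supported
acquisition mode.

## Evaluation statistics

Scoring against human readers is binomial: a case succeeds iff a phase was
detected and belongs to the case's reference set (typically the
intersection of two readers' selections, possibly several phases);
no-detection counts as failure, and the ratio runs over all cases.
Confidence intervals for the ratio are exact Clopper–Pearson, computed
from inverse incomplete-beta quantiles (`qbeta`): `lower = qbeta(alpha/2,
x, n-x+1)` (0 at `x = 0`), `upper = qbeta(1-alpha/2, x+1, n-x)` (1 at
`x = n`). The construction is deliberately asymmetric near 0 and 1 — for
0/29 the interval is [0, 1 − 0.025^(1/29)] ≈ [0, 11.9%] — and
conservative (coverage at least nominal, checked by simulation). Tests
cross-check it against `stats::binom.test`, an independent realisation of
the same interval.

Duration summaries use the normal approximation `mean ± z·sd/√n` (the
z-quantile, not t, matching the reporting convention for these timings),
and multiple pairwise comparisons among matrix sizes use a Bonferroni
threshold `alpha / m` (21 comparisons for 7 matrix sizes). Which paired
test to use for durations was an open choice; the package pins a paired t
over per-case durations as the documented assumption. Displayed
percentages round halves up to whole percents (`percent_round()`); raw
ratios are retained in serialized output.

## Numerical and design choices

* Phase numbers are 1-based in every interface and serialization; only
  internal array indices are 0-based.
* All phases of a series must share one grid; mismatches are an error, not
  a resampling request.
* HU calibration happens at read time (NIfTI slope/intercept applied by
  the reader); the detector assumes calibrated values.
* MetaImage support is a minimal uncompressed 3D reader/writer written in
  package code; NIfTI-1 (4D files and 3D series) goes through RNifti.
  3D series load in lexicographic filename order unless an explicit
  ordered vector is given.
* Problem sizes in the test suite were chosen for desk-scale runs: oracle
  equivalence on grids up to 9×9×9 × 6 phases (hundreds of randomized
  trials), phantom cohorts of 50 seeds at 64×64×48 × 20 phases. The
  recovery criterion (ground-truth LV peak recovered in at least 95% of
  seeds at matrix size 16, majority failure at matrix size 2) passes at
  100% on both sides under these conditions.

## Known limitations

The detector inherits the protocol assumptions discussed above: a late
acquisition start (RV already enhanced), short injection protocols (RV
dark again by the LV peak), and a field of view tight around the heart
(strongly enhancing lung regions inside a large FOV could masquerade as
the LV). None of these conditions are checked at run time. The phantom's
plausibility-based HU constants and curve parameters are fixed design
choices, not fits to any cohort.
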