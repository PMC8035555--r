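---
title: "Dose-difference-minimum planar QA: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-difference-minimum planar QA: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddmqa)
```

## The model

Patient-specific QA compares a measured planar dose `M(p)` (ion-chamber
array, coarse pitch, absolute dose in cGy(RBE)) with a TPS calculation
`C(q)` on a finer grid, both in an isocenter-centered mm frame. Two scores
are computed per measured pixel above a low-dose cutoff:

* **Gamma index.** The minimum over calculated test points of the combined
  distance/dose metric, with dose differences in percent of the global
  maximum dose and distance in units of the DTA criterion. The passing
  region in the (distance, dose) plane is one quadrant of an ellipse: the
  tolerated dose difference *decreases* as the distance grows.
* **DDM.** Over all test points within a *fixed* radius `r` of the pixel,
  the signed dose deviation of the point with the smallest deviation
  magnitude. The passing region is a rectangle: the dose tolerance is
  invariant across the search disk, and the search never leaves it. The
  sign (measured minus calculated) is kept so the heat map and histogram
  show direction as well as magnitude.

The radius `r` is not a free tuning knob: it is derived from measured spot
(beamlet) position accuracy. If the delivery system places 99.9% of spots
within 1 mm of nominal, dose agreement found beyond 1 mm is more plausibly
a coincidence than a correct delivery, and counting it inflates the pass
rate. `recommend_search_radius()` takes the smallest radius whose weighted
empirical coverage reaches the requested confidence (default 0.997, a
3-sigma-equivalent), rounded *up* to 0.1 mm — conservative in the only
direction that is safe.

### Assumptions

* Translation-only registration: setup errors are shifts; rotations and
  deformations are out of scope (the coarse DFT stage plus Nelder-Mead
  least-squares refinement recovers sub-pixel translations).
* Global normalization: dose differences are percentages of the calculated
  plane's maximum by default; the calculated plane is used because it is
  noise-free. `normalize_to = "measured"` switches to the measured maximum,
  and `criteria(normalization = "local")` gives the local variant.
* Measured pixels are never interpolated; only the calculated plane is
  resampled (bilinearly) onto the fine search grid. The detector model in
  the synthetic generator is accordingly point sampling, not
  volume averaging.
* Radial spot deviations are non-negative, hence non-normal; the one-sided
  t and Wilcoxon tests against the 1 mm limit lean on large-sample theory,
  which is how they should be read.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `dose_pct` | 3 | % of max dose | the common clinical dose tolerance; also the DDM pass tolerance |
| `distance_mm` (gamma DTA) | 2 | mm | the widely used gamma criterion for planar PSQA |
| `search_radius_mm` (r) | 1.0 | mm | ≥ 3-sigma coverage of measured beamlet accuracy (see below) |
| `low_dose_cutoff_pct` | 10 | % of max | pixels at or below it are unscored (strictly-above rule) |
| search-grid spacing | 0.1 | mm | ≥ 10x finer than r = 1 mm, so disk discretization error is negligible; exposed as `search_spacing_mm` |
| `max_search_mm` (gamma cap) | 3 × DTA | mm | a gamma search may range beyond the DTA; the cap bounds runtime and leaves every gamma < 3 exact |
| coarse mask | 20 | % of max | only meaningful dose patterns enter the DFT correlation |
| histogram bin width | 0.5 | % | resolves a 3% tolerance into six bins per side |
| detector pitch (synthetic) | 7.62 | mm | ion-chamber array chamber spacing |
| spot sigma / pitch (synthetic) | 5 / 5 | mm | typical scanned-proton lateral spot size at depth |

## Numerical choices

* **Disk membership** is the closed disk, tested on squared distance with a
  1e-9 mm^2 float guard; the brute-force test oracles use the same
  documented rule, so oracle-equivalence checks are exact rather than
  tolerance-laden.
* **Tie-breaking** is deterministic everywhere: the gamma argmin prefers
  smaller distance then smaller |dose difference|; the DDM argmin prefers
  smaller |deviation|, then smaller distance, then the positive sign;
  coarse-registration correlation ties resolve toward the smallest shift
  magnitude. Re-running any pipeline on the same inputs is byte-identical.
* **Boundaries.** Gamma passes at exactly 1 (inclusive, switchable); the
  DDM pass comparison is strict (`|DDM| < tolerance`, switchable). A
  uniform offset of exactly the dose tolerance therefore sits on the gamma
  boundary and passes, while the same offset fails strict DDM — both
  conventions are exposed because clinics differ.
* **Truncated disks** at the calculated-grid edge use the available test
  points and set a `truncated` flag; the search never extrapolates outside
  the calculated grid.
* **Degenerate inputs.** `r` below the search-grid spacing is a
  configuration error (the disk would be empty of guaranteed nodes);
  all-equal beamlet samples yield sd = 0 and an infinite sigma-limit with a
  warning; uniform (gradient-free) planes make the least-squares objective
  flat, in which case the initial shift is returned unchanged.
* **Folded-normal moment matching** in the deviation sampler solves for the
  underlying normal parameters by a bracketed root find to 1e-6; the
  mean/sd ratio of a folded normal is minimized by the half-normal
  (≈ 1.3237), below which a target pair is rejected as infeasible. Ratios
  above 1e3 use the normal limit directly.

## What the synthetic generator emulates — and what it does not

`synth_pair()` builds measured/calculated pairs with controlled error
structure: Gaussian-spot fields rendered on a TPS-like 1 mm grid, detector
point-sampling at 7.62 mm pitch, and four error families (global scale,
rectangular region offset, per-spot positional jitter, additive noise). The
region-offset and global-scale scenarios use a homogeneous square field —
the classic error-injection testbed, and the configuration in which the
gamma degeneracy (a 5% and a 15% region error giving the *same* pass rate)
is exactly reproducible.

It does **not** model depth structure (SOBP), range errors, detector volume
averaging, heterogeneities, angular dependence, or output drift. Passing
tests on these synthetics demonstrates the *algorithms* — oracle
equivalence, dominance and limit properties, the degeneracy and
global-underdose signatures, registration recovery — not clinical
performance on real plan libraries, which requires an institutional
measurement set.

## Design decisions taken where the design was open

* **Signed minimum.** The DDM minimum is taken over deviation magnitudes
  but the signed value is reported — required for a heat map and histogram
  that show direction. A magnitude-only reading would discard exactly the
  information the method exists to surface.
* **Which maximum normalizes.** "Global maximum of the dose plane" leaves
  the plane unnamed; the calculated maximum is the default here because it
  is noise-free, with a switch for clinics that normalize to the measured
  maximum.
* **Gamma beyond the DTA.** A gamma search can in principle range
  arbitrarily far. The engine caps it at `3 * DTA`: any pixel whose true
  gamma exceeds 3 is far outside any action level, so the cap changes no
  decision while bounding runtime.
* **Least-squares stage on interpolated values.** The fine registration
  stage optimizes over bilinearly interpolated calculated dose (on a
  0.25 mm grid by default), not nearest pixels — consistent with a
  continuous shift estimate and verified to recover 0.3–0.7 mm shifts
  within 0.05 mm.
* **Weights in hypothesis tests.** Clinical-use weights enter the moments
  and quantiles as frequency weights. For the t and signed-rank tests the
  samples are replicated deterministically in proportion to weight
  (normalized to sum to n, rounded); a summary function should not consume
  random numbers.
* **Relevant-point coverage measure.** The machine-relevant region is
  formalized as the rectangle |dose| ≤ tolerance, distance ≤ r with uniform
  area measure, giving the closed-form pi/4 ≈ 78.5% coverage for the
  1 mm gamma quadrant. Under this measure the 2 mm quadrant covers ≈ 95.7%
  of the rectangle; a probability-weighted measure (weighting distance by
  the observed spot-deviation density) would give different numbers and is
  deliberately not implied.
* **Optional mean-offset flag.** Some pass policies add a mean-offset
  condition (|mu| < 1%) to the DDM pass rate. That flag is reported in the
  JSON (`mu_within_1pct`) but kept out of `ddm_pass_rate()` itself.

## Problem sizes used in the checks

The test suite runs entirely on synthetic data at desk scale, chosen to
exercise every code path while staying quick: oracle equivalence uses 200
random 10 x 10 measured planes against ~1.5 mm calculated grids searched at
0.75 mm; the experiment-style checks use 10 x 10 cm fields at a 0.5 mm
search grid; registration recovery uses a 60 x 60 mm Gaussian-spot field on
the 7.62 mm detector. The default 0.1 mm search grid is used in the
documented examples and the CLI.

## Known limitations

* The sampled estimate of a 0.999 quantile from 10^4 spot deviations is
  noisy where it matters (the distribution's extreme tail): with the
  population quantile at 0.99 mm, the recommended radius lands on 1.0 mm
  for most seeds but on 1.1 mm for a substantial minority. More monitoring
  data tightens this; the rounding direction keeps it safe.
* 2D only: the volumetric (3D) DDM extension is not implemented.
* The DICOM reader handles exactly what a single-frame RT Dose plane needs
  (little-endian explicit/implicit VR, uncompressed 16/32-bit pixels); it
  is not a general DICOM implementation.
* Registration assumes the dominant residual spatial error after alignment
  is beamlet positioning — true for a tracked, laser-referenced setup, and
  an explicit prerequisite for interpreting `r` as machine accuracy.
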