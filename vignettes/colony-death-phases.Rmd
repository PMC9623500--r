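---
title: "Quantifying spatiotemporal cell death and sectoring in bacterial colonies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying spatiotemporal cell death and sectoring in bacterial colonies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Growing bacterial colonies imaged in time lapse with two fluorescence
channels — a constitutive live-cell reporter and a membrane-impermeant
dead-cell stain — show cell death that is structured in space and time. In
*Vibrio cholerae* colonies, contact-dependent toxin delivery (the type VI
secretion system, T6SS) drives two distinct death phases: an early phase
concentrated in a band along the expanding colony rim (roughly 8–40 h of
growth, "Phase 1"), and a later phase that appears in the colony interior
as a ring at about 44 h and propagates both inward and outward in a
wave-like manner ("Phase 2"). Rim death also creates the selective arena in
which clonal variant *sectors* — wedge-shaped outgrowths in which killing
is suppressed — arise.

`colonykym` turns such two-channel movies into the corresponding
quantities:

* radial **space–time kymographs** of each channel and of the dead/live
  ratio, built by iterative centroid tracking and circumferential
  averaging inside a sector-free pie-slice region;
* **phase statistics**: onset and cessation times, integrated death per
  phase, the Phase-1:Phase-2 ratio, and wave-front speeds;
* trainable **sector segmentation** (multi-scale features, random forest,
  Rényi-entropy threshold, particle filters) and sector area fractions;
* **strain comparisons** with Welch's two-sample t test.

Because suitable public movies do not exist, the package ships a seeded
synthetic movie generator with per-strain presets and full ground truth;
every stage of the pipeline is validated closed-loop against it.

## The synthetic colony movie generator

The generator is a phenomenological forward model, not a mechanistic
simulation of quorum sensing or T6SS dynamics. A colony of instantaneous
radius $R(t)$ carries a death-rate field

$$\rho(r,\theta,t) \;=\; \Big[\, \rho_{1}(r,t) + \rho_{2}(r,t) + \rho_u(t)
\,\Big]\; s(\theta, r, t) \; \mathbf{1}\{r \le R(t)\},$$

with a Gaussian rim band for Phase 1, a pair of travelling Gaussian fronts
for Phase 2, an optional spatially uniform term for constitutive killing,
and a suppression factor $s = 1 - \text{suppression}$ inside sector wedges.
The dead channel accumulates this field (plus a static founding-core
stain and camera background); the live channel is the reporter intensity
times colony occupancy minus the local accumulated death. Stage drift is an
integer-pixel random walk applied to both channels; noise is Poisson shot
noise (configurable gain) plus optional Gaussian read noise. Identical
parameters and seed give bit-identical movies.

### Choices behind the kernel shapes

The source observations fix *what* the phases look like (timings, location,
fold relations) but not any generative equations, so the kernel forms are
the package's own and were chosen as the simplest fields that reproduce the
described patterns under the package's own measurement definitions:

* **Saturating growth.** The radius grows linearly from 0.5 mm at the
  first acquisition (8 h) and saturates at 3.0 mm at ~43.5 h. Colonies
  stop expanding as nutrients deplete; numerically, freezing the radius
  just before Phase 2 begins also freezes the kymograph's radial-fraction
  bands, so the small interior Phase-2 signal is measured against a
  stationary background rather than a band that keeps sweeping outward.
* **Constant trail density.** The Phase-1 band has radial width
  proportional to $R(t)$ (`band_sigma_frac`, default 0.025) with its
  amplitude rescaled by $\sigma(t_0)/\sigma(t)$, so the stain surface
  density deposited along the swept trail is constant. The founding-core
  stain defaults to the exact complement of the trail's final 1-D profile.
  Together these make the interior dead/live ratio spatially uniform —
  the property that gives the Phase-2 detector a flat pre-onset baseline
  even though the dead stain is strictly cumulative.
* **Dead cells deplete the live reporter.** The live channel subtracts the
  locally accumulated death (including the founding core), which keeps the
  ratio seamless across the interior and reproduces the visibility of
  sectors as bright live wedges.
* **Phase-2 initiation burst.** The interior ring appears with a short
  multiplicative burst (4x for ~0.5 h). The described phenomenon is a ring
  that *appears* at a defined time; without the burst the cumulative ratio
  rises too gradually for any change-point rule to pin the onset to one
  frame.
* **Sectors.** Sectors nucleate at the rim at 9 h (shortly after rim death
  begins, matching the observation that sectors arise where Phase-1 death
  is high), occupy fixed 30° wedges drawn from the seeded RNG with a
  minimum angular gap of 32°, and multiply all death terms by
  $1-\text{suppression}$ (default 0.97). Presets differ in the *number* of
  wedges, so sector-area fold relations between strains are angular ratios
  by construction.
* **Amplitudes.** Absolute death magnitudes are not documented anywhere;
  only fold relations and timings are. The wild-type Phase-1/Phase-2
  amplitudes (2700 and 3.2 counts/h) were calibrated once, at design time,
  so that the package's own ratio-metric measurement returns a 10:1
  integrated-death ratio on noise-free default movies; the other presets
  are defined relative to the wild type (Phase-1 4-fold lower in the
  effector-less strains, Phase-2 absent in them, 10-fold-weaker Phase 2 in
  the naturally T6SS-silent background, and so on).

What the generator does **not** emulate: three-dimensional colony
structure, biomass thickening, stain bleaching or turnover, mechanistic
signalling, or mutation/selection dynamics. Passing the closed-loop tests
therefore shows that the measurement chain is correct and well-calibrated
on movies with these statistics — not that it is robust to every artefact
of real microscopy.

## The measurement chain and its numerical choices

`analyze_colony_movie()` runs the full chain: translation registration
with mechanical-jump removal (frame-to-frame FFT cross-correlation; only
displacements above 3 px are corrected, slow drift is left for the tracker),
iterative intensity-weighted centroid tracking (support disk 1.2x the
current radius estimate, tolerance 0.5 px; weights are capped at 25% of the
movie maximum so the estimate follows the colony footprint rather than
interior intensity structure), boundary detection at a fixed 10% of the
movie-wide maximum live intensity with a running maximum enforcing monotone
growth, automatic selection of a 30°-wide sector-free wedge (candidate scan
at 1° steps minimising a sector score; a manual wedge overrides it),
circumferential averaging in 1-px radial bins, and the linear dead/live
ratio kymograph (denominator floored at 0.1% of the live dynamic range;
bins within 2 px of the boundary are flagged missing because the
antialiased rim edge makes ratios there meaningless).

Phase quantities follow from the ratio kymograph:

* **Regions.** Phase 1 occupies the rim band $[0.85, 1]\,R(t)$ and
  Phase 2 the interior band $[0.2, 0.8]\,R(t)$ (disjoint by construction);
  both are configuration-exposed.
* **Windows.** `detect_phase_window()` flags the first/last run of at
  least `m = 3` frames in which the region-mean ratio exceeds
  `baseline + max(k·sigma, 0.04·(q95 − baseline))`, with the baseline the
  20th percentile of the series and `sigma` the robust frame-to-frame
  noise (`mad(diff)/sqrt(2)`). The quantile baseline is used because the
  rim band is already active at the first acquisition, so "the first few
  frames" are not death-free for Phase 1; the dynamic-range floor keeps
  slow structural drifts of a few percent from triggering. The pipeline
  additionally treats an interior onset that precedes rim-death cessation
  as bleed-over rather than a genuine second phase.
* **Integrals.** `integrated_death()` sums the positive part of the
  baseline-subtracted ratio over the masked cells with annulus weights
  $r\,\Delta r\,\Delta t$, so the statistic approximates a whole-colony
  area integral. The baseline is the band's phase-free level, estimated as
  the smaller of its median ratio over the first and last four frames
  (pre-onset for the interior band, post-cessation for the rim band). The
  Phase-1:Phase-2 ratio is reported as infinite when the Phase-2 integral
  is below 2% of Phase 1's — the operational reading of "did not occur".
* **Fronts.** `track_wave_front()` finds, per frame, the innermost and
  outermost radii where the baseline-subtracted ratio crosses 35% of the
  running peak, and fits robust least-absolute-deviation lines; outward
  speeds are positive, inward negative.

## Sector segmentation

The dead-channel maximum projection of the first 38 h (cumulative stains
make this the 38-h frame after registration) is background-subtracted with
a rolling ball (flat-disc grayscale opening; the full-scale default radius
is 1000 px, which acts as a flat-field on desk-scale images). A random
forest (100 trees, fixed seed) on a multi-scale feature stack (raw
intensity; Gaussian, gradient magnitude, Laplacian, difference of
Gaussians and local variance at sigma 1–16 px) yields a per-pixel sector
probability; the Rényi-entropy rule (orders 1/2, 1, 2 combined by the
published three-threshold weighting) thresholds the probability histogram
over the stained footprint; 8-connected components pass a particle-size
cutoff (0.1% of the colony area) and a class-probability filter (mean
sector probability at least 0.5 — the automatic threshold otherwise
collapses into the background mode when sectors occupy little area).
Manual curation is represented by a reproducible drop-list, never
interactive state.

Two domain choices matter for interpretation. The analysis support is the
*radially closed stained footprint*: sector wedges cut the stained annulus
open to its boundary, so the support is the disk out to the stained radial
extent. And pixel-level recall/precision against ground truth are
evaluated within that support: at the projection end the outermost ~7% of
the colony radius has not yet been reached by rim death, and a not-yet
stained rim pixel carries no signature of sector identity in either
channel, so no dead-channel classifier can recover it. Sector *area
fractions* always use the full live-channel colony footprint as the
denominator, which cancels in all between-strain fold changes.

## Strain comparisons

`compare_strains()` is Welch's two-sample t test (unequal variances,
Welch–Satterthwaite degrees of freedom, two-tailed), with group means, SD,
SEM, the fold change of means, and the significance stars
`*, **, ***, ****` at p < 0.05, 0.01, 0.005, 0.0005. Its type-I error is
verified by Monte-Carlo in the test suite.

## Worked example

```{r, eval = FALSE}
library(colonykym)

sim <- generate_movie(make_preset("wt_2740_80"), seed = 0)
ps <- analyze_colony_movie(sim$stack)
print(ps)
#> phase_summary
#>   final radius: 3.01 mm
#>   P1: [8, 41.5] h, integral 3.721
#>   P2: [44.5, 56] h, integral 0.3854
#>   P1:P2 integrated death ratio: 9.66
#>   P2 front speeds: outward +0.0345, inward -0.0226 mm/h
```

The movie starts at 8 h, so rim death is detected from the first frame and
persists (as stain in the moving rim band) until ~41.5 h; the interior ring
is detected at the first frame after its 44-h initiation; the integrated
rim death exceeds interior death about 10-fold; the colony rim ends at
~3 mm; and the interior fronts move outward and inward at a few hundredths
of a millimetre per hour.

## Problem sizes and reproducibility

The reference geometry is 512 x 512 px at 0.012 mm/px with 0.5-h frames
over 8–56 h (97 frames, rim at ~250 px) — small enough to generate and
measure in seconds per colony, large enough for ~20 radial bins in the rim
band. The test suite exercises the full acceptance loop at this geometry
(10 seeds for phase recovery, 7 seeds per strain for sector folds, 5
held-out seeds for segmentation) and uses a 168-px variant for unit tests.
All randomness flows from explicit seeds; repeated runs are bit-identical.

## Known limitations

* The phase-window detector assumes the pre-onset level of a region is
  visible either at the start or at the end of the movie; a phase spanning
  the entire movie in a region with no quiet period would be reported with
  a degenerate window.
* Rigid-body registration estimates rotation by a bounded search (±5°,
  0.1° refinement); it is intended for the slow stage drift of colony
  time-lapses, not large rotations.
* The rolling-ball background uses a flat disc structuring element; for
  the intended regime (element much wider than any foreground structure)
  this matches ball-type backgrounds to within the stated tolerances.
* Sector wedges are assumed radial and non-overlapping, as realized by the
  generator; strongly curved or merging sectors in real data would need a
  manual wedge and curated ROIs.
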