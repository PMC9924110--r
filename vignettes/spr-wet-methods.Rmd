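---
title: "Methods: SPR/WET quality assurance for proton immobilization devices"
author: "protonWET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SPR/WET quality assurance for proton immobilization devices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonWET)
```

## Overview

`protonWET` models the commissioning workflow by which a proton therapy
clinic validates the stopping-power ratio (SPR) that its treatment planning
system (TPS) assigns to immobilization devices, and quantifies what an SPR
error does to a plan.  The pipeline has five stages, each usable on its
own:

1. **Synthetic data** — an analytic Bragg-curve/detector model and voxel
   phantoms with exactly known ground truth;
2. **Range-shift measurement** — distal R80/R90 extraction and WET/SPR
   estimation from reference/sample IDD pairs;
3. **TPS emulation** — HU→density→SPR calibration and radiological ray
   tracing through CT phantoms;
4. **Density override and dose recalculation** — a broad-beam SOBP engine
   with setup/range robustness scenarios;
5. **Statistics** — DVH metrics, worst-case and beam-specific coverage,
   and an exact Wilcoxon signed-rank test.

Because every synthetic object carries its generating truth (injected WET,
injected SPR error), each downstream estimate can be checked against a
known answer — the property the test suite and `scripts/acceptance.R` are
built around.

## The pristine Bragg curve and the virtual MLIC

The depth-dose model is a power-law stopping approximation with two terms,

$$ d_0(z) \propto (R - z)^{-0.435} + b\,(R - z)^{0.565}, \qquad z < R, $$

convolved with a Gaussian of width $\sigma$ representing range straggling.
The first term is the quasi-singular Bragg peak (its exponent follows from
a range–energy power law $R \propto E^{1.77}$), the second a slowly varying
entrance contribution; $b$ is solved numerically so that the entrance-to-
peak signal ratio equals `plateau_entrance_ratio`.  The convolution is
evaluated once on a 0.02-mm grid, with the integrable singularity handled
by analytic cell averaging, and the whole curve is then shifted so that its
distal R80 sits exactly at `nominal_range_mm`.  A closed-form Bragg model
exists in the literature but requires parabolic-cylinder functions; the
convolved power law was chosen because it needs only base R, and the
pipeline only requires a smooth, strictly monotone distal falloff with a
controllable plateau.

Defaults (all configurable through `bragg_params()`):

* `nominal_range_mm = 259` — distal R80 in water of a 200-MeV beam;
* `straggling_sigma_mm = 3.1` — 1.2% of the range, the standard straggling
  fraction for protons in water;
* `plateau_entrance_ratio = 0.30` — typical for a single high-energy IDD;
* `n_chambers = 180`, `chamber_pitch_mm = 2` — the multilayer ionization
  chamber geometry; chamber $i$ (0-based) is centred at
  $(i + 0.5) \times \mathrm{pitch}$, so the detector spans 360 mm;
* `noise_cv = 0.005` — independent multiplicative Gaussian noise per
  chamber (set to 0 for noiseless studies).

A device of water-equivalent thickness $w$ upstream of the detector is
modelled as an exact depth shift, `signal(z) = pristine(z + w)`.  This
deliberately ignores the change in scatter and straggling introduced by
the device — appropriate for the thin, low-density materials under study,
and the reason the noiseless pure-shift law (R80 and R90 each decrease by
exactly $w$) holds by construction.

### Sampling resolution and the range estimator

R80/R90 are defined as fractions of the **curve maximum** (the standard
proton range convention) and located by linear interpolation on the most
distal decreasing segment that brackets the threshold, so spurious shallow
dips from noise cannot capture the crossing.  At the clinical 2-mm pitch,
linear interpolation of a $\sigma \approx 3$ mm falloff carries a
phase-dependent depth bias of up to about 0.2 mm for a *single* threshold;
averaging the R80 and R90 shifts of the reference and sample curves cancels
most of it, leaving the WET estimator accurate to better than 0.1 mm
noiseless (verified over injected thicknesses of 0.5–30 mm) and essentially
unbiased under 1% chamber noise.  No smoothing is applied by default; the
estimator operates on the raw chamber readings.

## Calibration and ray tracing

The TPS side uses a two-stage piecewise-linear calibration, HU→mass
density and density→relative stopping power, mirroring the clinical
pathway; a single-stage HU→RSP table is also accepted.  Out-of-domain
values clamp to the end nodes (the safe TPS behaviour; no extrapolation).
The bundled `default_calibration()` has nodes at air, lung, adipose,
water, muscle and bone surrogates — plausible values for a 120-kVp scan,
shipped as a package fixture, not a measured clinical curve.

WET in the TPS is the radiological path length: an exact Siddon-style
traversal accumulates (segment length × voxel RSP) over every voxel
boundary crossing, optionally restricted to the device contour.  Physical
thickness is the in-contour intersection length of the same probe line,
taken perpendicular to the device surface by default (the orientation is
configurable; clinical practice does not standardise it).  Grids use
`dim = (nx, ny, nz)` with x fastest (R's column-major layout, matching the
NRRD `sizes` convention); world position of voxel (i, j, k) is
`origin + (index − 0.5) × spacing`, all lengths in mm.

## Density override and the dose engine

The override multiplies RSP inside the device contour by
`measured_spr / tps_spr`.  A ratio (rather than additive) correction was
chosen because stopping power is approximately proportional to mass
density for a fixed material, which also makes the override exact: a
repeated TPS measurement through the contour returns the measured SPR to
machine precision.  Working in RSP space unifies the two clinical override
mechanisms (assigning a density or a CT number).

The dose engine is a declared surrogate for clinical Monte-Carlo or
pencil-beam algorithms: broad, divergence-free beams in the axial plane
with a hard-edged circular aperture and no lateral scatter or penumbra.
Per voxel and beam, the water-equivalent depth from the beam entry is
computed exactly by cumulative summation for axis-aligned beams and by
0.5·min(spacing) midpoint ray marching otherwise, then mapped through the
SOBP curve: relative dose 1.0 on `[range − modulation, range]`, a
raised-cosine distal falloff whose 80%–20% width is `distal_falloff_mm`
(default 4 mm, a typical clinical SOBP falloff), and a raised-cosine
proximal ramp of the same shape.  The falloff reaches zero at
`range + 2.44 × falloff`.  The raised cosine was preferred to a logistic
because it is exactly 1.0 at the plateau edge, exactly 0 beyond a finite
support, and continuously differentiable — properties the pullback and
bounding tests rely on.

What this engine reproduces correctly is the *longitudinal* consequence of
an SPR error: overriding an upstream slab of thickness $t$ from RSP $r_1$
to $r_2$ pulls the distal dose edge back by $t\,(r_2 - r_1)$ (verified to
0.2 mm on 1-mm grids), raises the dose to structures proximal of the
plateau and lowers it distally.  What it cannot reproduce is lateral
scatter, penumbra, aperture-edge effects, or any absolute dosimetry — all
dose comparisons in the package are therefore relative and directional.

## Robustness scenarios

Plans carry a setup uncertainty (mm) and a relative range uncertainty.
Robustness evaluation recomputes dose in 12 scenarios — the 6 cardinal
setup shifts at the setup uncertainty crossed with stopping power scaled
by (1 ± range uncertainty) — plus the nominal case kept separately.  The
composition is a package design choice; clinical systems do not publish a
standard enumeration.  Setup shifts are applied as rigid isocenter
translations: for a laterally unbounded broad beam a translation would be
invisible, which is why beams carry a finite aperture.  Worst-case DVH
metrics take the per-metric extremum across the 13 scenarios (minimum for
V95/D95/mean/conformity, maximum for max dose) — scenario-level worst
case, not a voxel-wise worst-case dose.

## DVH metrics and the Wilcoxon test

V95, max and mean dose use exact voxel counting; D95 is the k-th largest
voxel dose with $k = \lceil 0.95\,n \rceil$; the RTOG conformity index is
the prescription-isodose volume over the whole grid divided by the target
volume.  Binning (default 1000 bins to 110% of prescription) is used only
for plotted DVH curves.  Maximum dose is the maximum voxel dose; no
small-volume surrogate such as D0.03cc is applied.

The paired before/after comparison uses a Wilcoxon signed-rank test with
the reduced-sample convention (zero differences dropped) and average ranks
for ties.  For n ≤ 25 the two-sided p-value is exact, computed by dynamic
programming over doubled ranks — algebraically identical to enumerating
all $2^n$ sign assignments, which the tests verify literally for n ≤ 10 —
and for larger n a normal approximation with continuity and tie correction
is used.

## The patient-like phantom

`generate_patient_phantom()` builds a head-and-neck-like geometry: a
water-equivalent cylindrical body (HU 0, default radius 60 mm), a
spherical CTV (default radius 15 mm), spherical OARs placed proximal and
distal to the CTV along the posterior beam axis, and a cushion slab under
the body whose CT number maps to a prescribed TPS RSP.  Beams (default
posterior 180° through the cushion plus lateral 90°) get their SOBP range
and modulation from ray-traced water-equivalent path lengths to the CTV
edges plus a 5-mm WEPL margin, and an aperture of CTV radius + 6 mm.
Default grid spacing is 2 mm with a 40-mm axial extent (~10^5 voxels),
which keeps a full 13-scenario robustness evaluation of a two-beam case in
the order of seconds; the acceptance checks run the dose engine at 1-mm
spacing on a slab geometry where the pullback law needs sub-voxel
resolution.

What the generator emulates: the geometry class whose posterior fields
traverse the immobilization device, with realistic SPR errors (−21% to
−35%, the range reported for cushions, vacuum bags and base-of-skull
inserts) and realistic WET errors (&lt; 1 mm for the cushion).  What it does
not emulate: anatomical heterogeneity, realistic contour shapes, beam
arrangements beyond 2–4 coplanar fields, or absolute dose levels.  Passing
tests therefore demonstrate the correctness of the *method* — estimator
calibration, closure of the measurement loop, directional dosimetric
response — not clinical effect sizes, which depend on private patient
data.

## Numerical and degenerate-input choices

* Exact threshold hits on a chamber reading return that chamber's depth;
  multiple crossings take the most distal decreasing bracket.
* A curve whose maximum sits at the deepest sample (truncated falloff)
  raises a range-not-found error rather than extrapolating.
* Negative WET (sample deeper than reference) warns instead of failing —
  swapped inputs are a real QA failure mode worth surfacing.
* Rays that miss the grid or the contour return 0 with a warning;
  zero thickness is an error at the SPR step.
* The slab generator requires ≥ 4 voxels across the slab thickness; the
  virtual scanner otherwise cannot resolve the device it is meant to scan.
* All classed errors/warnings carry `protonWET_*` condition classes, so
  callers can discriminate failure modes programmatically.

## Reproducibility

Every stochastic element (chamber noise, per-location RSP jitter) is
seeded explicitly; `run_study()` derives all stage seeds from the single
configuration seed and writes a run log with the seed and package version,
making report bundles byte-reproducible.  `scripts/acceptance.R --seed S`
re-derives every reported quantity from scratch under seed `S`.
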