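---
title: "Simulating irregular breathing, 4D CT and gated dose delivery with breathe4d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating irregular breathing, 4D CT and gated dose delivery with breathe4d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

breathe4d is a fully synthetic, desk-scale model of a dynamic thorax phantom
experiment in lung stereotactic body radiotherapy (SBRT): a 20 mm
soft-tissue sphere inside a very low density insert translates
longitudinally (cranio-caudally) under regular or irregular breathing; it is
imaged by retrospective phase-binned 4D CT, contoured, planned, and treated
with gated or nongated intensity-modulated delivery while a radiochromic
film moves with it. Every stage — breathing trace, scanner, contouring,
planning, delivery, film and gamma analysis — is an explicit, seeded model,
so the geometric and dosimetric consequences of breathing irregularity can
be studied end to end and reproduced bit for bit.

This vignette explains the models, their assumptions, the tunable
parameters, and the design decisions taken where the physical chain had to
be collapsed to something a laptop can run. It states no numbers that the
package's tests and `scripts/acceptance.R` do not themselves compute.

## Breathing traces

The regular pattern is a sinusoid, `displacement(t) = -A cos(2*pi*t/T)`,
with amplitude `A = 15` mm (a ±15 mm longitudinal range) and period
`T = 4` s. Phase 0% is the end-inhale extreme, where the target sits at
`-A`; phase 50% is end-exhale at `+A`. The phase-velocity identity
`V(p) = -(2*pi*A/T) sin(2*pi*p/100)` then puts the peak speed, `2*pi*A/T`,
at phases 25% and 75%.

Irregular traces (`generate_irregular()`) are piecewise-cosine half-cycles
joined at turning points: each cycle draws a peak-to-trough range and a
period from truncated normal distributions around class base values, and the
waveform interpolates trough → peak → next trough with zero slope at every
extreme, so it is continuous and visually quasi-sinusoidal. Four classes are
parameterized — slightly irregular (S-I, 18.6 mm / 2.83 s, jitter fractions
0.016/0.035), amplitude irregular (A-I, 16.9 / 3.47, 0.13/0.10), period
irregular (P-I, 17.8 / 4.35, 0.04/0.18), and period-and-amplitude irregular
(P+A-I, 13.3 / 3.50, 0.23/0.31). The jitter fractions are the ratio of the
reported cycle SD to the mean for each class, so `trace_stats()` on a long
generated trace recovers the class mean ± SD. What this generator does *not*
emulate: baseline drift, end-exhale dwell asymmetry, cardiac contamination,
or surrogate-to-target phase lag; conclusions about those features of real
breathing are outside what a passing test shows.

Cycle boundaries are detected as end-inhale extremes (local maxima of the
inhale excursion) with a prominence of at least 25% of the trace range;
retrospective phase is the elapsed fraction of the enclosing cycle. The
default surrogate sampling rate is 25 Hz.

## Phantom and 4D CT

The digital phantom is rasterized on a 1 mm isotropic grid (about
61 × 91 × 61 voxels): a water-equivalent body block (0 HU), a foam insert
(-790 HU), and the target sphere (+40 HU) centred on the longitudinal axis.
Partial-volume fractions at the sphere edge come from 3× supersampling per
axis, which keeps the voxelized sphere volume within about 1% of the
analytic value and makes a half-occupancy threshold an accurate edge
criterion. Imaging noise is additive Gaussian (20 HU per acquired image).

The 4D CT model advances the couch in 10 mm slabs; at each couch position
images are taken every 0.25 s for 6 s (longer than any expected cycle, so
every phase bin is seen at least once per slab). Each image's *nominal* time
is assigned a retrospective phase, while its *content* is rendered at
`displacement(t + time_delay)`: this single latency rule produces both the
phase-dependent position errors of a regular trace (largest at the fastest
phases, 25% and 75%) and, because different slabs sample different cycles,
the mis-binning of irregular breathing. Each phase bin of each slab keeps
the image whose phase is nearest the bin center (ties to the earlier image).
The default latency is 0.14 s; dividing the phase-25% centroid deviation by
the phase-25 speed recovers it, which is exactly how the acceptance script
estimates it. A constant (flat) trace has no detectable cycles; the
simulator then renders every phase at the constant displacement, so
zero-motion 4D CT degenerates to the static scan.

Numerical choices worth knowing: acquisition starts at the first detected
cycle boundary (the gating learning period), and the required trace length
is checked up front with an informative error.

## Contouring: GTV, ITV, PTV

`segment_target()` thresholds a volume and keeps the largest 26-connected
component that does not touch the volume border (the body block also
exceeds any sensible threshold but always touches the border; with phantom
provenance attached the search simply restricts to the insert interior).
The GTV default threshold is the midpoint of insert and target HU
(-375 HU), i.e. the half-occupancy edge — a reproducible stand-in for the
study's auto-contour-plus-manual-edit workflow.

ITVs on MIP/AIP projections use a lower default, 15% occupancy (-666 HU).
This is a deliberate modelling decision: averaging over phases dilutes a
moving target's HU in proportion to occupancy, and a half-occupancy rule
would erase most of an AIP target that dwells anywhere less than half the
time — producing near-empty AIP ITVs instead of the modest AIP-vs-MIP
deficits seen clinically. A lung-window-like 15% occupancy reproduces the
expected ordering (AIP ⊆ MIP at any matched threshold, with the AIP deficit
growing from gated to nongated phase ranges) while staying far above the
projection noise floor. The threshold is an explicit argument everywhere,
so sensitivity to it can be explored directly.

The PTV is a Euclidean dilation of the GTV/ITV by a uniform 5 mm margin
(voxelized ball structuring element). The theoretical envelope of a sphere
of radius `r` translated over range `L` — sphere plus cylinder,
`4/3 pi r^3 + L pi r^2` — is the reference for nongated regular-motion
ITVs, which approach it from below as the phase count grows.

## Planning and delivery

The multi-beam 3D problem is collapsed to the coronal film plane. A plan's
dose is a product of error-function edge profiles (penumbra sigma 3 mm) at
the PTV projection's bounding box expanded by an aperture margin, times an
SBRT-style internal boost: each axis profile is multiplied by
`1 + 0.09 exp(-(u - c)^2 / (2 * 8^2))`, placing the prescription at the PTV
surface and a hotspot of roughly 125–135% of it toward the center, as in
prescribe-to-a-lower-isodose-line practice. The dose is renormalized so
exactly 95% of the PTV projection receives the 6 Gy prescription, and the
margin grows in 0.5 mm steps until at least 99% receives 90% of it, under a
1.35 × Dp hotspot cap.

Delivery integrates fluence in 10 ms steps. The sliding aperture is modeled
per 5 mm leaf row; the IMRT technique delivers the fluence in 7 sequential
sweep passes, the arc technique in 2 slower passes of the same total
fluence at the nominal 1200 MU/min dose rate (so the techniques differ only
in temporal segmentation, consistent with the study finding no
technique effect). A target-frame point accrues dose-rate-scaled fluence
whenever its lab-frame position sits inside its row's instantaneous window.
Finally the accumulated plane is shifted by the PTV-centroid offset,
emulating the image-guided registration of the measured film to the plan.

Two mechanisms make motion matter:

* **Internal-gradient blurring.** In the target frame, a point's dose is the
  exposure-time average of the lab profile at its shifted positions.
  Because the planned dose is deliberately heterogeneous inside the field,
  this average under-doses the hotspot and over-doses its shoulders in
  proportion to the motion variance — roughly an order of magnitude larger
  for the full nongated excursion than for the gated residual. This is the
  dominant, systematic interplay term, and it is why gated delivery
  "protects" the gamma comparison even though both deliveries place the
  prescription on the target.
* **Row-crossing texture.** Adjacent leaf rows sweep with slightly
  decorrelated pass phases (random-walk offsets, step 2% of a pass period),
  so motion across rows fragments exposure and adds a small stochastic
  texture. At the default level this term is minor; it exists so that
  perfectly flat regions are not unrealistically noiseless.

Gating uses a causal, prospective phase estimate: elapsed fraction of the
predicted period (mean of the last three cycles) since the last end-inhale
boundary, with beam-on inside the 30–70% end-exhalation window and a 0.1 s
on/off latency. Under irregular periods this estimate diverges from
retrospective phase — mis-gating, quantified by `misgating_fraction()`. Two
position safeguards mirror clinical practice: an adaptive corridor derived
from recent exhale peaks, or (preferred, and used by the study pipeline) a
fixed corridor configured at planning from the gated ITV so that the target
cannot be treated outside the planned envelope
(`gate_corridor_from_itv()`). Residual mis-gating inside the corridor is
real and is absorbed by the 5 mm PTV margin — the same conclusion the
physical experiment reaches. Without any position validation, the most
irregular class fires a quarter of its beam-on time at wrong-phase
positions outside the gated field, and gated delivery degrades below
nongated; we consider that a model of a gating system no clinic would
deploy rather than a property of gating.

## Film dosimetry

The generative sensitometric truth is a saturating netOD curve,
`netOD(D) = 0.12 D / (1 + 0.05 D)` — EBT3-like in shape and exactly
invertible. Exposure plus scanning maps dose to a 16-bit pixel value,
`PV = 40000 * 10^(-netOD)`, with 0.3% multiplicative Gaussian scanner
noise. Calibration exposes uniform patches at 0, 0.5, 1, 2, 3, 4, 5, 6 and
8 Gy and fits the standard third-order netOD-to-dose polynomial, whose
monotonicity over the fitted range is verified; the cubic is then an
approximation of the truth exactly as a fitted sensitometric curve is in
practice, and the tests bound both the noiseless round-trip error and the
noisy-calibration error against the prescription. Scan-to-dose clamps
netOD to the calibrated range (warning on saturation).

## Gamma analysis

`gamma_2d()` implements the dose-difference / distance-to-agreement index
at 3%/1 mm with global normalization to the 6 Gy prescription, a 10%
low-dose cutoff, a 3 mm search radius, and sub-grid bilinear interpolation
of the evaluated plane at a 0.1 mm step. The step is snapped to an exact
divisor of the dose-grid spacing so every reference point lies on the
interpolation lattice, and the offset search is sorted by distance with an
early exit once the distance term alone exceeds the worst running minimum —
an exact optimization, verified point-for-point against an exhaustive
brute-force oracle in the test suite. The scored region is the GTV's
film-plane projection dilated by 2 mm. Group comparisons use the standard
paired t-test at the 0.05 level, with zero-variance differences reported as
degenerate rather than silently significant.

## The study grid

`run_study()` reproduces the whole experiment from one seeded
configuration: static CT and regular-motion 4D CT for the position and
volumetry tables; per-class 4D CT, MIP/AIP ITVs and their gated/nongated
variations; and a dosimetric grid of 4 irregular classes × {AIP, MIP} ×
{gated, nongated} sliding-window plans, each delivered in 5 independently
seeded sessions (10 sessions per class) against fresh traces of the same
class, through the film model to gamma passing rates and paired tests.
Problem sizes — the ~0.34-Mvoxel phantom, 10-phase geometry grids, 5
sessions per cell — are chosen so the full default grid runs in a few
minutes on one core while leaving every ordering statistically resolvable;
all of them scale up through the configuration if finer answers are wanted.
The report bundle (`table2.csv` … `table5.csv`, `tests.csv`) is stamped with
an MD5 config hash and is byte-identical across reruns of the same
configuration.

## Known limitations

* No X-ray transport: volumes are rendered, not reconstructed, so streaks,
  partial projections and helical-pitch artifacts are absent; mis-binning
  appears only as between-slab position inconsistency.
* The delivery model is 2D (film plane), with separable fluence and a
  simplified leaf structure; MU optimization, heterogeneity corrections and
  dose calculation algorithm differences are out of scope.
* The film model omits lateral scanner artifacts, post-exposure darkening
  and lot variability.
* Measured passing rates for irregular patterns on real hardware depend on
  the physical film/linac chain; the package asserts orderings and bands,
  not those exact percentages.
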