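---
title: "Methods: simulating and measuring longitudinal spine dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and measuring longitudinal spine dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinedyn)
```

`spinedyn` analyses chronic two-photon image stacks of single unbranched
dendritic segments: it traces the dendrite, detects and filters spines,
matches them across imaging sessions by arc-length position, and summarises
density, addition/elimination/turnover and normalized spine intensity. This
vignette explains the models and the numerical choices, what the synthetic
data do and do not emulate, and the limitations a user should know about.

## The forward model (simulator)

A scene programs the complete ground truth of a multi-session experiment:

- a **backbone**: a natural cubic spline through control points spanning the
  field diagonally, mostly in-plane with a ±1 µm z excursion — an apical
  dendrite segment imaged near-parallel to the focal plane;
- **spines** on a jittered arc-length grid with programmed protrusion length
  (default 1–2 µm from the tube surface), axis elevation above the imaging
  plane (default 0–30°), head radius (default 0.4–0.6 µm, i.e. head
  diameters in the common 0.8–1.2 µm range — smaller heads are not reliably
  visible under the axial PSF below, for an automated detector and a human
  alike), per-session presence realizing the requested gain/loss schedule,
  and per-session brightness multipliers (baseline fixed at 1);
- **acquisition geometry**: 0.18 µm lateral pitch, 1 µm z-step. The default
  stack is 192 × 192 × 21 voxels (≈ 35 × 35 × 21 µm), chosen so the default
  schedule fits on the backbone with inter-spine spacing above the match
  tolerance; one session renders in a few seconds.

Rendering rasterizes each structure (shaft tube, spine neck, spherical head)
by **partial volume**: every voxel receives `amplitude × occupied fraction`,
estimated on a 3 × 3 × 5 sub-voxel grid. This matters at a 1 µm z-step,
where structures routinely straddle planes; a voxel-centre-inside test
renders a straddling 0.5 µm head almost invisible, which is not how a
microscope behaves. Overlapping structures combine by maximum (fluorophore
saturation rather than additivity — adequate for geometry-level testing).

The noise model is the standard simple forward chain: anisotropic Gaussian
PSF (default σ = 0.25, 0.25, 0.9 µm), constant background offset (10
counts), Poisson shot noise, additive Gaussian read noise (σ = 5), 16-bit
quantization. With the default shaft amplitude of 100 counts the structure
SNR is ≈ 8.6 (`render_snr()`). Event rates (1–2 gains/losses per interval on
8–10 spines) and densities (≈ 0.3–0.4 spines/µm) are plausible
literature-scale values for this preparation, not measured ones.

**What the simulator does not emulate:** motion artifacts and slow drift
within a session, bleaching, vasculature and neighboring neurites, branched
arbors, spine morphological subtypes, and non-uniform illumination. Passing
the recovery suites therefore demonstrates correctness of the measurement
chain under controlled conditions, not performance on arbitrary real data —
on real stacks the manual-annotation and manual-correspondence override
paths exist precisely because automation degrades with clutter.

## Backbone tracing and arc coordinates

Tracing runs on a noise-suppressed copy of the stack (Gaussian σ = 1, 1,
0.6 voxels; edge-renormalized so flat regions stay flat at borders). Voxels
above `median + 2.2 × mad` form a mask; connected components smaller than 50
voxels are discarded as residual noise. The centerline is the minimum-cost
path between the user seeds on the 26-connected masked voxel graph with edge
cost `step length / mean intensity`, then each path point is moved to the
intensity centroid in its normal plane, smoothed, and resampled every
0.2 µm. The per-point radius is the half-width at half-maximum of the
background-subtracted intensity profile along the two in-plane
perpendiculars (the out-of-plane profile is unusable at a 1 µm z-step under
a 0.9 µm axial PSF).

Every 3-D point projects onto the backbone as `(arc, lateral)`: the
cumulative arc length of the perpendicular foot on the nearest segment and
the perpendicular distance. Ties between segments resolve to the earlier
segment — a measure-zero case needing a deterministic rule.

## Session registration

Sessions are aligned by translation only (head-plate-fixed imaging; the
field is relocated on the same structures, so rotation is negligible). The
integer shift maximizes the **regularized phase correlation** of the
noise-suppressed stacks; plain cross-correlation is ill-conditioned here
because a dendrite is line-like and slides along itself almost freely,
whereas spectral whitening yields a sharp peak. Sub-voxel refinement fits a
parabola per axis (bounded to ±0.5 voxel). Confidence combines the Pearson
correlation of the aligned overlap (floor 0.2) with the peak's z-score over
the lag field (floor 8): a pure-noise pair can reach overlap correlations
near the floor purely by maximizing over thousands of lags, but its peak
never stands out of the lag distribution. Low-confidence registrations warn
and the pipeline continues.

## Spine detection, attachment and inclusion

Candidates are local maxima of the smoothed stack that lie outside the
backbone tube (lateral > radius + 0.15 µm), within 3 µm of it, and above
`background + 0.25 × (robust max − background)`. Duplicates within one voxel
merge; each candidate is then refined to the sub-voxel intensity centroid of
its neighborhood with a weight floor above the noise — without this, the
1 µm z-pitch dominates the localization error. Manual annotations are never
filtered at this stage and pass through verbatim.

Each endpoint connects to the backbone along the **brightest linear path**:
among 26-connected voxel paths from the endpoint to any tube voxel within
the search radius, the one maximizing the minimum intensity (bottleneck
criterion — scale-invariant and robust to path length, unlike max-sum), with
ties broken by shorter physical length and then lexicographic voxel order.
It is computed by bisection on the intensity threshold with connectivity
checks, followed by Dijkstra on the admissible voxels with physical step
lengths, so 1 µm z-steps cost their true distance. In the pipeline the
search runs on the noise-suppressed copy; shot noise otherwise opens sparse
bright corridors that inflate the geodesic. The protrusion length — the
geodesic from the endpoint to the tube surface along this path — is clamped
from below by `lateral − radius`, a bound the true geodesic can never
violate.

Inclusion implements the two filters exactly: protrusion **strictly
greater** than 0.72 µm (4 lateral pixels at 0.18 µm), and axis elevation at
most 45° above the imaging plane. The 45° default quantifies "primarily
parallel to the imaging plane": with a z-pitch more than five times the
lateral pitch, steeper spines cannot be measured reliably; the threshold is
configurable. Excluded marks are kept with `included = FALSE`, and the
filter is idempotent and monotone in the threshold.

## Cross-session matching and dynamics

Corresponding spines are identified by arc distance. For each consecutive
session pair the matching is the maximum-cardinality, minimum-total-distance
assignment among pairs within the tolerance (default 2 µm). Because arc
positions are scalar, an optimal assignment is non-crossing, and a dynamic
program on the sorted positions finds it exactly — deterministic and
order-independent, unlike greedy nearest-neighbour. Manual correspondence
overrides force individual links; duplicate links are rejected. The
**matching coordinate is the endpoint's perpendicular-foot arc** in the
reference frame: it depends only on the (accurately localized) endpoint,
whereas the attachment-path entry point can wander along the shaft by a few
µm on noisy renders. Lost-then-reappeared spines start a new track by
default (recurrence is a scene option, off by default).

Ratios follow the standard definitions: with N spines at the earlier
session, G gained and L lost, addition = G/N, elimination = L/N, turnover =
(G+L)/(2N) — the symmetric combination standard in the longitudinal spine
literature. Both reference modes are available: each session against the
previous one (default) or everything against baseline. With N = 0 the ratios
are reported missing rather than 0. Density is included spines per µm of
analyzed backbone.

## Intensity normalization

Three disjoint 3-D ROIs per spine: a cylinder (lateral r = 0.45 µm) around
the endpoint spanning the endpoint's z-plane ± 1; the backbone tube within
± 1 µm of arc of the attachment; and the same cylinder displaced ≥ 3 µm
radially away from the dendrite into structure-free space (falling back to
alternative directions, and failing the measurement if any overlap remains).
The normalized intensity `(spine − background)/(shaft − background)` cancels
session-wise illumination and expression drift; dividing by the same
spine's baseline value yields the reported relative series. Two choices
stabilize this estimate on noisy data: ROI means are taken on a
noise-suppressed copy (σ = 1, 1, 0.5 voxels — otherwise the ratio of noisy
means is biased upward for dim spines), and when registration shifts are
available every session's ROI is anchored at the track's *baseline* endpoint
mapped into that session's frame, so ROI content is identical across
sessions instead of following per-session localization jitter. By default
the series is restricted to spines present at every session, matching the
convention that intensity analysis uses spines identifiable at all time
points; `require_all_sessions = FALSE` relaxes this to baseline-plus-query.

## Morphometry and assay formulas

Sholl profiles count exact segment–sphere crossings (quadratic roots in the
half-open parameter interval (0, 1], so a crossing at a shared node counts
once, for the earlier segment; tangency counts as no crossing — a
measure-zero case fixed by rule). Reconstruction summaries report total
length, the number of primary processes (children of the root) and the sum
of conical-frustum volumes. Spontaneous alternation uses overlapping sliding
windows of three entries, consistent with the conventional successful-triad
examples (ABC, BCA, CAB); the preference index is novel time over total
time × 100; and the 2^−ΔΔCt fold change references each sample's ΔCt to the
**mean control ΔCt** (not a single calibrator) — control samples therefore
have geometric-mean fold 1 by construction.

## Recovery performance and interpretation

The test suite measures, on simulated study conditions (problem sizes chosen
to keep the default run in minutes on one CPU: 160–192-voxel fields, 8–10
spines, 4 sessions, 10-scene noisy suites at SNR ≈ 8.6):

- clean renders: the programmed schedule, counts and density are reproduced
  exactly, and brightness multipliers to < 1%;
- noisy renders: pooled endpoint precision ≈ 0.94 and recall 1.00 (0.5 µm
  criterion); interval addition/elimination ratios recovered exactly in
  ≈ 95% of intervals with mean absolute deviation < 0.01; registration
  error ≤ 0.5 voxel per axis for shifts up to 25% of the field; brightness
  multipliers within 15%.

One caveat deserves emphasis: on a dendrite carrying ~8 spines the ratio
quantum is 1/8 = 0.125, so a single spine-session misclassification moves
one interval ratio by far more than any small tolerance. Ratio accuracy is
therefore a *population-level* statement (mean deviation, fraction exact),
not a guarantee about every interval — the same reason the original
experimental workflow double-checks every correspondence by eye.

## Known limitations

- Single unbranched segments only; branched arbors are out of scope.
- Elevation estimates inherit the z uncertainty of both the endpoint and the
  traced centerline (~10–15° at this geometry); the 45° cutoff has margin
  for in-plane spines but genuinely steep spines are unmeasurable.
- Protrusion lengths on noisy renders are biased upward (bottleneck paths
  wander before entering the tube); inclusion is protected by the
  lower-bound clamp, but reported protrusions are not calibrated lengths.
- The turnover definition assumes both sessions analyzed on the same
  tracings; fields that rotate or deform between sessions violate the
  translation-only registration model.
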