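---
title: "Quantifying intraoral waterflow during suction feeding: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intraoral waterflow during suction feeding: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xptflow)
```

## The problem

Suction-feeding fish draw food into the mouth with a rapid expansion of the
buccopharyngeal cavity. The external flow toward the gape is well understood;
what happens *inside* the mouth is not, because the cavity is optically
inaccessible. Biplanar high-speed X-ray video solves this by tracking three
kinds of radio-opaque points at 750 frames/s: bone markers implanted in the
skull, locators on the jaw tips, hyoid and operculum, and small (1.4 mm)
near-neutrally-buoyant spheres seeded around the food that act as water
tracers. `xptflow` implements the downstream analysis: from tracked 3D point
trajectories to anatomical-frame kinematics, automatic feeding-phase
segmentation, path-curvature statistics that separate water from food
transport, skeletal peak sequences, and the physics that justifies treating
the spheres as water tracers in the first place.

## Data model and units

Positions are stored in millimetres and time in seconds; velocities are
reported in cm/s, the conventional unit in this literature. A
`trajectory_set` holds named per-frame 3D series with an explicit `NA`
sentinel for missing samples — zero is a legal coordinate (the origin of the
anatomical frame), so it can never stand in for "missing". The on-disk
format is a per-track `<name>_X,<name>_Y,<name>_Z` CSV, one row per frame,
blank cells for tracking dropouts, matching the common export convention of
marker-tracking software; a comment block carries frame rate, coordinate
frame and track kinds so that files written by `write_trajectories()`
round-trip losslessly. Short interior tracking gaps may be linearly
interpolated with `fill_gaps()`; how occluded frames are handled upstream of
velocity computation is an analysis choice, so the maximum fillable gap is an
explicit argument and an audit log of filled spans is attached to the result.

## The anatomical coordinate system

All science happens in a cranium-fixed anatomical coordinate system (ACS):
origin near the esophagus entrance (caudal tip of the chewing pad,
midsagittal), x anterior, y dorsal, z right. Per frame, the neurocranium
pose is fit from its implanted markers by the Kabsch least-squares rigid
alignment (SVD with reflection rejection); the ACS is the composition of
that pose with a fixed landmark-defined basis, orthonormalised by
Gram–Schmidt so it is right-handed to machine precision. Frames with fewer
than three visible markers are marked pose-missing and excluded rather than
extrapolated — no poses are invented. The specific landmark coordinates are
user inputs (they depend on each specimen's bone model); the synthetic
worlds ship a plausible synthetic set. Marker trajectories are low-passed at
25 Hz before pose fitting (`marker_cutoff`): skull motion is far slower than
the frame rate, and raw ±0.1 mm marker noise otherwise becomes milliradian
pose jitter that enters every re-expressed trajectory as common-mode noise.

## Smoothing: why a Gaussian kernel

Every smoothing step uses a zero-phase Gaussian convolution whose −3 dB
point sits at the configured cutoff (`lowpass()`). A Gaussian was chosen
deliberately over recursive (Butterworth-type) filters: flat-passband
kernels have negative sidelobes and ring near the sharp velocity-program
knots that delimit feeding phases, corrupting the sub-cm/s flank tails the
boundary refinement fits. The Gaussian's corner response is monotone, and
its effect on a locally quadratic signal is a known constant offset
(c·sigma²), which the phase-boundary fit models exactly.

Defaults, with rationale:

* positions for velocity: 25 Hz (phase dynamics are below ~2.5 Hz; this
  keeps a 92 cm/s intake pulse within 2% of its true peak);
* segmentation-internal resmoothing: 8 Hz (boundaries gain from heavier
  smoothing than reported velocities; bias is removed by the corner model);
* curvature path: 6 Hz (curvature differentiates the path twice, so its
  noise floor grows like the 2.5th power of the bandwidth, while intraoral
  path geometry evolves below ~4 Hz).

## Phase segmentation

The sequence is segmented from the mean anteroposterior velocity of the
water tracers (per-tracer mode is also supported; the mean is the default
because it suppresses tracer-level noise). Frames between −4.5 and
+2 cm/s are treated as stagnant — the dead band is asymmetric because slow
posterior drift at the swimming speed must not trigger a phase. Runs
shorter than 0.02 s (15 frames) are merged into their neighbours; the
shortest real phase is an order of magnitude longer. The first posterior run
reaching half the global posterior maximum is the intake (backflows have "a
similar but slower" profile); slow posterior motion before it is the
approach; later anterior runs are reverse flows (rf) and posterior runs
backflows (bf).

Raw threshold crossings are biased outward by O(sqrt(threshold)) because a
smooth pulse leaves its baseline with zero slope. Each run edge is therefore
refined to the underlying velocity knot by fitting the closed-form
Gaussian-smoothed flank model

m(tau) = (tau² + sigma²) Phi(tau/sigma) + tau sigma phi(tau/sigma),

with a quartic correction term whose ratio is fixed by the run's own
apparent duration (matching a cosine-like pulse to sixth order), and a
mirrored term for an opposite-sign pulse sharing the knot (rf/bf
junctions). The knot time is grid-searched at frame resolution with
parabolic sub-frame interpolation. The baseline is taken as zero — water at
rest in the anatomical frame — except ahead of the intake, where the
approach plateau (which may itself exceed the dead band) is estimated from
the data and split off the intake run. On 20 seeded synthetic sequences per
species this recovers over 95% of phase boundaries within ±2 frames,
intake durations within 9 ms and rf/bf periodicities within 0.2%.

## Path-line geometry and statistics

Curvature from three consecutive frames is the Menger (circumcircle)
curvature in the dorsoventral (x, z) plane — the unique three-point
curvature, dimensionally 1/length — computed on the 6 Hz-smoothed path and
summarised as the maximum per 10% interval of each tracer's own
anteroposterior trajectory (10 bins by default; the interval width is an
analysis choice). Water-vs-food comparisons pool all interval maxima into
one Kruskal–Wallis rank-sum test by default; a per-interval mode is provided
because the original comparison could be read either way. Side preservation
across the intake and the ingestion-timing effect are Kendall tau-b
correlations (tau-b because quantized coordinates produce ties). Per-phase
travel distances sum frame-to-frame 3D steps, with per-axis components
normalised to 100%. Flow-pattern labels are explicit heuristics: a
sustained (≥0.02 s) anterior velocity segment after mouth entry marks the
central-jet return flow; shedding more than half of the peak lateral
excursion while moving posteriorly marks posteromedial (crossflow-like)
motion; everything else is plain diverging posterior flow. The thresholds
are exposed as arguments and are not taken from any measurement.

## Skeletal kinematics

Gape is the 3D distance between the jaw-tip locators (projection onto a
plane would need an arbitrary plane choice); hyoid depression is the ventral
(−y) excursion and opercula abduction the lateral (|z|) excursion, both
referenced to the mean over a rest window, by default the approach phase —
no rest posture is defined otherwise. Peaks are global maxima within a phase
window without sub-frame interpolation (±1 frame = ±1.3 ms, far below the
phase timescales). The ordered peaks are labelled `intake_like`
(gape → hyoid → opercula, the anterior-to-posterior expansion wave),
`rf_like` (inverted) or `other`.

## Tracer physics

Stokes' law gives the tracer density from a drop test:
rho = 18 mu v_settle / (g d²) + rho_water, with v_settle positive when
sinking (the drop-test convention reports rising velocities as positive, so
the interface negates). Terminal velocity is the tail slope of the filmed
(50 frames/s) vertical trajectory, with a drift check that rejects records
still in the transient.

Tracer fidelity under suction is assessed with a reduced-order model rather
than a full moving-mesh CFD: the inflow is the exact potential flow through
a circular aperture of radius R in a plane wall (oblate-spheroidal
solution — far field a half-space sink, zero normal flow on the wall, smooth
through the aperture), developing into plug flow over one radius of cavity
depth; the aperture speed follows the quasi-steady Bernoulli closure
u = sqrt(2|p|/rho), about 2 m/s at the 2 kPa suction peak — the measured
intake peaks (~1 m/s) are the same order. The default geometry and forcing
are a 40 mm × 10 mm cavity and a sinusoidal pressure reaching 2 kPa at
20 ms then held, simulated for 100 ms at 0.125 ms steps. The particle obeys
a reduced Maxey–Riley balance: Stokes drag, buoyant weight, added mass and
the fluid pressure-gradient force; Basset history and Faxén corrections are
neglected (the main fidelity caveat), and a Schiller–Naumann finite-Reynolds
drag factor is available behind `drag_correction` (slip Reynolds numbers
reach O(100) at peak flow; both settings keep the heaviest tracer within the
1 mm gravity-deviation bound). Integration is fourth-order Runge–Kutta; the
Bernoulli ramp opens like sqrt(t) with an integrable infinite acceleration,
so the first step is taken analytically (displacement (2/3) h u(p, h)) and
the early ramp is substepped — without this, a spurious slip seeded at onset
persists for a full Stokes relaxation time (~0.16 s) and masquerades as
tracer infidelity. A neutrally buoyant particle then tracks the fluid
pathline to under 10 nm over the event, and halving the time step moves the
endpoint by well under 1% of the path length. The two default release
points, 5 mm ahead of the aperture on-axis and 5 mm off-axis, are
configurable; no coordinates are published for the original pair.

## The synthetic-data generator

`generate_feeding_sequence()` builds worlds with known ground truth: an
anteroposterior velocity program assembled from raised-cosine pulses
(smooth, band-limited, knot-aligned) — approach plateau at the swimming
speed, intake pulse, stasis, and contiguous rf/bf pulse pairs whose
transitions recur at the species period; water tracers with lateral
S-curves up to the cavity half-width; a food tracer staying dorsal and
midsagittal; locators following the canonical kinematic waves; four
neurocranium markers on a cranium advancing along its own anterior axis;
and isotropic ±0.1 mm noise on every world-frame sample. The species
presets hold the reported means (carp: approach 3.9 cm/s, intake peak
92.1 cm/s over 0.26 s, handling peak 32.9 cm/s, rf/bf period 0.58 s;
tilapia: 3.3, 97.8, 0.27, 24.7, 0.40), about 15 water tracers, and a
65 × 50 × 40 mm cavity scale. Pulse amplitudes are jittered between trials
with a 15% CV — the full printed between-trial SDs would make occasional
trials degenerate — while durations and periods are held at the preset
values, which is what the recovery analyses compare against. A tracer's
final lateral amplitude grows with its initial lateral offset (streamline
ordering: intake streamlines do not cross), reproducing the strong
side-preservation correlation observed in carp. Optional subpopulations
carry the anterior-return and posteromedial signatures.

What the generator does *not* emulate: marker-detection failure modes beyond
missing frames, cranium rotation during the strike (pure translation is
generated; rotation handling is exercised by unit tests instead), food that
decouples from the flow (the synthetic food follows a scaled version of the
water program, so the water-vs-food travel-distance contrast is much weaker
than in vivo even though the curvature contrast is strong), and any
turbulence or cavity-wall interaction. Passing the recovery suite therefore
demonstrates the estimators are correct and noise-robust under the stated
motion model — not that the biological conclusions would replicate on new
animals.

## Problem sizes and runtimes

The test suite and analysis scripts use desk-scale problems: 20 seeded
sequences per species (each ~4.7 s at 750 frames/s with 15 tracers) for the
segmentation recovery study, 7 + 6 trials for the cohort statistics, 50
seeded drop tests, and the 800-step default suction simulation per release
point and density. Everything runs in a few minutes on one CPU.

## Known limitations

* The phase-boundary refinement assumes pulses with locally quadratic,
  cosine-like flanks; pathological waveforms fall back to the raw dead-band
  crossing (within ~2 frames of the run edge).
* The reduced-order suction model has a rigid cavity and no gill-slit
  outflow, head expansion or two-way coupling; it supports the tracer
  fidelity claims, not intraoral flow-pattern prediction.
* Landmark coordinates for real specimens must be supplied by the user;
  the shipped values are synthetic.
* With fewer than ~10 water tracers the Kendall and Kruskal–Wallis tests
  lose power; the generator default of 15 matches the recordings.
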