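---
title: "Analysing spontaneous calcium activity in the developing cochlea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing spontaneous calcium activity in the developing cochlea}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Before hearing onset, the cochlear sensory epithelium generates patterned
spontaneous activity: inner hair cells (IHCs) fire calcium transients both
on their own and in coordinated groups, intercellular Ca²⁺ waves sweep
through the supporting cells of the greater epithelial ridge (GER), and
spiral ganglion (SGN) afferent terminals follow the presynaptic activity.
Two-photon GCaMP imaging of this system yields timelapse stacks in which
every one of these phenomena has to be detected, segmented, and quantified
— under breathing artifacts, lateral drift and photon noise.

`cochleaCa` implements that analysis as a reproducible pipeline, and pairs
it with a synthetic-movie generator whose hidden truth (every transient
time, wave trajectory, terminal coupling, artifact bout) is known, so that
each stage can be validated by parameter recovery rather than by eye.

## Coordinate conventions

Stacks are `(y, x, t)` arrays; pixel indices are 1-based (the natural R
convention; the trade-off against 0-based indexing is purely notational and
is confined to this one choice), time runs in seconds from recording start,
frame `k` spans `[(k-1), k) / frame_rate`, and physical distances are
pixels × pixel size (µm). Because field magnification varies between
experiments, the pixel size must always accompany the data; it is never
guessed. The IHC-row polyline (`cochlear_axis`) maps image positions to
`(s, d)`: longitudinal arc length and signed radial distance, positive
toward the modiolar side where the GER lies.

## The synthetic generator

`generate_geometry()` lays out a circular-arc row of IHCs (default 20 cells
at 9 µm spacing), a GER field of supporting cells on the modiolar side, and
1–10 terminal puncta per IHC (clipped-normal count, mean 4, SD 2).
`simulate_schedule()` draws the hidden truth:

* independent IHC transients — homogeneous Poisson, default 0.27 events/min
  per cell;
* GER waves — Poisson at 0.8/min, origin 5–20 µm modiolar of the row,
  elliptical footprint with half-axes 17 × 7 µm, expansion at 22 µm/s and
  contraction at 15 µm/s, plus a plateau chosen so the pixel-average trace
  of the rendered wave has the drawn FDHM (mean 2.24 s, SD 1.0 s): the wave
  trace crosses half-maximum when the equivalent radius passes
  `r_max / sqrt(2)`, so `t_plateau = FDHM − (1 − 1/√2)(t_exp + t_con)`;
* coordinated events — a fraction `p_reach` (default 0.5) of waves recruits
  a contiguous cohort (clipped normal, mean 7, range 3–20) with per-cell
  delays at the lateral spread speed 61 µm/s, amplitudes 1.9× the
  independent ones, and interior cells skipped with probability 0.15
  (skipped cells are guaranteed a transient elsewhere: they are quiet, not
  silent);
* terminal release — Bernoulli coupling to each parent transient, 0.3 for
  single-cell and 0.8 for coordinated activity, modulated by side
  (pillar 1.0, modiolar 0.5, middle 0.75) in both probability and
  amplitude;
* breathing bouts (multiplicative whole-frame dimming, 30–60 % deep,
  0.2–0.8 s long) and a slow sinusoidal drift path.

`render_movie()` turns a schedule into photon counts: double-exponential
indicator kernels (τ_rise 50 ms; the decay is solved numerically so a
single rendered transient has FDHM exactly 1.5 s: the kernel is
parameterised by the observable, not by the kinetics), elliptical wave
plateaus with a Gaussian edge, drift, dimming, and Poisson shot noise last.
The `express` argument selects which cell classes carry the indicator,
mirroring the mouse lines of the real experiments: waves are analysed on a
supporting-cell + hair-cell movie, terminals on an afferent-only movie
rendered at 0.5 µm/px (boutons 2–4 µm apart are unresolvable at the 1 µm/px
used for the cellular field). Everything is a pure function of
`(config, seed)`; `render_traces()` is the cheap trace-level sibling used
for statistics that do not need pixels.

One deliberate simplification: with these defaults the synthetic per-cell
total transient rate is ≈ 0.4/min, below the in vivo population mean —
the printed per-cell rate, wave rate and cohort size cannot all hold
simultaneously in a 20-cell field. The generator reproduces the structure
of the data (kinetics, geometry, coupling, artifacts), not every population
marginal at once; cohort size and wave extent are likewise independent
knobs even though in vivo they co-vary. Shot noise, rigid drift and
whole-frame dimming do not exhaust real-data pathologies (non-rigid tissue
motion, focus ramps, bleaching), so passing recovery tests here bounds
algorithmic error, not instrumental error.

## Preprocessing

Frame QC runs on the raw recording: the pixel-average trace over the
central 80 % of the field is detrended with a 5-s rolling median, and
excursions (either sign) with prominence above 4 robust SDs are flagged as
breathing/out-of-focus artifacts when their width at half prominence —
corrected in quadrature for any prior smoothing — is below 1 s. Breathing
is abrupt; calcium signals last ≥ 1.5 s, which is what makes the width
criterion discriminative. The robust scale is the larger of the MAD of the
first-differenced trace and the MAD of the detrended trace (the former
alone collapses on temporally smoothed data). Template search (normalised
cross-correlation against user snippets) and manual interval lists merge
into the same report. Flagged frames are substituted with the last in-focus
frame (a leading interval takes the first in-focus frame after it), *then*
the stack is smoothed with the 3D Gaussian (σ = 2 px in t, y, x — σ
semantics, mirror-padded, mean-preserving); substituting first keeps each
bout from leaking into its neighbours through the temporal filter.
Lateral drift is then removed by per-frame phase correlation against the
frame average with parabolic subpixel refinement (a rigid replacement for
piecewise non-rigid registration — sufficient for the drift model here;
externally computed shift tables are accepted), and the output is rescaled
to the input's global mean.

## Traces and transients

ROI masks are eroded label-by-label (disc, default radius 2 px, the
midpoint of the 1–3 px range) so adjacent cells cannot bleed into each
other; traces are ROI pixel averages with samples in removed intervals
linearly interpolated and flagged; dF/F₀ uses F₀ = 10th percentile of the
raw trace per recording (robust to active periods; median selectable) —
per recording rather than per stitched series, since baselines drift
between sessions. Detrending subtracts a 30-s centred rolling median.

Detection finds peaks by topographic prominence on a lightly smoothed copy
(Gaussian σ = 0.2 s, matched to the indicator rise), deduplicates ripples
with a 0.5-s separation window, then applies the inclusion rules:
amplitude > 2 × SD of the trace, FDHM > 200 ms, and an amplitude floor
calibrated so that noise alone produces at most 0.02 false events/min
(Gaussian quantile for white noise; Rice upcrossing level for smoothed
noise). Amplitude is the median of the three raw samples at the refined
peak — a bare maximum over noisy samples is biased high, and that bias
propagates into the half-maximum level and shortens every measured FDHM by
~20 %. Widths are measured on the smoothed trace (noise dips cannot
truncate the crossings) at half the larger of the raw and smoothed peak
heights, and the smoothing kernel's own width is removed in quadrature so
sub-sample spikes are still rejected by the 200-ms rule.

Grouping links transients whose peaks fall within 2 s — chained
(single-linkage), the only reading under which one event can span a cohort
activating in sequence; complete linkage is available as an option. Linked
clusters are split wherever more than 4 consecutive cells (counted in
positions along the axis, not µm) do not participate. Classes: single
(1 cell), pair (2), multiple (≥ 3). Skipped cells are inside the cohort
span, quiet during the event (no transient, or amplitude below 0.25 of the
cohort median — "substantially reduced" is not quantified in the source
method, so the fraction is a configurable default), yet active elsewhere.
Frequencies divide counts by the stitched observation time of each cell,
requiring at least 5 min. Correlation analysis computes Pearson r over
simultaneously recorded samples (pairs under 5 min stay NA — never imputed
as zero), averages through Fisher's z, and fits r(d) = r₀·exp(−d/d₀) to
the distance-binned curve.

## Waves

Segmentation subtracts each (2×-binned) pixel's rolling-median baseline
(30-s window — long against a 2–5-s wave, short against the slow
intensity ripple that residual drift leaves at cell edges, which a static
percentile baseline would turn into minutes-long suprathreshold foam),
restricts to a region mask — in the pipeline, the modiolar side of the
axis with the dilated hair-cell somata excluded, an automated stand-in for
the manual curation of fields in which hair cells carry their own signal —
and zeroes a 3-px border (rigid drift correction replicates edge rows, and
that ripple must not segment as activity). Voronoi–Otsu labelling then seeds nearest-seed territories from
local maxima of a strongly smoothed copy (maxima over a
ceil(spot_sigma)-radius box; 26-neighbour maxima fragment a single wave
into dozens of seeds) and takes 3D 26-connected components within each
territory of the Otsu-thresholded, lightly smoothed volume. The automatic
threshold is never allowed below 6 robust SDs of the dF distribution, so a
waveless recording yields nothing. Components below 10 voxels or confined
within 15 µm in both spatial extents are discarded — one cell diameter
plus the smoothing spread; transients in single isolated cells are not
waves.

Quantification reports per-frame areas, the maximal-expansion footprint
mapped into `(s, d)` (extents as pixel spans, centroid distance as |d|),
FDHM of the pixel-average dF trace over that footprint (undefined when the
wave touches the first or last frame — a truncated duration cannot be
measured; such waves still count toward frequency), and expansion /
contraction speeds as the slope of the equivalent radius √(area/π) against
time, fitted over the 10–95 % band of each branch so neither plateau
frames nor smoothing tails dilute the slope. The equivalent-radius
estimator is the single largest interpretation risk (the source method
never states its estimator); a boundary-displacement alternative sits
behind `speed_estimator = "boundary"`. Manually drawn 2D outlines can be
appended and contribute to counts and extents but never kinetics.
Kymographs sample mean intensity over ±3 px transects at 1-µm arc steps;
the propagation speed of an event box is the distance/time ratio from the
earliest suprathreshold sample to the farthest one, counting only expansion
beyond the footprint already present at onset (so a stationary blob reads
0, and an event visible in a single frame — e.g. obscured by breathing —
is undefined). Waves whose centroid lies within 35 µm of the row are
matched to IHC events overlapping their span (+2 s lag, the linkage
window); ambiguous multi-matches take the nearest in time and are flagged.

## Terminals

Puncta are segmented from the average of the raw recording (averaging
already suppresses shot noise, and the 3D filter would smear 1-µm puncta
into the background): grayscale white top-hat (disc radius 10–20 px;
implemented in-package since the installed image toolkits only provide
binary morphology) followed by 2D Voronoi–Otsu labelling. Terminals are
assigned to the nearest IHC when it beats the runner-up by more than 3 µm;
otherwise the two nearest IHCs compete by trace correlation (ties fall to
the lower index and are flagged). Sides follow the sign of `d`: beyond
±2 µm modiolar or pillar, otherwise middle; middle terminals count in
totals but never in side contrasts. Per-IHC activity averages the member
traces and merges peaks across terminals within 1 s (chained). Recruitment
counts a terminal active in an event when it has a transient within the
event span ±1 s, summarised per IHC and event class, together with the
fraction of events recruiting the entire visible pool. The pillar-modiolar
contrast is a paired Wilcoxon signed-rank over IHCs possessing both sides
(no p-value below 6 pairs).

Crowding is a real limitation: at realistic punctum spacing roughly half
of the underlying boutons merge into shared hotspots even at 0.5 µm/px,
exactly as overlapping boutons do under the microscope. Assignment
accuracy depends on observation time, because only the sparse independent
transients discriminate between neighbouring, strongly co-active IHCs: it
is ≈ 0.88 at 10 min and ≥ 0.95 at 30 min of recording (the acceptance
condition, matching stitched fields in practice).

## Numerical choices and degenerate inputs

Intervals are half-open everywhere; interval unions merge overlaps; an
all-flagged recording is an error ("no in-focus frames"). |r| = 1 is
clamped inside the Fisher transform's domain. Otsu runs on a 256-bin
histogram of the rescaled distribution. Erosion that deletes every ROI is
an error; single vanished labels are dropped and logged. The noise-free QC
path replaces a zero robust SD with machine epsilon so that any excursion
on a clean trace is significant. Wave speed fits need at least two frames
per branch, otherwise the speed is NA and logged. All RNG flows through
per-call seeds with save/restore of the global state; identical
`(config, seed)` reproduce movies, schedules and result tables
byte-for-byte.

## Problem sizes used in validation

The test-suite studies run at deliberately desk-friendly sizes chosen once:
frequency recovery at 20 cells × 20 min × 5 seeds per rate; detection
calibration on 100 × 10-min noise traces; artifact QC on 20 one-minute
movies; event-grouping oracle equivalence on 1000 random instances (≤ 12
cells, ≤ 30 transients); terminal assignment on ≥ 500 terminals from
30-min recordings; the determinism check on a 90-s dual-movie pipeline.
The acceptance script simulates one 5-min field end-to-end plus three
20-min trace-level cohorts.
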