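# cochleaCa

Analysis of spontaneous calcium activity in the pre-hearing cochlea from
in vivo two-photon GCaMP imaging — and a ground-truthed simulator that
makes every stage of the analysis testable.

## What it is for

Before hearing onset, the cochlear sensory epithelium produces patterned
spontaneous activity: inner hair cells (IHCs) fire Ca²⁺ transients both
independently and in coordinated multi-cell events, supporting cells of
the greater epithelial ridge (GER) generate propagating intercellular
Ca²⁺ waves, and spiral ganglion (SGN) afferent terminals are recruited by
the presynaptic activity. `cochleaCa` takes timelapse stacks of this
system through a full quantitative pipeline:

* **Preprocessing** — breathing/out-of-focus frame detection on the
  pixel-average trace (prominence, template and manual routes), last
  in-focus frame substitution, 3D Gaussian smoothing (σ = 2 px),
  rigid drift correction by phase correlation with subpixel refinement.
* **Traces** — label-wise ROI erosion (1–3 px), pixel-average traces,
  linear interpolation over removed frames, dF/F₀ against a low-percentile
  baseline, rolling-median detrending, stitching of repeated recordings
  through persistent cell identities.
* **Transients and events** — prominence-based peak detection with the
  inclusion rules amplitude > 2 × SD of the trace and FDHM > 200 ms plus a
  noise-calibrated amplitude floor; chained 2-s linkage into events, split
  at positional gaps of more than 4 silent cells; single / pair / multiple
  classes; skipped-cell identification; per-cell frequencies
  (events/min, ≥ 5 min observation); Pearson correlation matrices with
  Fisher-z averaging,

  `z = artanh(r)`, `avg(r) = tanh(avg z)`, `SD(r) = tanh(SD z)`,

  and an exponential fit `r(d) = r0·exp(−d/d0)` of correlation against
  inter-cell distance.
* **Waves** — 3D Voronoi–Otsu segmentation of the binned ΔF volume into
  spatiotemporal wave objects; per-wave maximal area, longitudinal/radial
  extents and centroid distance in the cochlear-axis frame `(s, d)`, FDHM
  of the footprint trace, expansion/contraction speeds from the equivalent
  radius √(area/π); kymographs along the IHC row and the GER with
  ridge-slope propagation speeds; matching of waves to IHC events within a
  35-µm origin window.
* **Terminals** — grayscale white top-hat + Voronoi–Otsu punctum
  segmentation, proximity-then-correlation assignment of terminals to
  IHCs, modiolar/pillar/middle side labels from the signed radial
  coordinate, per-IHC averaged traces with 1-s peak merging, recruitment
  fractions during single vs multiple IHC events, and paired
  pillar-vs-modiolar Wilcoxon statistics.
* **Synthetic data** — `generate_geometry()`, `simulate_schedule()`,
  `render_movie()` / `render_traces()` produce GCaMP-like recordings with
  a complete JSON ground-truth sidecar (transient times, wave kinematics,
  terminal couplings, artifact frames), bit-reproducible from
  `(config, seed)`.

## A worked example

```r
library(cochleaCa)

g     <- generate_geometry(n_ihc = 12, seed = 1)
sched <- simulate_schedule(g, synth_defaults(), duration_s = 600, seed = 2)
sched
#> activity_schedule: 600 s, 61 IHC transients (5 coordinated events),
#>   11 waves, 101 terminal transients, 5 artifact bouts

rt <- render_traces(g, sched, seed = 3)          # dF/F0 traces + noise
ts <- as_trace_set(rt$ihc, rt$frame_rate, "demo")
tr <- detect_transients(detrend_traces(ts, 30))
head(tr, 3)
#>   identity recording_id peak_time amplitude prominence     fdhm
#> 1   IHC_06         demo       6.8 0.1457460  0.1584233 1.093758
#> 2   IHC_04         demo      45.2 0.2572159  0.2660231 1.206797
#> 3   IHC_03         demo      67.0 0.4873699  0.4523316 1.207774

grouped <- group_events(tr, setNames(g$ihc$order, g$ihc$identity))
table(grouped$events$class)
#> multiple     pair   single
#>        6        1       30

mean(compute_frequency(tr, 600)$freq_per_min)
#> [1] 0.52

event_amplitude_by_class(grouped)
#>      class  n mean_amplitude sd_amplitude
#> 1   single 30      0.2397727   0.08644938
#> 2     pair  2      0.1830202   0.01350349
#> 3 multiple 31      0.3874519   0.13873622
```

The detected frequency (0.52 events/min per cell) counts both independent
transients and coordinated-event participations; amplitudes during
multi-cell events run ~1.6–1.9× the single-cell ones, as scheduled by the
generator. `run_pipeline(config, seed, outdir)` executes the whole chain —
two sibling movies of one activity schedule (a supporting-cell/hair-cell
recording for IHC and wave analysis, an afferent-only recording for
terminals), preprocessing, every analysis stage — and writes one CSV/JSON
table per result. A thin command-line wrapper lives at
`inst/scripts/cochleaca` (`simulate`, `preprocess`, `trace`, `run`).

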