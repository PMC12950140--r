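# spinedyn

Longitudinal dendritic-spine dynamics from in-vivo two-photon image stacks.

Chronic two-photon imaging follows the same dendritic segments of
fluorescently labeled cortical neurons across days. The biology of interest
is spine remodeling: which spines appear, which disappear, and how the
brightness of persistent spines changes relative to baseline. `spinedyn`
implements the full analysis chain for such experiments on single unbranched
apical dendrite segments, together with a ground-truthed simulator that makes
every stage testable without any imaging data:

- **Simulation** — `make_scene()` programs a multi-session experiment (spine
  positions, per-interval gains/losses, per-session brightness multipliers)
  and `render_session()` renders it into a realistic 3-D stack (anisotropic
  voxels, default 0.18 × 0.18 × 1 µm; partial-volume rasterization; Gaussian
  PSF; Poisson shot noise and Gaussian read noise).
- **Tracing** — `trace_backbone()` extracts the dendritic centerline between
  seed points as a minimum-cost bright path on the voxel graph, recenters it
  on the local intensity centroid, and estimates a per-point radius from the
  in-plane half-width at half-maximum. `arc_position()` gives every point an
  arc-length coordinate along the backbone.
- **Registration** — `register_sessions()` recovers the rigid translation
  between sessions by regularized phase correlation with sub-voxel
  refinement.
- **Spine detection** — `detect_endpoints()` finds spine endpoints as local
  maxima outside the backbone tube (manual annotations always pass through);
  `brightest_path()` connects each endpoint to the backbone along the
  brightest linear path (max–min bottleneck criterion over 26-connected voxel
  paths); `apply_inclusion_filters()` keeps spines protruding more than
  0.72 µm (4 lateral pixels) from the tube surface and oriented primarily
  parallel to the imaging plane.
- **Longitudinal statistics** — `match_spines()` identifies corresponding
  spines across sessions by arc-length position (maximum-cardinality,
  minimum-total-distance assignment with a hard tolerance);
  `dynamics_summary()` computes per-session density and per-interval
  addition, elimination and turnover ratios; `intensity_series()` measures
  spine / shaft / background ROI intensities and expresses each spine's
  normalized brightness relative to baseline.
- **Morphometry and assay formulas** — `sholl_profile()` (intersections with
  concentric spheres), `morphology_summary()` (total length, primary
  processes, frustum volume), `preference_index()` (novel-object
  recognition), `spontaneous_alternation()` (Y-maze triads), and
  `fold_change_ddct()` (2^−ΔΔCt qPCR normalization).

## The statistics at the core

For a session pair (t₀, t₁) with N spines present at t₀, G gained and L lost:

    addition    = G / N
    elimination = L / N
    turnover    = (G + L) / (2 N)

Spine density is the count of included spines per µm of analyzed backbone.
Normalized spine intensity is

    (spine − background) / (shaft − background)

measured in three disjoint 3-D ROIs, then divided by the same spine's
baseline value so that illumination and expression drift cancel.

## Worked example

```r
library(spinedyn)

# a 4-session experiment: 10 spines at baseline, then per interval
# lose 2/1/1 and gain 1/1/1, rendered without noise
rep <- run_demo(seed = 1, noise = clean_noise_model())
rep$dynamics$ratios[, c("session", "n_prev", "gained", "lost",
                        "addition_ratio", "elimination_ratio", "turnover_ratio")]
#> # A tibble: 3 × 7
#>   session n_prev gained  lost addition_ratio elimination_ratio turnover_ratio
#>   <chr>    <int>  <int> <int>          <dbl>             <dbl>          <dbl>
#> 1 d3          10      1     2          0.1               0.2            0.15
#> 2 d7           9      1     1          0.111             0.111          0.111
#> 3 d14          9      1     1          0.111             0.111          0.111
```

The pipeline traced the dendrite, detected and filtered every spine, matched
them across the four sessions, and reproduced the programmed schedule
exactly: at d3, 1 of 10 baseline spines was added (10%), 2 eliminated (20%),
turnover (1+2)/(2·10) = 15%. With the default noisy render
(`noise_model()`: SNR ≈ 8.6) the same numbers are recovered to within a few
percent. `autoplot(rep$dynamics)` draws the density and ratio panels;
`save_report(rep, "out/")` writes the tables, the backbone SWC and a
reproducibility manifest.

A thin command-line wrapper ships in `inst/cli/spinedyn.R`
(`demo`, `simulate`, `metrics` subcommands).

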