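# fibmap — panoramic phase mapping of atrial fibrillation sources

Atrial fibrillation (AF) looks spatiotemporally disorganized on the surface
ECG, yet it can be driven by a small number of localized sources: electrical
**rotors** (re-entrant spiral waves pivoting about a phase singularity) and
**repetitive focal beats** (sites radiating centrifugal activation). Finding
those sources in panoramic basket-catheter recordings is a signal-processing
and computational-geometry problem: detect local activation on 64 unipolar
electrograms, build per-cycle isochronal maps, compute instantaneous phase
with the Hilbert transform, locate and track phase singularities, and measure
how far each source's pivot migrates.

`fibmap` implements that whole chain for R, together with an excitable-medium
simulator that generates spiral-wave, focal and plane-wave episodes with known
ground truth, so every stage can be validated against a known answer. It is
aimed at cardiac-electrophysiology methodologists and anyone studying
spatiotemporal pattern analysis on sparse electrode grids.

## The quantities at the core

* **Phase.** Each electrogram `x(t)` is detrended and transformed to its
  analytic signal `x(t) + i H[x](t)`; the instantaneous phase is the angle of
  that signal, wrapped to (−π, π]. Phase fields are interpolated on the unit
  circle (cos/sin separately), never as raw angles.
* **Phase singularity (topological charge).** For each elementary 2×2
  plaquette of the phase raster the four wrapped phase differences around the
  loop are summed; `∮ ∇φ · dl = ±2π` marks a singularity of charge ±1 — the
  rotor pivot. A brute-force winding-number oracle evaluates the same integral
  on arbitrary loops and is used to verify the detector exhaustively.
* **Activation and restitution.** Local activation is the sharp negative
  unipolar deflection; intervals shorter than the recovery time predicted by
  an APD-restitution curve (floored at the minimum atrial repolarization time,
  100–110 ms) are physiologically impossible and are discarded by a forward
  scan.
* **Migration locus.** Tracked singularity positions, cleaned of isolated
  outliers, are joined by a chord-length parameterized piecewise-cubic curve
  with continuous first and second derivatives; the locus area is the convex
  hull area of that curve in cm².
* **Wavelength.** `wavelength = repolarization × CV`; with 100 ms and 40 cm/s
  this is 40 mm, the minimum re-entrant path an electrode array must resolve.

## Worked example

Simulate two seconds of a stable spiral-wave episode, sample it at a 64-pole
basket on the unwrapped 4×4 cm sheet, and run the full mapping pipeline:

```r
library(fibmap)
report <- run_pipeline(list(kind = "spiral", duration_ms = 2000, seed = 1))
print(report)
#> <run_report> spiral episode, seed 1: 1 source(s)
#> # A tibble: 1 × 9
#>   kind  chirality n_rotations n_beats  u_cm  v_cm locus_area_cm2 t_start_ms
#>   <chr>     <dbl>       <dbl>   <int> <dbl> <dbl>          <dbl>      <dbl>
#> 1 rotor         1        9.32      NA  1.99  1.74         0.0414        101

glance(report)
#> # A tibble: 1 × 7
#>   kind    seed n_sources n_rotors n_focal mean_locus_area_cm2 mean_cl_ms
#>   <chr>  <int>     <int>    <int>   <int>               <dbl>      <dbl>
#> 1 spiral     1         1        1       0              0.0414       200.
```

One source is found: a counterclockwise rotor (charge +1) near the sheet
centre that completes 9.3 rotations during the recording, with a migration
locus of 0.04 cm² (it is a deliberately stable spiral). The mean cycle length
measured from the electrograms, 200 ms, matches the simulator's true rotation
period of 201 ms. A focal configuration (`kind = "focal"`) yields exactly one
source of kind `focal` at the pacing site, and a plane-wave control
(`kind = "planewave"`) yields zero sources.

Intermediate objects are attached to the report for plotting and inspection:

```r
autoplot(attr(report, "phase_map"))        # phase field + singularities
autoplot(attr(report, "maps")[[1]])        # per-cycle isochrones
autoplot(attr(report, "tracks"))           # tip track and smoothed locus
tidy(attr(report, "tracks"))               # one row per track
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/fibmap.R` (subcommands `simulate`, `activations`, `map`,
`phase`, `track`, `run`, `report`).

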