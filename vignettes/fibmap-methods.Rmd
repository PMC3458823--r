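---
title: "Methods: phase mapping of fibrillation sources and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase mapping of fibrillation sources and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes, the
assumptions behind each stage, and what the validation against the built-in
simulator does and does not demonstrate.

## The mapping problem

Panoramic mapping of atrial fibrillation records unipolar electrograms from a
multi-spline basket catheter — here emulated as 8 splines × 8 electrodes on a
flat "unwrapped" atrial sheet, with 4–6 mm spacing along a spline and 4–10 mm
between splines. Two complementary analyses are computed from the same
recording:

1. **Isochronal analysis.** Local activation times per electrode, filtered by
   a restitution (recovery-time) rule, interpolated per cycle onto a 1 mm
   raster. Gradients of the activation-time field give propagation direction
   and conduction velocity; repeated cycles give a directionality-recurrence
   score.
2. **Phase analysis.** The Hilbert-transform phase of each electrogram,
   interpolated to the raster on the unit circle, yields an instantaneous
   phase field. Points where the loop integral of the phase gradient is ±2π
   are phase singularities — rotor pivots — and are tracked over time into
   source tracks whose migration locus is smoothed and measured.

A rotor is declared when a track sustains at least `min_rotations` (default
2) full rotations of the surrounding phase field without interruption; a
focal source when an interior raster node is a local minimum of activation
time with monotonically increasing times along all eight grid rays for about
two electrode spacings, recurring across at least `min_repeats` (default 2)
consecutive cycles.

## Coordinate conventions

All analysis happens in continuous (u, v) coordinates in cm on a flat,
non-periodic sheet; each atrium's sheet is mapped independently and the
"opened" seam is an ordinary boundary. No 3-D chamber registration is
attempted. The analysis raster (default 1 mm) is far below the electrode
pitch (4–10 mm), so raster error is negligible against the ~5–7 mm practical
resolution set by an ablation-lesion footprint. Nodes outside the electrode
convex hull are treated as unobserved.

## Signal conditioning and activation detection

* **Band-pass** is a zero-phase (forward–backward) Butterworth filter; the
  clinical band is 0.05–500 Hz at 1 kHz sampling. Because 500 Hz is exactly
  the Nyquist frequency there, only the high-pass stage runs in that
  configuration; the channel mean is always removed first so DC rejection is
  exact on finite windows.
* **Detection operator.** The package marks the electrogram's sharp negative
  (intrinsic) deflection: peaks of −V after a 40 ms moving-mean detrend. A
  `-dV/dt` slope mode is available (`operator = "slope"`). On the simulator's
  pseudo-unipolar signals — which are themselves built from −dV/dt of the
  tissue — the deflection criterion aligns with the true local upstroke to
  ~1 ms, whereas differentiating a second time introduces a systematic
  several-millisecond lag.
* **Adaptive threshold.** Fibrillatory electrograms are continuously active,
  so a plain MAD of the whole trace overestimates the noise floor. The
  default threshold is the larger of 3× the quiet-window noise level (10th
  percentile of the 21 ms rolling RMS) and 0.5× the robust peak height (98th
  percentile of the positive detection signal); the second term keeps smaller
  secondary lobes — repolarization far-field — below threshold. A fixed
  threshold can be supplied instead.
* **Restitution filter.** A forward scan keeps the earlier event of any pair
  closer than the recovery time and re-evaluates subsequent intervals against
  the last accepted event. Recovery is the APD read off a monotone
  interpolation of a supplied DI→APD table, floored at `min_apd_ms`
  (default 100 ms, the minimum human atrial repolarization time); with no
  table the rule is the flat floor. The scan is idempotent and only ever
  removes events.

## Cycle segmentation

Windows are anchored on the most regular channel (lowest coefficient of
variation of its intervals) with length equal to its median cycle length, and
their phase is shifted to the diastolic gap — the least-active bin of all
activation times folded modulo the cycle length (centre of the longest run of
minimal bins). When conduction is slow enough that a wavefront's transit
approaches the cycle length there is no globally quiet phase; focal-source
detection therefore additionally scans six evenly spaced window phases and
keeps the phase whose interior-monotone origins recur most often. The scan is
deterministic and its result is phase-stable for genuinely focal patterns,
while rotors and plane waves produce no interior monotone origin at any
phase.

## Phase analysis choices

* **Detrending before the Hilbert transform** subtracts a moving mean over
  one dominant cycle length (per-channel spectral peak in 2.5–20 Hz). Unipolar
  signals carry baseline wander at the 0.05 Hz high-pass corner; the moving
  mean is the minimal stabilization and can be switched off
  (`detrend = "none"`), in which case the transform is applied to the raw
  signal.
* **Interpolation on the circle.** cos φ and sin φ are interpolated
  separately (barycentric linear on a Delaunay triangulation of the
  electrodes) and recombined with atan2, so values near the ±π wrap never
  average through zero.
* **Plaquette charge test.** Discrete wrapped loop sums equal exact multiples
  of 2π only in ideal fields, so a plaquette is flagged when |sum| > π and
  its charge is the rounded sum/2π. Plaquettes whose 4×4 node neighbourhood
  touches missing data or the hull edge are flagged `boundary = TRUE` and are
  excluded from tracking by default: edge plaquettes are where interpolation
  artifacts concentrate.
* **Tracking** is greedy nearest-neighbour per time slab (default sampling
  every 30 ms, configurable within 25–45 ms), same chirality only, with
  `max_jump_cm` (1 cm, one electrode spacing) and `max_gap_ms` (90 ms, about
  half a rotation period) controlling joins and track closure. In regimes
  where clusters are separated by more than twice the jump radius greedy
  linking provably coincides with optimal assignment, which the tests check
  against a permutation oracle.
* **Outlier removal** drops samples whose leave-one-out nearest-neighbour
  distance exceeds 5× the track's median nearest-neighbour distance — the
  "isolated extreme point" rule — never more than 20% of a track.
* **Locus smoothing** is a chord-length parameterized natural cubic spline
  through the retained samples: a piecewise third-order curve whose first and
  second derivatives are continuous at every interior knot (the stated
  continuity class forces piecewise cubics). The migration-locus area is the
  convex hull area of the smoothed curve — a reproducible, rotation- and
  translation-invariant definition; kernel-density or alpha-shape outlines
  would be tunable and are deliberately not the default.
* **Rotation counting** unwraps the phase of eight probe nodes on a 0.8 cm
  ring around the track centroid over the track's time span; the rotation
  count is the mean total progression / 2π. At the default 30 ms sampling a
  200 ms rotor advances ~0.9 rad per sample, well under the π unwrap limit.

## The synthetic-data generator

The simulator is a two-variable cubic excitation/recovery (Aliev–Panfilov
form) sheet, explicit Euler, 5-point Laplacian, no-flux boundaries, stepped
in C++:

    dV/dt = ( −k V (V − a)(V − 1) − V r ) / τ + D ∇²V
    dr/dt = ( (ε₀ + μ₁ r / (V + μ₂)) (−r − k V (V − a − 1)) ) / τ

Defaults: 128×128 nodes over a 4×4 cm sheet (h = 0.31 mm), D = 3.5×10⁻⁴
cm²/ms, k = 8, a = 0.1, ε₀ = 0.05, μ₁ = 0.2, μ₂ = 0.3, τ = 7.1 ms per
dimensionless unit, dt = 0.1 ms (the diffusion stability bound h²/4D is
0.70 ms; the reaction terms are the binding constraint). These were
calibrated once so that a sustained spiral rotates with a ~200 ms period —
inside the 150–250 ms human AF cycle-length range — and so one full turn
fits the sheet. The implied conduction velocity (~10 cm/s) is below the
~40 cm/s of healthy atrium; it represents the slow conduction of remodeled
tissue and is the price of containing a whole rotor in a 4 cm domain at desk
scale. CV-related checks are therefore relative (estimate vs simulator
truth), while the 40 mm minimum-wavelength worked example uses the clinical
numbers directly.

Episodes: **spiral** (S1 plane wave broken by a cross-field reset; meander by
periodic modulation of the excitability a with amplitude `meander_level`,
usable 0–0.25 — at 0.3 the spiral extinguishes and the simulator raises an
error rather than returning a dead episode), **focal** (point pacing at a
chosen origin and cycle length; 2:1 capture is detected from a probe node and
flagged in the truth), **plane wave** (edge pacing at 450 ms so each front
clears the sheet before the next launches). The ground-truth tip path is the
intersection of the V = 0.5 isoline at consecutive frames — the standard tip
definition, computed on the fine grid, independent of the phase-based
detector it validates.

Pseudo-unipolar electrograms are a 1/r-weighted (floored at one node
spacing) sum of −dV/dt over tissue nodes, tapered by a Gaussian sensing
volume of 0.5 cm: on a 2-D sheet an untapered 1/r sum grows with distance and
every channel would see global, not local, activity; the taper restores the
near-field dominance a contact electrode has while keeping the biphasic
far-field morphology. Stimulated nodes are excluded from the sum (pacing
artifact blanking, as clinical systems do). Signals are resampled to 1 kHz
with optional additive white noise.

What the generator does **not** emulate: ventricular far-field (QRS/T
contamination), fractionated multi-component electrograms, fibrosis and
anisotropic conduction, 3-D wall thickness and epi/endo breakthrough,
contact-quality variation, and basket spline deformation. Passing the
recovery tests therefore shows the chain is correct on clean, single-source
2-D physics; it does not establish clinical sensitivity or specificity on
human recordings.

## Numerical and degenerate-input conventions

* Interpolation requires ≥3 non-collinear channels; collinear layouts raise a
  degenerate-geometry error. Nodes outside the hull are missing, and all
  field consumers mask missing data.
* Gradients are central differences with one-sided fallback at the edge of
  the defined region; directions are undefined where |∇T| falls below
  tolerance.
* Phases are wrapped to (−π, π] with −π mapped to +π; wrapped differences
  use atan2, so ±π inputs are handled consistently.
* Duplicate consecutive locus points are collapsed before spline fitting; a
  two-point locus is the straight segment, and degenerate (≤2 distinct or
  collinear) loci have zero hull area. Conservation overlap of zero-area
  loci is computed on 1 mm-buffered points and flagged.
* All stochastic stages derive child seeds from the single run seed; the PDE
  itself is deterministic, so identical configurations reproduce
  byte-identical serialized reports.

## Problem sizes used in validation

The shipped tests and the acceptance script run 1.5–2 s episodes at the
128×128 default grid, 200–500 random phase screens for the topological-charge
oracle, 1000 random event trains for the restitution oracle, and 100 random
point sets for the hull oracle. These sizes were chosen as the smallest at
which every property is exercised across several cycles of every episode
kind.

## Known limitations

* Cycle-window phase is a genuine degree of freedom when wavefront transit
  is comparable to the cycle length; the diastolic-gap alignment plus the
  focal phase scan resolve it for the patterns generated here, but heavily
  multi-wave fields may need manual windows.
* Greedy linking is order-stable but not globally optimal when sources pass
  within `max_jump_cm` of each other; crossing tracks can swap identities.
* The rotor/focal dichotomy is exclusive by construction; hybrid patterns
  (a rotor drifting past a focal site) are reported as whichever criterion
  they satisfy, possibly both.
* The minimum rotation count for rotor status (2) and the hull-based locus
  area are documented package definitions; other reasonable choices exist
  and change the reported numbers.
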