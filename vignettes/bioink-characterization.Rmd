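---
title: "Characterizing shape-shifting bioinks: models, scores and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing shape-shifting bioinks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bioinklab)
```

## The problem

Internally crosslinked alginate hydrogels (Ca²⁺ released in situ from
suspended CaCO₃ by slow acidification) gel over tens of minutes rather
than instantly. That slow kinetics gives one formulation two distinct
processing windows: before the gel point the material is a viscous
liquid that self-spreads and takes the shape of any mold; after it, the
elastic network dominates and an extruded filament retains its shape.
A bioink intended for liver-tissue models (alginate loaded with
decellularized porcine liver ECM powder) exploits exactly this duality,
and its characterization requires a consistent set of quantities:

* **gel point** — the time at which the storage modulus G′ first
  exceeds the loss modulus G″ in an oscillatory time sweep;
* **yield point** — the oscillatory stress amplitude at which G″
  overtakes G′ in an amplitude sweep on the crosslinked gel;
* **structural recovery** — the fraction of G′ regained after a
  high-strain (extrusion-like) interval;
* **shear-thinning parameters** — the consistency index K and flow
  index n of η = K·γ̇ⁿ⁻¹;
* **drop-spreading geometry** — the spreading ratio S₀ and the minimum
  layer height of a sessile drop modeled as a spherical cap;
* **shape-fidelity scores** — spreading factor S, uniformity U,
  perimeter Pe, pore Pr and printability P of printed fibers and grids;
* **extrusion pressure** — the pressure at which the wall shear stress
  in the dispensing needle reaches the yield stress;
* **embedded-cell distribution** — the area fraction occupied by
  stained nuclei on top/middle/bottom focal planes, before and after
  the gel point.

The package implements each of these as a small, tested operator, plus
seeded synthetic-data generators that stand in for the rheometer, the
camera and the confocal microscope, with ground truth returned next to
every dataset.

## Rheological analyzers

### Gel point

`detect_gel_point()` locates the first *sustained* sign change of
G′ − G″ along a time sweep. "Sustained" means the new sign must persist
for at least two consecutive samples (configurable), which rejects
single-point flips produced by instrument noise. Between the two
bracketing samples the crossing is interpolated with **log-modulus
versus linear time**, because moduli span decades while time sweeps are
sampled uniformly. If a sample has G′ exactly equal to G″, that
sample's time is reported. A sweep in which G′ never overtakes G″
returns `NA` (no gel in the window) rather than an error.

### Yield point

`detect_yield_point()` mirrors the gel-point logic for amplitude
sweeps, but interpolates **log-log** (stress amplitudes are log-spaced
by protocol). Two distinct negative outcomes are kept apart: a sweep
that starts with G′ ≤ G″ has *no solid regime at all* and raises an
error of class `no_solid_regime`; a solid sweep with no crossing in
range returns `NA` ("no yield observed in the protocol window").

### Power-law fit and recovery

`fit_power_law()` regresses log η on log γ̇ (`lm`): the slope is n − 1
and the intercept log K. This is exact on noiseless power-law data and
median-unbiased under the multiplicative log-normal noise the
generators use. `compute_recovery()` takes the median G′ over the last
half of the first and third protocol intervals (100/200/100 s) and
reports their ratio; medians over the settled halves make the estimate
insensitive to the transient at the interval switch.

Temperature is carried through the containers but never modeled: over
25-37 °C the crosslinking kinetics of these materials are unaffected,
so no correction is applied.

## Drop-spreading geometry

A dispensed volume V (µL ≡ mm³) that does not spread sits as a sphere
of diameter D_ideal = (6V/π)^(1/3); `ideal_drop_diameter(100)` =
5.759 mm for the 100 µL protocol drop. The spreading ratio is

> S₀ = D_eq / D_ideal,

with D_eq the measured equilibrium contact diameter; S₀ > 1 means the
material flowed outward. A spread drop is modeled as a **spherical
cap** of contact radius a = D_eq/2 and height h solving
V = (πh/6)(3a² + h²); contact angle is not modeled because only
diameters are measured. `cap_height()` brackets the unique positive
root on (0, D_eq/2 + D_ideal] and bisects to 10⁻¹² mm, so reconstructed
cap volumes agree with the input volume to better than 10⁻⁹ relative.
The root is the *minimum layer height* achievable by self-spreading at
that time point. The cap model is refused when D_eq < D_ideal (the
drop did not spread; the cap geometry is meaningless there).

`spreading_timecourse()` labels each observation `self_spreading`
(t < gel point) or `shape_retaining` (t ≥ gel point — the gel point is
the onset of solid behavior, so the boundary is closed on the gel
side) and warns when S₀ increases with time, since self-spreading
ability can only decay as crosslinking advances.

## Shape-fidelity scores

With D_needle the needle inner diameter (22G = 0.41 mm by default,
configurable since only the gauge is standardized), L_i the fiber
diameters measured at 10 random points on each of 5 fibers, L_real
their mean, L0x/L0y the CAD side lengths and Lbx/Lby/SDbx/SDby the
means and standard deviations of the printed sides:

| score | definition | ideal |
|---|---|---|
| spreading factor | S = 100 · L_real / D_needle | 100 % |
| uniformity | U = 1 − SD(L_i)/L_ideal, L_ideal = D_needle · S/100 | 1 |
| perimeter | Pe = (Lbx − SDbx + Lby − SDby)/(L0x + L0y) | 1 |
| pore | Pr = (Lbx · Lby)/(L0x · L0y) | 1 |
| printability | P = U · Pe · Pr | 1 |

S quantifies die-swell-like relaxation of the extruded fiber and is
deliberately a percentage; the other four are dimensionless with unity
as the optimum. The side standard deviations enter Pe (and through it
P) so that irregular sides are penalized even when their mean length is
right; Pr compares enclosed areas through the mean sides only. All
five are invariant under a common rescaling of every length, and U of
a single measurement point is defined as 1 (dispersion undefined) with
a warning. Mean and SD are sample statistics (n − 1 denominator),
matching rheometer-software convention, and the exact algebraic forms
above are fixed by the package's tests against an independently coded
transcription at 10⁻¹² relative tolerance.

### Extrusion pressure

For pressure-driven flow through a cylindrical needle of radius R and
length L the wall shear stress is τ_w = ΔP·R/(2L) regardless of the
constitutive law, so the minimum pressure that brings the wall to the
yield stress τ_y is

> ΔP = 2 L τ_y / R  (`variant = "wall_stress"`, the default).

When a power-law fit is supplied, the Rabinowitsch factor
(3n + 1)/(4n) is applied (`variant = "power_law"`); it reduces to the
Newtonian form at n = 1. Every result is labeled with the variant
used. For the 22G/12.5 mm needle and a 205 Pa yield stress the
wall-stress model gives 25 kPa; published model pressures for
comparable systems also fold in material-specific flow parameters that
are rarely reported, so pressures computed here should be read as the
wall-stress lower bound, not as a reproduction of any particular
instrument setting.

## Image quantification

All images are grayscale matrices with pixel centers at integer
coordinates, origin top-left, x right / y down, and a physical scale
(µm/px) carried in the `image_field` container (and in a JSON sidecar
on disk). Physical outputs are pixels × scale.

* **Thresholding** is Otsu by default: the reference workflow adjusts
  thresholds manually, which is not reproducible, so a deterministic
  automatic threshold stands in, with a fixed-value override
  (`segmentation_config`).
* **Connected components** use `EBImage::bwlabel` (4-connectivity).
  Every structure the generators render is 4-connected with more than
  one pixel of separation, so the choice of connectivity does not
  change any result here; pores are background components that do not
  touch the image border.
* **Drop diameter** is the equivalent-area circle diameter of the
  largest component (ties broken by size, with a warning when several
  objects are present).
* **Fiber width** is measured as twice the Euclidean distance
  transform at the fiber centerline, sampled at seeded-random rows
  away from the fiber ends; this reads the perpendicular width even
  where the fiber is locally oblique. Fibers thinner than 3 px are
  refused — below that the distance transform quantizes too coarsely.
* **Grid sides** are measured per pore row/column as the foreground
  extent along a scanline through the row's center, which matches the
  generator's definition of a jittered printed side.
* **Cell area fraction** converts to 8-bit, thresholds cells to white,
  measures the *black* fraction and reports one minus it. For binary
  images foreground + black fraction is exactly 1.
  `compare_plane_coverage()` reports per-plane effect sizes and a
  homogeneity flag ((max − min)/mean < 20 % by default); hypothesis
  testing across planes is intentionally out of scope.

## Synthetic data: what it emulates, and what it does not

No raw instrument data accompany the study conditions, so the
generators are *phenomenological stand-ins* whose one contractual
property is the location of the feature the analyzers consume:

* **Gelation sweeps** — the published record shows gelation curves only
  graphically, so no functional form is prescribed anywhere. G′ rises
  as a saturating exponential; the log loss tangent decays
  monotonically from log 10 toward log(G″∞/G′∞) with its timescale
  *solved* so that tan δ = 1 exactly at the requested crossover. The
  monotone construction guarantees exactly one crossing in any window
  containing it, and none otherwise (or when the G″ plateau exceeds
  the G′ plateau — a material that never gels).
* **Yield sweeps** — same trick in log stress: tan δ = (σ/σ_y)^α with
  α anchored so the low-stress plateau has the requested G″/G′. The
  default grid spans 0.1 Pa to max(100, 2σ_y) Pa, wider than the
  nominal 0.1-100 Pa protocol because realistic yield values exceed
  100 Pa.
* **Noise** is multiplicative log-normal on moduli and viscosity —
  instrument-like, positivity-preserving, and median-unbiased so
  expected crossings do not move.
* **Images** are rendered binary at 8-bit depth with half-open
  rasterization (a w-px fiber is w ± 1 px wide at every row). Grid
  truth records the *pre-rasterization* side lengths so measurement
  error can be attributed honestly. Drops are ideal circles; particles
  are non-overlapping disks; nuclei are non-overlapping spots placed
  until the requested area fraction is reached (the rendered fraction,
  returned as truth, lands within one spot area ≈ 0.08 percentage
  points of the request).

Every generator takes one explicit seed, uses `withr::with_seed`, and
leaves the caller's RNG state untouched; identical seeds give
bit-identical outputs.

These generators deliberately do **not** model gelation chemistry
(CaCO₃/GDL kinetics), spreading hydrodynamics, optical blur, uneven
illumination, out-of-focus planes or segmentation ambiguity. Passing
round-trip tests therefore demonstrates that the *measurement and
scoring chain* is correct and unbiased at pixel resolution — not that
segmentation would be this clean on real micrographs.

## Default parameters and problem sizes

The demo configuration (`demo_config()`) encodes the study conditions:
three materials with gel points 120/60/60 min and yield stresses
205/155/121 Pa, a 22G × 12.5 mm needle, 20 × 20 mm CAD squares with a
5 × 5 pore grid (the pitch a 25 % grid infill gives at this fiber
diameter), 100 µL drops every 30 min, 0.45 mm fibers rendered at
25 µm/px, 1 % multiplicative instrument noise, and uniform 5 %
per-plane nuclei coverage. Time sweeps are sampled at 1 min (gel-point
tolerance is therefore one sampling interval, matching the roundness
of reported gel points); amplitude sweeps use 60 log-spaced points;
flow curves 50 points over 1-100 s⁻¹. Monte-Carlo checks in the test
suite use 50-200 replicates and 12-50 image seeds — sizes chosen so
the whole suite runs in about a minute on one core while keeping
sampling error an order of magnitude below every asserted tolerance.

## Known limitations

* The score formulas are algebraic transcriptions fixed by this
  package's documentation and tests; other printability indices exist
  in the literature and are not interchangeable with these.
* The pressure model ignores entrance effects, the syringe barrel
  taper and wall slip; it is a lower bound.
* The cap model assumes an axisymmetric drop on a flat, homogeneous
  substrate; contact-angle hysteresis is invisible to it.
* Grid measurement assumes an axis-aligned grid with detectable
  enclosed pores; heavily merged or collapsed pores raise errors
  rather than guessing.
* `read_rheo_table` accepts only the package's own CSV dialect;
  vendor exports need one rename/reshape step upstream.
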