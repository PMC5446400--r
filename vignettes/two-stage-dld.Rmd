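---
title: "Models and methods: two-stage DLD cluster sorting at desk scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: two-stage DLD cluster sorting at desk scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dldcluster)
```

`dldcluster` models a two-stage deterministic lateral displacement (DLD)
chip that isolates circulating tumor cell (CTC) clusters from blood by
size and asymmetry. This vignette is the package's account of the
science behind each module: the models, their assumptions, the
parameters that matter, and what the desk-scale tests do and do not
demonstrate.

## The separation principle

A DLD array is a lattice of pillars in which each pillar row is offset
laterally by a fraction $\varepsilon$ of the pitch $\lambda$. Flow
through each gap divides into $N = 1/\varepsilon$ flux lanes; a particle
whose effective radius exceeds the width $\beta$ of the wall-adjacent
lane is bumped across lanes at every row and drifts along the array axis
("displaced", one pitch per reset), while smaller particles follow the
flow ("zigzag"). The critical diameter is $D_c = 2\beta$.

The device modeled here exploits two cluster properties:

* **Stage 1 (size).** Cylindrical pillars (50 µm) with 63 µm gaps,
  $\varepsilon = 1/7$ and a 90 µm ceiling. The deep channel lets
  clusters align their longest axis vertically, so the array sees their
  *transverse* extent: only clusters at least ~30 µm thick in every
  direction deflect.
* **Stage 2 (asymmetry).** Asymmetric pillars — an upstream "I"-grooved
  rectangular half and a downstream semi-elliptical half, 77 µm wide by
  60 µm along flow — with the same gaps and tilt but a 30 µm ceiling.
  Flattened clusters tumble when they traverse the grooved faces; a
  cluster that presents its long axis laterally deflects even though its
  transverse axis is below $D_c$. Spherical single cells have no long
  axis to present and stay in the flow.

Undeflected output of Stage 1 feeds Stage 2; each stage sends one third
of its flow to a product stream, giving three terminals: Stage 1 product
(large clusters), Stage 2 product (small clusters), Waste (blood).

## Design arithmetic (`geometry`, `hydraulics`)

`critical_diameter()` implements three constructions. The default
parabolic flux rule solves $3x^2 - 2x^3 = \varepsilon$ for the
first-lane width fraction $x = \beta/g$ (bisection to $10^{-10}$); with
$g = 63$ µm and $\varepsilon = 1/7$ it yields 29.97 µm — the design's
nominal 30 µm. The plug rule $D_c = 2g\varepsilon$ (18 µm) and Davis'
empirical correlation $1.4\,g\,\varepsilon^{0.48}$ (34.7 µm) bracket it;
the correlation disagrees with the nominal value and is provided for
comparison only.

Reset bookkeeping encodes that a continuously displaced particle crosses
one lateral pitch per reset, so an array `n_columns` pitches wide needs
at least that many resets; the fabricated stages carry safety margins of
4 (Stage 1) and 16 (Stage 2) extra resets.

Outlet splits are set by resistance matching. `channel_resistance()`
uses the wide-duct formula $R = 12\mu L / (w a^3 (1 - 0.63a/w))$ with
the shorter cross-section dimension cubed; `design_split()` returns the
branch resistance that draws a target fraction against a fixed branch,
and `outlet_network()` matches the Stage 1 compensation branch against
the *entire* undeflected path (Stage 2 plus its outlet pair), which is
what makes the one-third splits come out exactly in the full network. A
uniform Newtonian viscosity of 1 mPa·s is assumed throughout; blood's
higher effective viscosity also slows it relative to the buffer co-flow,
so the uniform assumption is a reasonable screen for wall stresses.

## Unit-cell flow solver (`flowfield`)

The solver computes steady viscous flow in one periodic unit cell (one
row pitch × one lateral pitch, pillar centered). Numerical choices:

* **Staggered (MAC) grid, sparse direct solve.** Velocities on faces,
  pressure at centers, 5-point Laplacian plus a linear drag term; one
  sparse LU factorization per depth mode with two forcings (x and y).
  The two solutions are combined so the net lateral flux is zero (mean
  flow along the channel axis) and rescaled exactly to the target
  per-gap flow — Stokes linearity makes iteration unnecessary.
* **Shifted periodic wrap.** Crossing the downstream boundary re-enters
  laterally shifted by the row shift, so the single cell tiles the whole
  tilted array. The grid spacing is derived as `dx = Lx/nx` so the wrap
  is geometrically exact; the default resolution is 2 µm/cell.
* **Ghost-cell immersed boundary.** A face is solid when either adjacent
  cell center is inside the analytic pillar outline (so no flux ever
  leaks into solid cells and mass is conserved to solver precision);
  stencil legs that cross the outline are shortened to the bisected wall
  distance, restoring near-second-order wall placement. Critical
  diameters and peak shears move by under 3% between 2 and 1 µm grids.
* **Depth treatment.** `midplane_2d_brinkman` solves the depth-averaged
  field with the shallow-channel drag $-12\mu/h^2\,u$ (midplane = 1.5×
  depth average). `coarse_3d` expands the velocity in odd sine modes of
  depth; each mode is an independent 2D solve with drag
  $\mu(k\pi/h)^2$ and the modes sum to a divergence-free slab flow with
  no-slip floor and ceiling. Three modes change results by under 1%
  versus five. The z-momentum equation is neglected (per-mode pressure),
  which is the usual slab approximation.
* **Hybrid pillar fillets.** Fabricated pillars have finite corner
  radii; a perfectly sharp corner carries a stress singularity whose
  discrete value grows without bound under refinement. The hybrid
  outline therefore takes a `corner_radius` (default 4 µm,
  photolithography-scale) applied to the upstream corners, groove mouths
  and groove floors. The exact groove dimensions are not published;
  groove width/depth fractions (defaults 1/3 and 1/4) and the fillet are
  explicit parameters.

From a solved field: `critical_diameter_from_field()` applies the
first-streamline construction at the gap throat — the station of
maximum pillar half-width, with wall positions taken from the analytic
outline rather than the rasterized staircase — and doubles the width of
the wall-adjacent midplane stream carrying flux fraction $\varepsilon$,
averaging the two walls. For the Stage 1 cylinder cell this gives
27.8 µm, within 10% of the analytic 30 µm; the gap between the two is
real hydrodynamics (the converging–diverging cylinder-array profile is
flatter than a parabola, and depth drag flattens it further).

`wall_shear_map()` evaluates two wall families: floor/ceiling shear from
the depth model's wall gradient, and pillar-wall shear by probing the
tangential midplane velocity at two fixed distances (4 and 8 µm) off the
analytic outline and extrapolating the gradient quadratically through
the no-slip anchor. Fixed physical probe distances make the estimate
mesh-convergent and regularize residual corner concentrations at the
probe scale — comparable to the element size a practical 3D mesh would
use. At the standard 0.5 mL/hr operating point the solver reports peak
shears of about 2.8 Pa (Stage 1, at the gap throat) and 6.0 Pa (Stage 2,
at the filleted leading corner and lateral face), both well under the
5–20 Pa arterial range.

`asymmetry_metric()` scores the fore–aft mirror asymmetry of the
midplane speed pattern about the throat line. Because the array tilt
itself breaks this symmetry (~0.1 for a tilted cylinder cell), the score
isolates pillar shape when evaluated on untilted cells: cylinders score
below 0.05 (discretization residue) while the hybrid pillar scores about
0.17.

## Cluster transport (`transport`)

The simulator is a reduced kinematic model, the standard level for DLD
mode logic:

* the centroid advects along the interpolated midplane velocity (RK4,
  arc-length step of half a grid cell);
* hard contact keeps the centroid one effective radius clear of the
  pillar surface — the nearest-point signed distance to the sampled
  analytic outline — which produces the bump. Using the true outline
  matters: a rectangular-footprint stand-in for the hybrid pillar holds
  particles tens of microns off the real elliptical surface and breaks
  the lane logic;
* orientation: under a tall ceiling the long axis is taken near-vertical
  (Gaussian tilt noise, SD 0.15 rad) so the presented diameter is close
  to the transverse axis; under a shallow ceiling the cluster lies flat
  in its two longest principal axes and its presented diameter is the
  lateral extent at the current in-plane angle;
* rotation in the flat regime combines damped rigid-body rotation
  (half the vorticity times a confinement factor, default 0.2 — floor
  and ceiling at 30 µm strongly hinder free tumbling) with a
  groove-induced restoring torque toward the perpendicular pose while
  the centroid passes a grooved face. The torque strength is a free
  parameter (default 20, roughly 1.4 rad per passage): the mechanism is
  documented for this pillar class but its magnitude is not, so the
  default is set in the middle of the wide plateau where marginal small
  clusters deflect with the torque and mostly do not without it —
  which is the qualitative behavior the stage exists to produce;
* per-reset drift is measured after a one-reset lead-in (the entry
  transient before a particle reaches its first pillar lane would
  otherwise dilute the average); displaced means at least 0.9 pitch per
  reset, zigzag at most 0.1, anything else mixed;
* degenerate situations: stagnation points get a deterministic lateral
  nudge; clusters taller than a ceiling in their flattest pose are
  flagged as jammed and excluded from flow.

`simulate_device()` chains the stages (displaced at Stage 1 → product;
else re-oriented for Stage 2; displaced → product; else waste) and
reports per-class outlet fractions with the enumeration size classes
(single = 1 cell, small = 2–8, large = ≥ 9).

## Enumeration (`enumeration`)

The image pipeline mirrors a standard high-content script: adaptive
local-window threshold (window 50 px, offset 0.08 by default — both were
tuned per experiment in practice and are exposed), morphological
opening, distance-transform watershed declumping, then events as
connected components of the membrane-contact graph (labels touching
within a one-pixel dilation). Classification is a pure function of
component areas: isolated cell → single; component area **strictly
greater** than 3169 µm² → large cluster; otherwise small cluster. At
0.65 µm/px the cutoff corresponds to ~7500 px and ~8.7 cells of the
implied ~365 µm² reference cell, which is how the 2–8 / ≥9 cell class
boundary arises. Overlays color outlines blue (singles), yellow (small)
and red (large).

## Synthetic data (`synthio`) — and what it does not emulate

The generators exist so every module is testable with no external data:

* **Populations**: log-series cluster sizes (θ = 0.85, truncated at 150
  cells) put most clusters at 2–4 cells with a tail past 100; single-CTC
  diameters are uniform on 4–30 µm; cluster members uniform on 10–20 µm
  (cultured-cluster-like); clusters grow by random sequential attachment
  of touching spheres, which guarantees a connected contact graph and
  generically asymmetric shapes. These are stand-ins: the true
  cluster-size distribution of cultured or patient material is not
  published, and no biological packing model is claimed.
* **Frames**: blurred discs with per-cell intensity variation on a noisy
  background (1392 × 1040 px at 0.65 µm/px, Poisson event counts,
  Gaussian noise SD 0.02, blur σ 1.5 px), with exact per-event ground
  truth. The 50-frame benchmark scores detection-plus-classification
  accuracy against that truth; the default pipeline exceeds 90%.
  Real blood-run imaging adds red-cell clutter, debris,
  out-of-focus cells and uneven illumination that these frames do not
  contain, so the benchmark demonstrates pipeline correctness, not
  field performance.
* **Count tables**: multinomial draws from given stream probabilities,
  for parameter-recovery checks of the statistics.

Passing desk-scale tests therefore shows the implementation is faithful
to the models — it does not reproduce blood-run capture efficiencies,
which depend on cell deformability, crowding and other physics outside
scope (below).

## Statistics (`stats`)

Partition fractions are computed per replicate and summarized as mean ±
sample SD; the three stream fractions sum to 100% per class by
construction, and recovery equals 100% minus the waste fraction.
Summing *published* stream summaries uses the independence
approximation $\sqrt{sd_1^2 + sd_2^2}$ — the replicate-level correlation
is not recoverable from printed tables, which is why raw-count recovery
is preferred. Log10 depletion is `log10(input/output)` on
concentration × volume counts, additive over serial stages, and censored
(reported as a bound) when the output count is zero. Viability
comparisons use a pooled-variance two-sample t test on replicate
percentages (two-sided, 95% CI): with duplicate/triplicate conditions,
per-group variance estimates are too unstable for separate weighting,
and the pooled test reproduces the expected verdicts on the published
viability series (no difference at ≤1.0 mL/hr; clear loss at ≥2.5
mL/hr). Cytometry gating is hierarchical: nuclear⁺ required, then
epithelial⁺/leukocyte⁻ → cancer, viable iff viability⁺ and apoptosis⁻.

## Problem sizes

The shipped tests and the acceptance script solve unit cells at
2 µm/cell (about 3000–5000 cells per field, three depth modes), advect
tens of particles over three resets, and score 50 synthetic frames —
sizes chosen so a full run completes in a few minutes on a laptop while
every reported quantity is grid- and seed-stable at the tolerances the
tests assert.

## Known limitations

* The flow model neglects z-momentum (slab approximation) and inertia;
  it is not a substitute for a full 3D simulation when absolute shear
  values matter beyond a few tens of percent.
* Transport is kinematic: no hydrodynamic resistance tensors, lift,
  deformation, adhesion or particle–particle interactions. Blood-cell
  crowding — the suspected cause of reduced small-cluster recovery in
  whole blood — is deliberately not modeled.
* The groove torque magnitude and the Stage 2 groove geometry are free
  parameters, constrained qualitatively, not measured.
* Enumeration assumes a single fluorescence channel; two-channel
  leukocyte subtraction is provided only as count arithmetic
  (`wbc_counts()`).
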