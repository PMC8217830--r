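---
title: "Modelling local oxygen challenges through a PDMS exchange window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling local oxygen challenges through a PDMS exchange window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxywindow)
```

## The physical picture

A gas-exchange chamber sits under a glass slide; rectangular windows cut in
the slide are sealed by a thin (~25 µm) polydimethylsiloxane (PDMS)
membrane, and a muscle rests on top. Changing the chamber gas changes the
oxygen partial pressure (PO2) at the window surface almost instantly, and
oxygen then diffuses through the membrane into the tissue. Because PDMS
conducts oxygen well, the membrane also carries the perturbation *sideways*
past the window edge, so the challenged region is larger than the window
footprint. `oxywindow` quantifies that region and the speed of the
response.

## Governing equations and assumptions

Two diffusion regions share the PO2 field `P(x, y, z, t)`:

* **Tissue** (`z > h_pdms`): `k ∂P/∂t = Dk ∇²P + Kk(1 − P/P0) − M0 P/(P + P50)`.
  The capillary bed is modelled as a homogeneous volumetric exchanger with
  rate `K` toward the mean capillary PO2 `P0`; consumption is
  Michaelis–Menten with maximum `M0` and half-saturation `P50`.
* **Membrane** (`0 ≤ z ≤ h_pdms`): pure diffusion, `k′ ∂P/∂t = D′k′ ∇²P`.

Key assumptions: oxygen moves by diffusion only (no convective transport by
flowing red cells), supply and consumption are spatially homogeneous (no
discrete vessels), solubilities and diffusivities are constant (no
temperature or CO2 dependence), and haemoglobin saturation is not a state
variable. Dividing the tissue equation by `k` puts everything in PO2 units;
the consumption prefactor becomes `M0/k ≈ 4.04 mmHg/s`.

All internal units are µm, s and mmHg; literature diffusivities in cm²/s
convert as 1 cm²/s = 10⁸ µm²/s.

| symbol | meaning | default | units |
|---|---|---|---|
| `D`   | tissue O2 diffusivity          | 2410    | µm²/s |
| `k`   | tissue O2 solubility           | 3.89e-5 | mL O2/mL/mmHg |
| `D′`  | PDMS O2 diffusivity            | 3400    | µm²/s |
| `k′`  | PDMS O2 solubility             | 1.32e-5 | mL O2/mL/mmHg |
| `M0`  | maximal consumption            | 1.57e-4 | mL O2/mL/s |
| `P50` | half-maximal-consumption PO2   | 0.5     | mmHg |
| `P0`  | mean capillary PO2             | 48      | mmHg |
| `K`   | capillary exchange rate        | 30      | mmHg/s |
| `h_pdms` | membrane thickness          | 25      | µm |

With these defaults the reaction term has a unique positive root
`equilibrium_po2() ≈ 41.62 mmHg` — unique because both the source and the
consumption are monotone in `P` — which is the far-field tissue plateau and
the natural cold-start value.

```{r}
equilibrium_po2()
reaction_rate(c(0, 41.62, 48))
```

## Geometry and boundary conditions

The domain is a box: glass plane at `z = 0`, membrane up to `z = h_pdms`,
tissue above. Windows are closed rectangles on the glass plane; every
`z = 0` node inside a rectangle is clamped to the chamber PO2 (Dirichlet),
the rest of the glass and all other outer faces are zero-flux. The grid is
vertex-centred and isotropic; `h_pdms` must be a multiple of `dx` so the
material interface falls on a grid plane.

The default box is 1200 × 1000 µm laterally with 300 µm of tissue at
`dx = 5 µm`, sized so every reported extent (~130 µm depth, ~120 µm lateral
spread) stays at least 150 µm from all zero-flux walls; at that distance the
field has visibly joined the far-field plateau (the corner node sits within
0.001 mmHg of the reaction equilibrium in the shipped checks). Halving the
lateral margins was the main risk; comparing `dx = 6.25` and `dx = 5` runs
on the full box changes every extent metric by at most one grid cell
(≤ 3 %), which is the package's grid-sensitivity evidence at desk scale.

Coordinate conventions, fixed package-wide: "depth from the glass" is `z`;
"depth from the tissue surface" is `z − h_pdms`.

## Discretisation

Space: second-order central differences. Time: a semi-implicit
(implicit–explicit) update — in tissue

```
P⁺ = [ P + dt ( D ∇²P + K − (M0/k) · P/(P + P50) ) ] / ( 1 + dt·K/P0 )
```

with diffusion and the nonlinear sink explicit and the *linear* part of the
capillary source implicit, which buys stability over forward Euler at no
extra cost; membrane nodes update by explicit diffusion alone. The step is
bounded by the 3D diffusion limit `dx²/(6·max(D, D′))` with a 0.9 safety
factor (`stable_dt()`); the implicit source term only helps, so this bound
is governing. A uniform field at `equilibrium_po2()` is an *exact* fixed
point of the update — the IMEX splitting does not bias the equilibrium.

**Material interface.** The PDMS/tissue boundary lies on a grid plane, so
the interface node's control volume is half membrane, half tissue. Its
vertical faces carry the pure one-sided products `D′k′` (below) and `Dk`
(above), balanced over a composite solubility `(k + k′)/2`, with lateral
faces at the arithmetic mean of `Dk` and the tissue reaction at half
weight. This conservative treatment makes the discrete steady state exact
for piecewise-linear two-layer profiles (continuity of `P` and of flux
`Dk·∂P/∂z`), which is what the two-layer verification below demands.

**Zero-flux faces** use mirror ghosts: the missing neighbour reflects the
opposite one, doubling that face term. This keeps the spatial order at two;
the shipped convergence check estimates order ≥ 1.7 on a smooth 1D
column with linearised consumption (observed ≈ 2).

**Degenerate inputs and failure modes.** Negative or non-finite PO2 after a
step raises an error naming the node and time rather than clamping — an
unstable `dt` should surface, not hide. `Lx = 0`/`Ly = 0` collapse axes for
1D verification columns; `h_pdms = 0` removes the membrane.

## Steady state, settling, and protocols

The field is declared steady when the largest nodal rate `|ΔP|/dt` drops
below `steady_tol` (default 10⁻³ mmHg/s; with the slowest relaxation rate
`K/P0 = 0.625 s⁻¹` this bounds the remaining field error by roughly
`steady_tol/(K/P0) ≈ 2×10⁻³ mmHg`). The stopping rule is a package choice —
the criterion is configurable — and `run_to_steady_state()` reports the
first time it held.

`settle_time()` reports the first time a probe trace enters and stays
within `tol` (default 0.1 mmHg) of its final value. Because the final
sample trivially matches itself, a trace whose in-band tail covers less
than 5 % of its duration is reported as `Inf` with a warning.

Gas protocols are piecewise-constant, right-continuous schedules; the
boundary PO2 switches instantaneously at segment edges, mirroring the
assumption that chamber exchange is much faster than tissue diffusion.
Fractions convert to mmHg as dry gas at 760 mmHg by default; a humidified
flag subtracts 47 mmHg of water vapour. The chamber is fed by dry
mass-flow-metered gas, hence the dry default; both conversions are
supported and logged. `square_wave_protocol()` is the built-in 6-minute
5/12/2/5 % schedule. Within a segment the boundary is constant, so once the
field reaches `steady_tol`, `run_protocol()` holds it analytically for the
remainder of the segment (`fast_forward`), making long schedules cheap
without changing any recorded value by more than the steady tolerance.

## Perturbation-extent metrics

The perturbed region ends where the magnitude of the PO2 directional
derivative drops below `e⁻⁴ ≈ 0.0183 mmHg/µm` (`extent_criterion()`). The
threshold rule does not by itself fix an evaluation locus, so the package
pins these choices and records them in every `extent_report()`:

* **Depth**: along the vertical line through the window centroid, the
  largest `z` whose central-difference `|∂P/∂z|` still meets the threshold,
  reported from the tissue surface.
* **Lateral extents**: in each horizontal plane at or above the tissue
  surface, march outward from the window-edge midpoints along the window
  axes (both directions, larger taken); the first node *strictly below*
  threshold ends the ray, distance measured from the edge-node centre. The
  headline value is the maximum over planes; per-plane profiles and
  single-plane evaluation (`plane_z`) are also available since both
  readings of "maximum extent" are defensible.
* **Affected area** at an imaging plane: window dimensions plus twice the
  lateral extents in that plane.

All extents are non-increasing in the threshold and invariant (to one grid
cell) under window translation away from the walls; both properties are in
the test suite. On synthetic exponential fields the metrics match their
closed forms to within one grid spacing.

## Verification strategy

The production kernel is never its own referee. `verify_solver()` compares
it against independently coded references:

```{r, eval = FALSE}
verify_solver()
#>   [PASS] dense Newton vs time-marched steady (10^3 grid)    error ~7e-07 (tol 0.001)
#>   [PASS] two-layer linear profile vs closed form (1D)       error ~8e-09 (tol 1e-04)
#>   [PASS] linearised consumption vs cosh profile (1D)        error ~4e-05 (tol 0.001)
#>   [PASS] no-window relaxation to reaction equilibrium       error ~2e-07 (tol 0.05)
```

* `two_layer_steady_profile()` — piecewise-linear steady diffusion through
  two dissimilar layers; exercises the interface stencil exactly.
* `linear_consumption_profile()` — `cosh` profile of a column with
  consumption linear in `P` (the capillary source linearises to
  `α = K/P0`, decay length `√(D/α) ≈ 62 µm`).
* `krogh_slab_depth()` — the classical zero-order-consumption depth scale
  `√(2·D·Ps/(M0/k))`; ~134 µm for a 15 mmHg surface drop, a useful sanity
  scale for the simulated ~145 µm penetration.
* `dense_steady_solution()` — damped Newton on an independently assembled
  sparse steady system (≤ 2000 nodes), sharing no stencil code with the
  kernel.

A scalar Runge–Kutta integration of the reaction ODE checks the IMEX time
discretisation on a well-mixed domain, and the cosh column at two
resolutions estimates the spatial order.

## What the study scenario does and does not emulate

The shipped defaults describe the reference challenge: one 400 × 200 µm
window, 25 µm membrane, 2 % O2 against a 5 % baseline, default muscle
parameters. Within those assumptions the model reproduces the expected
behaviour — penetration ~145 µm below the tissue surface, lateral spread
~120/125 µm beyond the edge, a ~580 × 400 µm affected footprint at the
75 µm imaging plane, settling in ~3–3.7 s.

Passing these checks shows the *solver* is faithful to the *model*; it does
not show the model is faithful to real muscle. Real tissue has discrete
capillaries with flowing red cells (convection limits penetration further;
local supply heterogeneity broadens it), consumption varies with fibre
type and activity, and measured saturation responses extend farther than
this homogeneous model predicts. Parameter sweeps (`M0`, `K`, membrane
thickness) are the intended way to explore that sensitivity.

## Numerical sizes used by the shipped checks

Problem sizes were chosen as the smallest that keep every verification
meaningfully resolved: the end-to-end reference chain runs the full default
footprint at `dx = 6.25 µm` (~1.6 M nodes, ~75 s on one CPU); the
acceptance script uses `dx = 5 µm` (~3.2 M nodes, a few minutes); oracle
comparisons use 10³-node 3D grids and ≤ 400-node 1D columns. `dx = 6.25`
rather than a coarser power of two keeps the 25 µm membrane grid-aligned.

## Known limitations

* Diffusion only — no convective O2 transport by moving red cells.
* Homogeneous source/sink — no vascular geometry, no oxygen-dependent flow
  regulation.
* Explicit diffusion stepping — fine at `dx ≥ 5 µm`, but the `dx²` step
  bound makes sub-micron grids impractical; an implicit diffusion solve
  would be the natural extension.
* The window pitch of multi-window slides is a required configuration value
  (no default is bundled), and `five_window_layout()` assumes a collinear
  row.
* Settling times depend visibly on the 0.1 mmHg band: with the default
  band the deepest probes settle in ~3.7 s, while any band ≥ 0.2 mmHg
  (still below plotting resolution) reads as ≤ 3 s. Report the band with
  the number.
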