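---
title: "Poroelastic wound signaling: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Poroelastic wound signaling: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poroplant)
```

## The physical picture

A turgid plant is a water-filled poroelastic composite with two very
different compartments. The xylem is a bundle of dead, stiff conduits with
low flow resistance: its hydraulic conductivity `k_xyl` is large and its
capacitance `c_xyl` (moles of water stored per volume per Pa) is small, so
pressure perturbations diffuse through it with an enormous poroelastic
diffusivity `kappa_xyl = k_xyl / c_xyl ~ 1 m^2/s`. The living tissue around
the veins is the opposite: soft, high-capacitance cells connected by
high-resistance paths, with `kappa_t ~ 1e-10 m^2/s` — coincidentally the
molecular diffusivity of a small solute.

Wounding ruptures cells and releases their water into the tensioned xylem
(gauge pressure `P0 ~ -0.2 MPa`). Two transients follow:

1. **Fast xylem relaxation.** Pressure equilibrates along the whole plant
   axis within `tau_xyl = L^2 / kappa_xyl` — 100 µs for a 1 cm herbaceous
   plant, 40 ms for a 20 cm cereal seedling, under a second for anything
   below a meter. This phase communicates the wound everywhere essentially
   instantaneously on physiological timescales.
2. **Slow tissue relaxation.** With the local xylem now near atmospheric
   pressure, tissue everywhere draws water from its vein and its turgor
   rises from `P0 + pi_t` toward `pi_t` (0.75 MPa for the default osmotic
   pressure). The half-spacing between veins `W` is the diffusion length, so
   `tau_t = W^2 / kappa_t` — minutes, and nearly species-independent because
   vein spacing is conserved (0.1–1 mm).

The mass flows these transients drive through the xylem can advect a
wound-released chemical elicitor; the pressure/strain changes themselves are
a candidate mechanical signal. The package simulates both and the
quantitative comparison between them.

## Model equations and geometry reduction

The plant is reduced to a 1-D axial xylem line `x in [0, L]` (wound at
`x = 0`, stem node at `x = L/2`, distant leaf tip at `x = L`), each axial
station carrying a 1-D transverse tissue slab `y in [0, W]`. Per unit vein
length, with `C_x = c_xyl a_xyl` and `K_x = kappa_xyl C_x`:

```
C_x dP_xyl/dt = K_x d2P_xyl/dx2 - Q_t - Q_E + Q_stem      (xylem)
c_t dP_t/dt   = k_t d2P_t/dy2                              (tissue)
```

with coupling through water-potential continuity at the vein,
`P_t(y = 0) = P_xyl(x, t) + pi_t` (tissue osmotic pressure constant and
uniform during the fast transients; xylem osmotic pressure zero), symmetry
at mid-spacing `y = W`, and

* `Q_t = 2 d_th k_t dP_t/dy|_0` — membrane draw into the tissue on both
  sides of the vein;
* `Q_E = 2 E (2W)` — transpiration from both leaf surfaces of the strip a
  vein serves;
* `Q_stem = h_stem a_stem (0 - P_xyl)` — a lumped stem/soil water source at
  one interior cell.

The transverse reduction is the model's own timescale analysis made
geometric: `tau_t = W^2 / kappa_t` is one-dimensional in the across-leaf
coordinate, and a full 2-D lamina adds nothing at the level of the
quantities compared here.

**Why transpiration enters the xylem line, not the tissue slab.** Routing
`E = 1e-3 mol m^-2 s^-1` through tissue of conductance `k_t = 1e-12
mol m^-1 Pa^-1 s^-1` over `W = 200 µm` would require a pressure drop
`E W / k_t ~ 2e8 Pa`, five orders beyond the physiological scale. Real
leaves evaporate through low-resistance apoplastic paths near the veins, so
the homogenized model must take transpiration as a draw on the xylem line.
The package therefore always applies `Q_E` axially; an alternative
tissue-side placement was considered and rejected on this argument.

**Wound boundary.** The wound cell holds `P_xyl = wound_pressure` (0 gauge
by default) while released water lasts. `sustained_reservoir` idealizes a
water-immersed wound; `depleting_reservoir` an air-exposed wound that seals
(switches to no-flux) once the cumulative influx reaches `reservoir_moles`,
after which xylem tension redevelops and elicitor propagation stops short —
the mechanism behind the immersed-versus-air-exposed difference. The switch
is evaluated every substep and the switch time recorded. In examples and
tests the depleting reservoir defaults to `1e-7 mol` (about 2 nL of liquid
water, the content of a small crushed wound region); the parameter is
always explicit, never hidden.

**Initial condition.** Transpiring runs start from the computed pre-wound
steady state (stem source balancing transpiration; tissue in local
water-potential equilibrium). Nontranspiring (`E = 0`) wounded runs cannot:
their steady state is the atmospheric rest state `P = 0`, which carries no
wound response, while the published nontranspiring simulations clearly
retain the characteristic tension. They therefore start from uniform `P0`
with tissue at `P0 + pi_t`, i.e. a plant that was recently under tension.
`steady_state()` itself always answers the steady-flow question (`E = 0`
gives `P = 0` everywhere).

## Parameters

| field | meaning | default (herbaceous preset) | unit |
|---|---|---|---|
| `L` | leaf-tip-to-leaf-tip span | 0.01 | m |
| `vein_spacing` | `2W`, distance between parallel veins | 4e-4 | m |
| `d_th` | leaf thickness | 2e-4 | m |
| `kappa_xyl` | xylem poroelastic diffusivity | 1 | m²/s |
| `kappa_t` | tissue poroelastic diffusivity | 1e-10 | m²/s |
| `c_t` | tissue hydraulic capacitance | 1e-2 | mol m⁻³ Pa⁻¹ |
| `c_xyl` | xylem hydraulic capacitance | 5.6e-4 (calibrated) | mol m⁻³ Pa⁻¹ |
| `a_xyl` | conducting xylem cross-section per vein | 1e-8 (calibrated) | m² |
| `P0` | pre-wound xylem pressure (tension) | -0.2e6 | Pa gauge |
| `pi_t` | tissue osmotic pressure | 0.75e6 | Pa |
| `E` | transpiration flux per leaf surface | 1e-3 | mol m⁻² s⁻¹ |
| `h_stem` | stem source conductance per area | 1e-8 | mol m⁻² Pa⁻¹ s⁻¹ |
| `a_stem` | stem coupling area | 4e-6 (calibrated) | m² |
| `D` | elicitor molecular diffusivity | 1e-10 | m²/s |
| `Vw` | molar volume of water | 1.8e-5 | m³/mol |

Everything internal is strict SI; presets and config files accept
`{value, unit}` pairs (cm, mm, µm, min, MPa, mmol/m²/s, ...) converted once
at parse time, which removes unit mixing as a bug source. Pressures are
gauge (atmosphere = 0).

**Calibrated inputs.** Three parameters are not independently measured and
are documented as calibrated, chosen once and never tuned against test
outcomes:

* `c_xyl = 5.6e-4 mol m^-3 Pa^-1` reproduces the reported fast-relaxation
  tracer displacement of 20 µm through `d = c_xyl Vw |dP| L` with
  `dP = 0.2 MPa`, `L = 1 cm`. It only scales tracer magnitudes and the
  (negligible) xylem storage term; pressure dynamics depend on `kappa_xyl`
  alone.
* `a_xyl = 1e-8 m^2` — a main-vein bundle of roughly 15–20 conduits of
  ~25 µm — sets the conversion from molar flow to tracer speed
  `u = J Vw / a_xyl` and is order-consistent with the reported
  centimeter-scale front plateau.
* `a_stem` makes the pre-wound steady mean xylem pressure equal the
  characteristic tension: `a_stem = 2 E (2W) L / (h_stem |P0|)`. A single
  mesh cell's leaf area cannot pass the whole transpiration stream through
  `h_stem` at 0.2 MPa, so the conductance must be lumped; this is the
  "presets tuned to `P0`" statement made explicit.

## Numerics

* **Space.** Cell-centered conservative finite volumes on uniform meshes;
  Dirichlet boundaries enter through half-cell ghost fluxes; the stem node
  is a conductance on one interior cell. Default coupled mesh 200 x 64.
* **Time.** Theta scheme, fully implicit by default — the only stable
  choice across the ten-decade `kappa_xyl/kappa_t` gap. Crank–Nicolson
  (`theta = 0.5`) is used in verification runs where second-order accuracy
  matters. Output times are geometric from `tau_xyl/20` to `3 tau_t`, so
  both transients are resolved with uniform relative accuracy and the grid
  is scale-free (the property behind the clean `t ~ W^2` and `t ~ L^2`
  scaling recoveries).
* **Coupling.** Each global step is exactly two tridiagonal solves: the
  transverse tissue step's boundary flux is affine in its Dirichlet value,
  `F = (2 k_t/dy)((1 - a) V - b)`, with the scalar `a` shared by all
  stations and `b` obtained by one multi-RHS Thomas sweep vectorized over
  stations; the axial solve absorbs `(1 - a)` into its diagonal. The step
  is therefore fully implicit in the coupling and discretely
  water-conserving: the `water_balance()` audit recomputes every term from
  the same discrete fluxes and its residual is roundoff-level (enforced at
  `1e-6` of the largest term, with an absolute floor at the cancellation
  noise of a quiescent plant).
* **Quasi-steady mode.** `mode = "quasi_steady"` drops the xylem storage
  term (elliptic axial solve per step), exploiting `tau_xyl << tau_t`; it
  agrees with the full integration to better than 1% after `10 tau_xyl` and
  is what the fitting loop uses.
* **Advection.** First-order upwind with CFL substepping, operator-split
  from implicit diffusion. Upwind smearing is controlled through the
  *cumulative* criterion `dx * integral |u| dt <= 0.1 * 2 D t_end`: the
  instantaneous rule `u dx/2 < 0.1 D` is unsatisfiable here because the
  tissue-relaxation velocity decays like `t^(-1/2)` and the fast transient
  briefly reaches ~0.6 m/s, while what actually moves a front is the
  accumulated variance. The mesh auto-refines to meet the criterion (capped
  with a warning at 20 000 cells). For depleting wounds the mesh is sized
  once against the full horizon, not stage-wise.
* **Degenerate inputs.** Singular systems are reported, never regularized:
  `h_stem = 0` with `E > 0` has no steady state and says so; non-finite
  fields, invalid theta, sub-8-cell meshes, zero-dilation (unwounded)
  normalizations and non-monotonic relaxation curves are all hard errors.

## Derived quantities and their definitions

* **Thickness kinetics.** Strain is isotropic linear poroelastic,
  `eps = Vw c_t (P_t - P_t(0))`; normalized thickness is mean strain over
  the exact equilibrium strain `Vw c_t (wound_pressure - P0)`, so
  `theta(t)` equals the analytic slab-uptake fraction and tends to 1. Each
  vein spacing runs on a time grid proportional to its own `tau_t`; the
  `W^2` collapse is then a direct property of the discrete problem and the
  published common-time-axis curves are recovered by interpolation.
* **Relaxation time.** Two definitions are reported because the published
  comparison does not pin one down: the scaling value `W^2 / kappa_t`
  (headline; 225 s = 3.75 min at `2W = 0.3 mm`) and a least-squares
  exponential fit over the rise `theta in [0.05, 0.95]` (systematically
  smaller, since diffusive uptake starts like `sqrt(t)`). The headline is
  the number compared against the observed 3.9 ± 1.7 min.
* **Front distance.** `d(t)` is the farthest point at which concentration
  reaches 1% of the source value — a detection-threshold crossing, as for
  fluorescent reporters. The front is advection-sharp, so the choice is
  insensitive (< 15% between 0.5% and 5%, verified in the tests). A
  tracer-particle displacement definition would track `integral u dt` and is
  available implicitly through the pure-advection limit.
* **Local signals.** Molecular elicitor diffusion and poroelastic pressure
  diffusion in the tissue obey the same radial diffusion equation and are
  solved by literally the same code path (the `kind` argument is a label),
  so the equal-diffusivity ambiguity is structural, not approximate.
  Cylindrical symmetry is the default (a leaf lamina is a thin sheet);
  spherical is an option. The source is a fixed normalized value at a
  10 µm radius — a single-cell wound — since the release kinetics are not
  otherwise constrained. Local advection is excluded by the closed-form
  bound `Vw c_t dpsi W ~ 5 µm`, an order below the observed 0.1–1 mm
  spread.

## What the simulated world does and does not establish

The scenarios are stated parameter worlds, not data fits: geometry,
diffusivities, capacitances and pressures are the published characteristic
values, and the single fitted quantity anywhere is the transpiration flux
`E` (`fit_transpiration_rate()`, bounded 1-D least squares, with
self-recovery verified to 5%). A green test therefore establishes that the
implemented equations reproduce the published scalings, equilibria,
timescales and front magnitudes under those stated parameters — not that
any particular plant obeys them. Features of real systems deliberately not
represented: phloem poroelasticity (slower, excluded), osmotic-pressure
dynamics, nonlinear elasticity and large strains, root architecture beyond
the lumped stem source, Taylor dispersion in the conduits, and all
electrophysiology — observed calcium/electrical signals enter only as
fronts to compare against.

## Known limitations

* First-order upwind advection trades sharpness for monotonicity; the
  refinement guard makes the trade explicit and bounded.
* The quasi-steady mode mispredicts only the first `~10 tau_xyl` of a run,
  by construction.
* `c_xyl`, `a_xyl` and `a_stem` are calibrated, not measured (above); all
  tracer *magnitudes* inherit their uncertainty, while timescales and
  pressures do not.
* The stem far-field potential is fixed at 0 Pa gauge; a dry-soil far field
  would shift the pre-wound tension accordingly.
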