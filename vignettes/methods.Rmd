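---
title: "Methods: pattern-mediated treatment resilience in a tumour–immune model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pattern-mediated treatment resilience in a tumour–immune model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`turimm` analyses a three-species reaction–diffusion model of solid-tumour
immunotherapy. Effector cells `u` are recruited by the tumour (rate
`alpha`), proliferate under IL-2 stimulation with saturating kinetics
(`rho_u u w/(1+w)`), decay (`mu_u`) and are supplied externally
(`sigma_u`). Tumour cells `v` grow logistically against a carrying capacity
scaled to 1 and are killed on contact with effector cells with a
Michaelis–Menten interaction (`u v/(gamma_v+v)`, reflecting that only the
surface of a solid mass is accessible). IL-2 `w` is produced by
effector–tumour interaction, decays quickly (`mu_w = 55.56`, the fastest
timescale in the system) and is supplied externally (`sigma_w`). All three
species diffuse; lengths are scaled so the tumour diffusivity is 1 and time
so the tumour growth rate is 1, making `delta_u` and `delta_w` the
mobilities of effector cells and IL-2 *relative to the tumour*.

The main modelling assumptions inherited with this framework: transport is
pure Fickian diffusion (no chemotaxis, haptotaxis or mechanics), kinetics
are deterministic and continuous-state, and treatment enters either as a
volumetric source or as a prescribed IL-2 concentration on the tissue
boundary. The one transport refinement included is a volume-filling tumour
flux `∇·((1−v)² ∇v)` (option `nonlinear_v` in `simulate_model()`), which
suppresses motility as the tumour approaches confluence.

## Parameters

The reference kinetics are stored in `reference_nondim()`:

| parameter | value | meaning |
|---|---|---|
| `mu_u` | 0.167 | effector death rate (per tumour doubling time) |
| `rho_u` | 0.692 | IL-2-stimulated effector proliferation |
| `mu_w` | 55.56 | IL-2 decay (IL-2 is quasi-steady on cell timescales) |
| `rho_w` | 2.5 | IL-2 production by effector–tumour contact |
| `gamma_v` | 0.1 | half-saturation of effector kill |
| `gamma_w` | 1e-3 | half-saturation of IL-2 production |
| `delta_u`, `delta_w` | 100 (default) | relative mobilities; plausible range runs from below 1 to ~8000 |
| `alpha` | 0.07 (default) | immune-response strength, range 0–0.154 |

These are the published *rounded* values rather than exact ratios of the
underlying dimensional estimates (`nondimensionalise()` reproduces them
from `reference_dimensional()` to printing precision). The package
standardises on the rounded values because all reference quantities —
most visibly the Hopf location `0.0196081750` — are reproducible to many
digits only under them; with exact ratios (`mu_u = 1/6`, ...) the Hopf
point moves to `0.01950`, a 0.5% shift that would silently offset every
downstream number. The dimensional table stores the tumour diffusivity
`1.21e-6 cm²/day`, corresponding to an 11 µm cell diameter at one division
per day; `tumour_diffusivity()` exposes the `D² λ` estimator so other
choices are one call away.

Treatment inputs `sigma_u`, `sigma_w` are *not* baked into protocol state:
kinetics functions accept instantaneous values, so equilibrium analysis
(constant inputs) and simulation (ramped inputs) share one code path.

## Steady states and their classification

The cancer-free state is known in closed form, with eigenvalues
`lambda_1 = 1 − u0/gamma_v`, `lambda_2` (feasibility) and
`lambda_3 = −mu_w`; `transcritical_sigma_u()` gives the dosing level at
which `lambda_1` crosses zero, which is exactly where the constant term
`a0 = gamma_w(gamma_v rho_u sigma_w + (mu_w+sigma_w)(sigma_u − gamma_v
mu_u))` of the coexistence quintic vanishes — the only way the cancer-free
state loses or gains stability is a transcritical exchange with a
coexistence branch.

Coexistence states eliminate `u0 = (gamma_v+v0)(1−v0)` and the
corresponding `w0`, leaving one scalar residual in `v0`. Two independent
routes find its roots in `(0,1)`: a dense sign-scan with bisection polish
(2001-point grid; the default because it makes no assumptions beyond
continuity) and the coefficients of the denominator-cleared quintic via
`polyroot()` (used in grid scans, where it is several times faster). A
property test holds the two routes to within 1e-7 of each other across 200
random parameter draws. Roots closer than 1e-8 merge (folds produce
near-double roots); stability uses `Re(lambda) < −1e-10`, with the band
`|Re| <= 1e-10` flagged marginal and excluded from stable counts so that
classification is deterministic near boundaries.

`scan_stability_plane()` classifies the default window
`sigma_u ∈ [0, 0.05] × sigma_w ∈ [0, 20]` at 201×201; this window contains
every structural feature of the reference kinetics (transcritical ≈ 0.016,
Hopf ≈ 0.0196, all ramp protocols). Grid-cell classification in bulk uses
the Routh–Hurwitz conditions of the characteristic cubic rather than
per-cell `eigen()` calls — same mathematics, two orders of magnitude
cheaper. `bistability_alpha_bound()` bisects `alpha` (step 1e-3) for the
largest value at which both bistability types (cancer-free+coexistence and
two-coexistence) still occur somewhere in the window; with the reference
kinetics this lands at 0.0831.

## Turing analysis

Linearising about a homogeneous state with modes `e^{ikx}` gives a cubic in
the growth rate whose coefficients `dispersion_coefficients()` returns; the
trace-level coefficient is `(delta_u + 1 + delta_w)k²` (the tumour's unit
diffusivity appears explicitly). Since wave instabilities do not arise in
the studied regimes (asserted by a property test: wherever the leading
growth rate of an ODE-stable state is positive it is real), instability is
governed by `a0(k²) = A k⁶ + B k⁴ + C k² + D` turning negative, and it
suffices to test the closed-form interior minimum
`k_c² = (−2B + sqrt(4B² − 12AC))/(6A)`. Cancer-free states short-circuit to
"never Turing-unstable": perturbing `v` about zero is sign-changing, and
the remaining `(u,w)` subsystem is triangular.

`k²` is treated as continuous here (infinite-domain idealisation);
finite-domain quantisation `k = n π/L` under Neumann conditions lives in
`turing_onset()`, which is what the continuation layer uses. In scans with
two stable coexistence states, a cell is labelled Turing-unstable if *any*
stable state is (multistability is deliberately collapsed in the map; the
per-equilibrium information is available by calling `turing_test()`
directly).

## Continuation

Discretised steady states (3-point Neumann Laplacian, the same stencil as
the simulator — an equality asserted to 1e-12 by a dual-assembly test) are
continued in either treatment input by a secant-predictor/Newton-corrector
pseudo-arclength scheme with adaptive step (default 1e-2, halved on
corrector failure, grown 1.4× on fast convergence, capped at 0.1–0.25
depending on the run). Folds are tagged at parameter-direction reversals
and refined by a parabolic fit of parameter against arclength; with the
default steps the arclength refinement error is negligible against the
spatial discretisation error, which dominates and decreases at second
order: the reference patterned-branch fold moves by 1% from m = 128 to
m = 256 (the default), implying a residual error near 0.3% at m = 256 —
far inside the 2% band within which the acceptance test reproduces it.

Negative `sigma_w` is *allowed during continuation only* (it is the only
way to round the fold that anchors the hysteresis loop; `simulate_model()`
rejects negative dosing). The homogeneous branch also has a closed-form
parameterisation by `v0` (`homogeneous_branch()`) because the steady
kinetics are linear in either input — this provides the oracle that the
PDE-level continuation restricted to a degenerate 3-node domain must and
does reproduce.

Branch switching perturbs the homogeneous state along
`cos(nπx/L) ⊗ φ` (φ the critical eigenvector of the mode matrix) and pins
the amplitude while Newton adjusts the parameter. The two half-branch seeds
`±n` are reflections `x → L−x` of each other when `n` is odd; for even `n`
the eigenfunction is itself reflection-symmetric and the two seeds converge
to genuinely distinct sub-branches — the test suite exercises the odd case
for the symmetry property. Criticality is read off the branch geometry:
subcritical if the branch initially extends into the parameter side where
the homogeneous state is still stable. Stability along branches uses dense
eigenvalues of the discretised Jacobian (affordable to m = 256; computed on
demand rather than per point). Branch enumeration is capped (first 12
modes): completeness of the census is not a goal, stable-segment structure
is.

## Simulation

`simulate_model()` integrates the method-of-lines system with
`deSolve::lsodes` (sparse-Jacobian BDF) using an explicitly supplied
sparsity pattern; the well-mixed case runs through `lsoda`. Stencils: 3-point
in 1D, compact 9-point in 2D (exact on quadratics in the interior), ghost
reflection for Neumann walls; the disc is a masked Cartesian grid whose
stair-step rim reflects into the nearest interior node — adequate for the
qualitative and timing targets, not for spectral rim accuracy. Boundary
IL-2 dosing replaces the rim `w`-equations by the exact derivative of the
prescribed dose `B_w(t)` (rim values then track `B_w` exactly, with no
stiffness penalty). The volume-filling flux uses a conservative face
scheme: face diffusivity `((1−v_i)²+(1−v_j)²)/2` times the face-normal
difference, so zero-flux structure is preserved exactly; a uniform state
stays uniform to solver precision.

Reference tolerances are `1e-11` with `m = 1e4` (1D) or `100×100` (2D)
grids. The package's default test and acceptance runs scale this down —
`1e-6`–`1e-8` tolerances, 64×64 grids, `m = 96`–`1024` in 1D — sizes chosen
so each stage completes in minutes on one core; `analysis/05` carries the
grid-refinement comparison for the boundary-dosing runs (64×64 vs 100×100
at `delta_u = 10`) and the homogeneous-limit (`eta = 0`) simulations reduce
exactly to the ODE so their extinction times are tolerance-limited, not
grid-limited.

Extinction is declared when the spatial maximum of `v` first drops below
1e-6, linearly interpolated between saves. At the density scale of the
model (1e6 cells per unit length) this is about one cell — densities below
it are biological fiction. The related `atto_fox_floor` option adds the
sink `−H(1e-15 − v) v` to the tumour equation so that sub-atto densities
cannot later regrow; a test confirms that enabling it changes a patterned
ramp run by less than 1e-10 in max norm, i.e. it removes an artefact
without touching the physics. The Heaviside convention is `H(0) = 1/2`;
every protocol formula used is continuous at its switch points, so the
convention is immaterial (asserted by evaluation at the switch point ± ε).

## Random initial conditions

`perturbed_ic()` emulates the study conditions for simulations: each
species' homogeneous equilibrium value is multiplied by `1 + eta ξ(x)`
with `ξ` i.i.d. standard normal per node and `eta = 0.1` by default, then
floored at zero (at `eta = 0.1` negative draws are a ~1e-23 tail event, so
flooring is a formality rather than a bias). Noise fields are drawn
independently per species by default — the alternative of one shared field
is switchable (`per_species_independent = FALSE`) since either reading is
defensible. Seeds are mandatory whenever `eta > 0`; identical spec and
domain give bit-identical fields, and the RNG state of the caller is
restored afterwards.

What this generator does *not* emulate: spatially correlated perturbations,
heterogeneous tissue (parameter fields), or structured initial tumour
geometries. Passing tests therefore certify the pattern-formation
*mechanism* under generic small perturbations, not robustness to any
particular clinical initial condition.

## What the analysis finds

Numbers below are produced by the test suite and `scripts/acceptance.R`;
none are inputs.

* Homogeneous Hopf point at `sigma_u = 0.0196081750` (`alpha = 0.07`,
  `sigma_w = 0.5`); the L = 30 Turing onset precedes it at `0.0166674`
  (mode 2), and the bifurcating branch is subcritical.
* Both bistability region types persist up to `alpha ≈ 0.0831`.
* The patterned branch seeded from the mode-2 state at `sigma_u = 0.014`
  folds at `sigma_w ≈ −0.8458`; two distinct stable patterned states
  coexist with the stable homogeneous state at `sigma_w = 0` (hysteresis:
  withdrawing IL-2 treatment does not undo patterning).
* Under the slow effector ramp (`0.01 → 0.04` over `T = 1e5`) the
  well-mixed tumour collapses just after the ramp crosses the Hopf point:
  extinction at `t ≈ 34750`, dose `≈ 0.0204` — about half the final dose,
  which spatially patterned runs survive. Under the faster ramp
  (`0.015 + 5e-5 t`) the unperturbed run goes extinct at `t ≈ 176`.
* Boundary IL-2 dosing (`w = 0.01 t` on the rim of a 300×300 square,
  `delta_w = 1000`): extinction at `t ≈ 337` for `delta_u = 10` but
  `t ≈ 1840` for `delta_u = 1000` (64×64 grids, seed 42) — greater
  effector mobility widens the Turing-unstable region and so *delays*
  clearance by a factor above five.

## Known limitations

* Criticality is inferred from branch geometry, not from normal-form
  coefficients; near-degenerate bifurcations could be misclassified if the
  probe window is shorter than the branch's turning scale.
* No two-parameter continuation of bifurcation loci and no 2D
  continuation; 2D multistability is explored only through simulation
  seeds.
* The stair-step disc boundary limits boundary-layer accuracy on discs;
  extinction-time targets on discs should be read with grid error in mind.
* Secondary bifurcations along patterned branches are tagged but not
  followed.
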