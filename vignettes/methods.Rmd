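---
title: "chondrosim: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{chondrosim: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chondrosim)
```

`chondrosim` simulates the mechanobiochemical cascade set off when a
cartilage explant is struck by a drop-tower indenter: impact mechanics,
strain-induced chondrocyte damage, cell-fate kinetics, proteolytic
proteoglycan loss, and antioxidant (NAC) treatment. This vignette is the
package's account of the science it implements, the parameters that matter,
and the numerical decisions taken where the design was genuinely open.

## The constitutive model

Cartilage is modeled as a fibril-reinforced poroviscoelastic swelling
continuum. The solid skeleton splits into a compressible Neo-Hookean
non-fibrillar matrix (proteoglycan gel; modulus `E_nf`, Poisson ratio
`nu_nf`) and a tension-only collagen network. Each fibril obeys a nonlinear
viscoelastic law: a linear spring `E0` in parallel with a Maxwell branch
whose spring is quadratic (stress `E_eps * eps^2`) in series with a dashpot
`eta`. Two limits of this one equation matter in practice and both are
exposed by `fibril_ramp()`:

* **slow loading** — the dashpot flows, the Maxwell branch relaxes, and the
  response tends to `E0 * eps`;
* **millisecond loading** — the dashpot is effectively rigid (its relaxation
  time `eta / (2 sqrt(E_eps * u))` is tens of seconds at the stresses
  reached here, against a 1 ms event) and the response is the instantaneous
  curve `E0 * eps + E_eps * eps^2`.

The implicit integrator (`fibril_stress_update()`) solves the backward-Euler
residual of the overstress ODE by safeguarded root bracketing, clamping the
radicand at `1e-12 * E_eps * E0` so the elastic limit (`sigma = E0 * eps`,
where the original equation is singular) is approached smoothly.

Fluid flow follows Darcy's law with deformation-dependent permeability
`k = k0 * J^M`. Swelling enters through the Donnan osmotic pressure at the
current fixed charge density and through a chemical-expansion stress; the
fixed charge density itself follows volumetric deformation exactly
(`fcd_current()` encodes conservation of the matrix-bound charges). The
mobile anion concentration, which the chemical-expansion law needs but which
is not part of the state, is computed from ideal Donnan equilibrium
(`mobile_anion()`); it is a swappable function. The water chemical potential
is folded together with the pore pressure into one effective pressure in the
total-stress sum — only total boundary tractions are observable, so the
split is not identifiable and carrying it separately would add state without
physics.

Material defaults (the "mature bovine" preset in `material_params()`) are
literature-plausible values for mature bovine cartilage: `E_nf` = 0.8 MPa,
`nu_nf` = 0.15, `E0` = 10 MPa, `k0` = 1.5e-15 m⁴/(N s), M = 5, 0.15 M bath
at 310 K. `E_eps` = 1 GPa was chosen so the instantaneous fibril curve
delivers the 0.5–1 GPa tissue-scale stiffness implied by drop-tower impacts
that reach ~200 MPa peak stress at strains well below unity; with a soft
`E_eps` the simulated tissue would flow unphysically under such loads. The
chemical-expansion constants use the molar-per-cubic-meter convention
(`a0` in Pa·m³/mol, `kappa` in m³/mol); a config value in the mEq/ml
convention must be divided by 1000, and the unit tags in YAML configs make
the expected dimension explicit.

## The impact stage

`impact_solve()` performs a quasi-static transient poroelastic (u–p) solve
in the soils-consolidation idiom: solid inertia is omitted and the 1-ms
half-sine load (peak 4000 N at 0.5 ms) is resolved with 50 implicit
backward-Euler steps. The mesh is an axisymmetric tensor grid of 4-node
displacement–pressure quadrilaterals, radially graded so that nodes land
exactly on the indenter radius (2.5 mm) and the band around the contact edge
is refined. Contact is simplified as the experiment suggests: the contact
area is constant, the top nodes inside the contact radius are constrained
radially, and the vertical traction is uniform over the flat face with a
cosine taper across the 1-mm fillet, normalized so the total equals the
waveform. The bottom is fixed (osteochondral junction; bone not modeled),
the axis is symmetric, free surfaces are drained, and the indenter-covered
surface and bottom are impermeable.

Equal-order Q1/Q1 interpolation is stabilized with an element-local
pressure-projection term (Bochev–Dohrmann style, applied incrementally), and
the assembled saddle-point system is Jacobi-equilibrated before LU
factorization — the pressure block is ~16 orders of magnitude below the
stiffness block and naive pivoting fails without the scaling.

Kinematics are linearized inside the solve; the damage-driving maximum shear
strain is computed in post-processing from the full deformation gradient
(Green–Lagrange tensor, `max_shear_strain()` with the `(E_I − E_III)/2`
convention; the un-halved convention is a switch). Strains are measured from
the post-swelling configuration, so the swelling pre-strain does not count
toward damage; `initial_swelling_solve()` provides that equilibrium
pre-state. Fibril tension-only behaviour and strain stiffening enter through
three damped Picard passes: each pass re-evaluates a per-element secant
tangent from the previous pass's Green–Lagrange strains, direction by
direction (the two arcade primaries weighted `C`, a fixed 13-direction
near-isotropic secondary set). Three numerical safeguards keep this
fixed-point iteration stable, and all were necessary: a smooth (logistic)
tension activation instead of a hard on/off switch, a damped update
(0.7 old + 0.3 new), and clamping of the feedback strains to [−0.25, 2.5].
The iteration is deliberately truncated rather than run to a fixed point:
with hard switching the activation pattern at the tension/compression
boundary oscillates indefinitely, and the truncated damped iteration is
deterministic and reproducible.

Mesh resolution: the default is 60×20 elements. The axial count is a
multiple of five so that the 200-µm superficial reporting zone is an integer
number of element layers on both the default and the half-resolution mesh;
otherwise the refinement comparison measures zone-sampling misalignment
rather than discretization error. The half-sine reaction force at the fixed
bottom reproduces the applied waveform to numerical precision (quasi-static
equilibrium), boundary fluid loss over the impact is far below 1% of tissue
fluid (permeability ~1e-15 m⁴/(N s) gives negligible millisecond drainage),
and the superficial-zone mean shear strain changes by under 5% between the
30×10 and 60×20 meshes.

## Cell damage

The damage function is zero below `eps_init` = 0.40 maximum shear strain,
one above `eps_max` = 1.50, and `(eps_max/eps) * (eps - eps_init) /
(eps_max - eps_init)` between — continuous at both thresholds and
nondecreasing. Damaged cells are seeded nodewise as `f_dmg * C_init` with
`C_init` = 0.5e14 cells/m³ homogeneous; the healthy/damaged/dead total is
conserved at every node for all time (no proliferation). Reporting zones are
axisymmetric annular boxes with exact 2πr-weighted averages: the
"superficial impacted" zone is the top 200 µm within r ≤ 2 mm (half the
4-mm-wide dissected impacted region), the intact reference an annulus at
8–10 mm. Whether reported scalars are zone averages or surface point values
is a reporting-mode choice; the package uses zone averages everywhere, and
the fixture is built so the two coincide under the indenter (the strain is
constant across the impacted column).

## Biokinetics

All species live on an axisymmetric finite-volume grid (default 40×20
cells). Per time step the update is operator-split:

1. implicit (backward-Euler) diffusion for the mobile species — NAC
   (Dirichlet bath value on the top and outer surfaces per the treatment
   schedule, zero flux on axis and bottom) and proteolytic enzyme (zero flux
   everywhere, the explicitly stated condition; an outflux alternative is a
   config switch away);
2. exact exponential cell-fate update with NAC frozen over the step — the
   damaged pool decays at `k_death + k_rec*C_NAC` and the death/recovery
   split is `k_death : k_rec*C_NAC` *exactly at any step size*, which is why
   the default `dt` = 60 s needs no sub-second refinement after treatment
   onset;
3. exact relaxation of the enzyme-release stimulus `dS/dt =
   alpha_aga*(k_aga*f_dmg − S)` and of first-order enzyme clearance;
4. explicit proteoglycan update (Michaelis–Menten degradation by enzyme,
   baseline turnover `−k_turn*C_PG` plus synthesis `k_turn * C_PG_init *
   viable_fraction`), whose rates live on the scale of days.

Intact tissue is at steady state by construction: full viability, no
enzyme, and synthesis exactly balancing turnover. The viable fraction
includes damaged cells — they still synthesize until dead. Proteoglycan is
immobile and degraded proteoglycan leaves the intact pool instantly;
fragment transport is not modeled because only intact content is compared
to measurements.

Parameter notes:

* `k_death` = 6.9e-5 s⁻¹ (range 4.6–13.9e-5), `k_rec` = 0.53e-4 m³/(mol s)
  (range 0.29–0.53e-4), `alpha_aga` = 0.4e-5 s⁻¹: the reference rates of the
  study conditions.
* `D_NAC` = 1.2e-10 m²/s. The literally printed value of 120e-6 m²/s is
  unphysical for a 163-Da solute — it exceeds free-water diffusivity by five
  orders of magnitude — and is read as a units slip; a `literal_reported_dnac`
  switch restores the literal number. Superficial-zone outcomes are
  insensitive to the choice because either value floods the top 200 µm in
  well under an hour (L²/D ≈ 6 min at the default).
* The Michaelis–Menten block is not fully constrained by printed values, so
  its constants are fixed once at plausible scales — `K_M` = 100 mol/m³
  (comparable to the initial proteoglycan concentration, itself computed as
  half the fixed charge density), `k_enz_clear` = 1e-5 s⁻¹ (~1-day enzyme
  lifetime), `D_enz0` = 1e-12 m²/s with `exp(-C_PG/C_PG_init)` modulation
  (large enzymes move faster through a depleted matrix), `k_turn` = 5e-8 s⁻¹
  (aggrecan half-life of months in explants, keeping enzymatic loss — not
  suppressed biosynthesis — the dominant degeneration channel) — and the
  single scalar `k_aga` is then calibrated.
* `calibrate_kaga()` bisects `k_aga` until the untreated day-14
  impacted-vs-intact relative proteoglycan content matches its target
  (0.2-percentage-point tolerance), seeding the bracket from the
  near-linearity of the deficit in `k_aga`. Treated arms are then pure
  predictions: because the stimulus equation is linear in the damaged
  fraction, total enzyme production scales with the damaged-cell exposure
  integral, so deficit ratios across arms track
  `k_death/(k_death + k_rec*C_NAC)`-type exposure ratios
  (`exposure_integral()`) — a structural relation the tests use as an
  independent check on the PDE.

`wellmixed_viability()` is the closed-form reduction used as the fast oracle
(NAC at bath concentration everywhere): death-only decay before the delay,
competing first-order death/recovery after. Its known gap to the spatial PDE
is the NAC diffusion transient through the tissue depth, worth ~1 point of
viability at 48 h on the default grid.

## The synthetic generator

`make_strain_fixture()` produces the strain fields that drive every
quantitative biology scenario: the reference preset has a constant
maximum shear strain of 0.679 across the impacted column (r ≤ 2.5 mm, all
depths) decaying as a radial Gaussian (2.5-mm half-width) beyond, so the
superficial impacted zone carries a damaged fraction of 0.56 at the
reference thresholds — the reference outcome of the impact stage. This
deliberate decoupling is anti-circular: the finite-element chain is
validated by properties (convergence, conservation, monotonicity,
equilibrium), while the biology is validated against reference numbers from
an input field that encodes only the published damage level, not any
unpublished material parameters. The generator emulates the geometry and
magnitude of an impact strain field; it does not emulate experimental noise,
confocal imaging artifacts, assay variability, or surface lesions — so
passing biology tests say nothing about those aspects of real data.
`make_depth_profile_fixture()` provides smooth monotone composition profiles
(fixed charge density 120→250 mol/m³, fluid fraction 0.85→0.70, collagen
density 0.22→0.16 from surface to deep) in physiological ranges.

## Degenerate inputs and edge behaviour

Zero peak force yields an identically zero strain field; zero fixed charge
density with equal internal/external coefficients yields zero swelling; a
compression that would collapse the pore space (`n_fl0 − 1 + J ≤ 0`) raises
an invalid-deformation error rather than producing negative fluid volume;
negative proteoglycan excursions of the explicit update are clipped at zero
with an accounted mass budget, and the run aborts if the clipped mass stops
being negligible. The damage function is exactly continuous at both
thresholds; `eps_max = eps_init` is rejected at construction.

## Problem sizes and runtimes

Defaults were chosen so the whole pipeline runs comfortably on one CPU: the
impact solve takes seconds (60×20 mesh, 50 implicit steps, 3 Picard passes),
a 48-h kinetics run about a second (40×20 grid, dt = 60 s), a 14-day
proteoglycan arm ~10 s, and the full calibration plus three treatment arms
about two minutes. The test suite exercises reduced grids for unit tests and
the full default sizes in the acceptance checks.

## Known limitations

The impact solve linearizes kinematics; at the extreme local strains near
the contact edge the reported Green–Lagrange values are post-processed, not
equilibrium finite-strain solutions, and a small suction pocket appears in
the last cells under the rounded fillet of the simplified contact (pressure
under the flat face stays strongly positive). Damage does not feed back into
material properties; inflammation, cytokine transport, the
necrosis/apoptosis split, NAC consumption and charge effects, surface
lesions and fluid leakage through cracks are all out of scope. Oxidative
stress is represented implicitly by the damaged-cell pool, not by explicit
ROS concentrations.
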