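# chondrosim

Mechanobiochemical simulation of impact-injured articular cartilage and its
antioxidant treatment, for researchers in cartilage mechanobiology and
post-traumatic osteoarthritis (PTOA) modeling.

A single high-energy impact on a cartilage explant sets off a cascade:
excessive shear strain damages chondrocytes (oxidative stress), damaged
cells die over hours to days and release proteolytic enzymes (aggrecanases)
that degrade matrix proteoglycans, and an antioxidant bath
(N-acetylcysteine, NAC) can rescue damaged cells — if it arrives early
enough. `chondrosim` implements this whole chain as composable stages:

1. **Constitutive model** — fibril-reinforced poroviscoelastic swelling
   continuum: compressible Neo-Hookean non-fibrillar matrix
   σ<sub>nf</sub> = E<sub>nf</sub>/(3(1−2ν)) · lnJ/J · **I** +
   E<sub>nf</sub>/(2(1+ν)) · (1/J)(**FF**ᵀ − J^(2/3) **I**);
   tension-only viscoelastic collagen fibrils (linear spring E₀ in parallel
   with a quadratic spring E<sub>ε</sub>ε² in series with a dashpot η);
   deformation-dependent permeability k = k₀Jᴹ; Donnan osmotic pressure
   Δπ = φ<sub>int</sub>RT √(c²<sub>FCD</sub> + 4(γ±<sub>ext</sub>/γ±<sub>int</sub>)²c²<sub>ext</sub>) − 2φ<sub>ext</sub>RT c<sub>ext</sub>;
   chemical-expansion stress T<sub>c</sub> = a₀c<sub>FCD</sub> exp(−κ(γ±<sub>ext</sub>/γ±<sub>int</sub>)√(c⁻(c⁻+c<sub>FCD</sub>))).
2. **Impact solver** — axisymmetric transient poroelastic (u–p) finite
   elements; a 4000 N half-sine force over 1 ms applied through a rigid
   5-mm indenter; maximum shear strain γ<sub>max</sub> = (E_I − E_III)/2 from the
   Green–Lagrange tensor at peak force.
3. **Cell damage** — a strain-thresholded damage function: no damage below
   40% shear strain, complete damage above 150%, with
   f(ε) = (ε<sub>max</sub>/ε)·(ε − ε<sub>init</sub>)/(ε<sub>max</sub> − ε<sub>init</sub>) between.
4. **Biokinetics** — reaction–diffusion of healthy/damaged/dead cells
   (death rate k<sub>death</sub> = 6.9·10⁻⁵ s⁻¹, NAC protection rate
   k<sub>rec</sub> = 0.53·10⁻⁴ m³mol⁻¹s⁻¹), an enzyme-release stimulus
   dS/dt = α(k<sub>aga</sub>f<sub>dmg</sub> − S), Michaelis–Menten proteoglycan
   degradation, and diffusive NAC with a configurable treatment delay.
5. **Scenarios** — untreated viability time courses, treatment-delay and
   protection-rate sweeps, impact-force sweeps, day-7/14 proteoglycan
   outcomes, and a comparison table against the reference experimental
   endpoints.

## Worked example

```r
library(chondrosim)

field <- make_strain_fixture()    # peak-impact strain field (reference preset)
field
#> Strain field: 800 points, r in [0.156, 12.3] mm, depth in [0.025, 0.975] mm
#>   gamma_max: max 0.679, mean 0.28; pore pressure max 0 MPa
#>   extracted at t = 0.5 ms

run_delay_sweep(field)            # 48-h viability vs NAC treatment delay
#>  delay_h viability
#>        0    0.7791
#>        1    0.7044
#>        4    0.5653
#>       12    0.4569
```

The strain plateau of 0.679 under the indenter damages 56% of superficial
cells. With an immediate 2 mM NAC bath, 78% of all cells are still alive two
days later; delaying the same treatment by 12 h drops that to 46% — the
recovery reaction k<sub>rec</sub>·C<sub>NAC</sub>·C<sub>dmg</sub> loses its substrate as damaged
cells die at k<sub>death</sub>. `comparison_table()` tabulates all eleven tracked
scalars (nine viability percentages, two proteoglycan deficits) against the
reference outcomes; the current build agrees to within 1.6 percentage points
everywhere.

The full chain from the finite-element impact onward:

```r
fld <- impact_solve(mesh_spec(), load_spec(F_peak = 4000))  # ~10 s
cells <- seed_cell_field(fld$gamma_max)
res <- simulate_kinetics(species_state(kinetics_grid(), fld),
                         kinetics_params(),
                         treatment_schedule(delay = 4 * 3600),
                         t_end = 48 * 3600)
summary(res)
```

A thin CLI wraps the same functions
(`inst/exec/chondrosim {impact,kinetics,reproduce,sweep,fixture}`).

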