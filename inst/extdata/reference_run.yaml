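# Reference ("mature bovine") run configuration. Every value shown here
# equals the package preset; any entry may be overridden, either as a plain
# SI number or as a "value unit" string.
material:
  E_nf: "0.8 MPa"        # non-fibrillar matrix modulus
  nu_nf: 0.15
  E0: "10 MPa"           # initial fibril network modulus
  E_eps: "1000 MPa"      # strain-dependent fibril network modulus
  eta: "1000 MPa.s"      # fibril damping coefficient
  C: 3.0                 # primary/secondary fibril stress ratio
  k0: 1.5e-15            # m4/Ns, initial permeability
  M: 5                   # permeability strain-dependence exponent
  c_ext: "0.15 M"        # external NaCl bath
  T: 310
load:
  F_peak: "4 kN"
  t_impact: "1 ms"
  indenter_radius: "2.5 mm"
  fillet: "1 mm"
mesh:
  nr: 60
  nz: 20
thresholds:
  eps_init: 0.40         # damage-initiation max shear strain
  eps_max: 1.50          # full-damage threshold
kinetics:
  k_death: "6.9e-5 1/s"  # damaged-to-dead rate
  k_rec: 0.53e-4         # m3/mol/s, NAC protection rate
  alpha_aga: "0.4e-5 1/s"
  D_NAC: 1.2e-10         # m2/s
schedule:
  delay: "0 h"
  bath_concentration: "2 mM"
  duration: "1 d"
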