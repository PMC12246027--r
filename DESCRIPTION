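Package: chondrosim
Title: Mechanobiochemical Simulation of Impact-Injured Articular Cartilage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates the response of articular cartilage to a drop-tower
    impact and the biological cascade that follows. A fibril-reinforced
    poroviscoelastic swelling constitutive model with Donnan osmotic pressure
    and chemical expansion drives an axisymmetric transient poroelastic
    finite-element solve of a 1-ms half-sine indenter impact; the peak
    maximum-shear-strain field seeds a strain-thresholded cell-damage field;
    reaction-diffusion kinetics then evolve healthy, damaged and dead
    chondrocytes, proteolytic-enzyme release, Michaelis-Menten proteoglycan
    degradation, and diffusive N-acetylcysteine (antioxidant) treatment with a
    configurable delay. Scenario runners reproduce untreated viability time
    courses, treatment-delay and protection-rate sweeps, and day-7/14
    proteoglycan outcomes, with a well-mixed analytic reduction available as a
    fast oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
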