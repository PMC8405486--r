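Package: cnspbpk
Title: Physiologically Based Pharmacokinetic Simulation of Drug
    Distribution in Brain and Cerebrospinal Fluid
Version: 0.1.0
Authors@R:
    person("CNS PBPK", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Simulates unbound drug concentration-time profiles in nine
    compartments of the central nervous system (brain microvessels, brain
    extracellular and intracellular fluid, lysosomes, brain cell membrane,
    and four cerebrospinal fluid spaces) driven by an empirical compartmental
    plasma model.  Passive transport is split into transcellular and
    paracellular routes, with ionization handled by Henderson-Hasselbalch
    neutral fractions per compartment, non-specific binding to membrane
    phospholipids via octanol-water partitioning, and active transport lumped
    into asymmetry factors calibrated against unbound partition coefficients
    (Kp_uu) at steady state.  Includes replicate-simulation machinery for
    visual predictive checks, fold-error evaluation statistics, a parameter
    sensitivity analysis, and an altered-CSF-dynamics scenario study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    Matrix,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
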