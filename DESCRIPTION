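Package: poroplant
Title: Poroelastic Simulation of Wound-Induced Hydromechanical Signaling in Plants
Version: 0.1.0
Authors@R:
    person("Plant Hydraulics", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Finite-volume simulators for the coupled poroelastic dynamics
    triggered by wounding in vascular plants: fast pressure diffusion along
    the xylem, slow turgor relaxation of the surrounding tissue, the mass
    flows these transients drive, advection-diffusion of chemical elicitors
    in the xylem stream, wound-induced leaf swelling kinetics, and radial
    propagation of local signals by molecular versus poroelastic diffusion.
    Ships fully parameterized presets for small herbaceous plants
    (Arabidopsis-scale) and cereal seedlings (wheat-scale), analytic oracles
    for solver verification, and CSV/JSON run artifacts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    rlang,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
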