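Package: petflow
Title: Coupled Microvascular Flow and PET Tracer Transport in Solid Tumors
Version: 0.1.0
Authors@R:
    person("petflow", "developers", email = "petflow@example.org", role = c("aut", "cre"))
Description: Simulates the spatiotemporal distribution of a PET radiotracer
    (FDG) in vascularized tumor and normal tissue. A capillary network is
    obtained either from a colour micrograph (green-channel extraction, CLAHE,
    thresholding, skeletonization to a centerline graph) or from a seeded
    synthetic generator. Steady intravascular Poiseuille flow on the network is
    coupled to interstitial Darcy flow through Starling transvascular
    filtration and lymphatic drainage, yielding interstitial fluid pressure and
    velocity fields. A three-compartment convection-diffusion-reaction system
    (free extracellular, intracellular, and phosphorylated tracer) driven by an
    arterial input function is then integrated on the steady flow field.
    Includes closed-form oracles (well-mixed kinetics, radial Bessel pressure
    profile), region/probe reporting, mesh-convergence studies, and a command
    line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    jsonlite,
    png,
    stats,
    utils,
    tools,
    grDevices,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
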