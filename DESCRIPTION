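Package: memprobe
Title: Membrane Probe Trajectory Analysis and Free-Energy Post-Processing
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for molecular-dynamics-style trajectories of
    fluorescent fatty-acid probes in lipid bilayers. Provides structural
    descriptors (area per lipid, phosphate-plane thickness, deuterium order
    parameters, chain tilt distributions, transverse positions, mass density
    profiles), proximity-conditioned tilt statistics around probe molecules,
    atom-atom radial distribution functions with cumulative coordination
    numbers, rotational autocorrelation analysis with multiexponential
    hindered-rotation fitting and limiting-anisotropy estimation, lateral
    mean squared displacement and diffusion coefficients with leaflet
    centre-of-mass correction, and 1-D weighted-histogram (WHAM)
    reconstruction of umbrella-sampling free-energy profiles with barrier
    decomposition and membrane partition-coefficient estimation. Synthetic
    trajectory, hindered-rotor, lateral-walk and umbrella-window generators
    with known ground truth make every analysis stage testable without
    molecular dynamics engines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
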