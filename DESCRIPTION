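Package: canopyflow
Title: Two-Way Coupled Canopy-Airflow Simulation and Dynamic Stratified Porosity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates assisted (sprayer-driven) airflow through a procedurally
    generated 3D cotton plant and measures the resulting dynamic stratified
    canopy porosity. The fluid is solved with a uniform-grid D3Q27
    lattice-Boltzmann BGK method closed by a WALE large-eddy eddy viscosity;
    leaves, petioles and branches are thin elastic shells advanced by an
    explicit central-difference integrator; the two are coupled two-way by a
    direct-forcing immersed boundary. A post-processing image pipeline renders
    orthographic canopy projections, binarizes them, and computes per-layer
    windward area, outer-contour area and porosity over time and over canopy
    relative height, together with probe, error-metric and regression
    utilities for validation against anemometer measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    EBImage,
    grDevices,
    stats,
    utils,
    yaml,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
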