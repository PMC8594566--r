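Package: senkflow
Title: Stochastic Ensemble Kalman Filtering for Voxel-Based Flow Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data assimilation for pulsatile and turbulent incompressible
    flow. A second-order staggered-grid (MAC) Navier-Stokes projection
    solver with fringe forcing serves as the forward model of a stochastic
    ensemble Kalman filter whose ensemble is built from successive pulses
    (phase averaging). Coarse voxel-based observations (per-voxel mean
    velocity and covariance, as produced by 4D flow MRI or tomographic PIV)
    are mapped onto the computational grid through a node-counting
    observation operator, and a per-voxel block Kalman gain updates the
    forecast, yielding enhanced flow fields on the finer grid. Includes
    twin-experiment factories (confined cylinder at Re = 150, turbulent
    channel at Re = 5000, synthetic pulsatile jet), running D-regularized
    phase statistics, and wall/turbulence diagnostics (friction Reynolds
    number, wall units, turbulent kinetic energy, Reynolds-stress profiles).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
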