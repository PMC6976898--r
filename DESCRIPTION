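Package: palight
Title: Monte Carlo Light Delivery Simulation for Photoacoustic Probes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel Monte Carlo simulation of light delivery for combined
    ultrasound/photoacoustic probes that pair a linear transducer array with
    external fiber-bundle illumination. Builds layered skin-over-bulk tissue
    volumes from a bundled optical-property database, transports photon packets
    with Henyey-Greenstein scattering and a track-length fluence estimator,
    and reduces the fluence maps to the quantities that drive probe design:
    imaging-plane depth profiles, peak fluence over emission-angle and
    fiber-offset sweeps, mouse-to-human maximum-fluence ratios, and a kernel
    signal-to-noise convergence score. Includes a milk-over-gelatin phantom
    pipeline with a synthetic graphite-rod scan generator and the
    ultrasound-based normalization used to compare model and experiment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
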