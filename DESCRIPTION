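Package: batnight
Title: Diffusion and Shrinking-Domain Models of Nightly Bat Movement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the nightly movement of roosting bats from
    irregular radio-tracking detections. Computes mean squared displacement
    (MSD) curves with standard-error ribbons from interpolated tracks, solves
    radially symmetric diffusion and convection-diffusion equations on a disk
    (including non-autonomous coefficients and an apically shrinking domain
    that encodes a "leap frog" return mechanism), fits piecewise
    linear-quadratic MSD models with derived ecological parameters (diffusion
    rate, flight speed, departure delay, core sustenance zone radius), and
    compares candidate return mechanisms through within-radius return curves.
    Includes seeded agent-based generators of synthetic bat-night trajectories
    and of irregular detection records for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
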