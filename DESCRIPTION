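Package: phagedrop
Title: Label-Free Analysis of Bacteria-Phage Dynamics in Anchored Microdroplets
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for time-lapse analysis of two-species bacterial
    co-cultures and lytic phage infection inside anchored water-in-oil
    microdroplets. Implements droplet encapsulation arithmetic (ellipsoid
    volumes, Poisson occupancy, OD600 to CFU calibration, multiplicity of
    infection), a classification-score autofocus feedback controller with
    Hough-transform droplet re-centering, a Z-stack detection counting
    pipeline (confidence filtering, exclusion-sphere deduplication,
    majority-vote species assignment, static false-positive removal,
    moving-average smoothing), growth and lysis kinetics extraction
    (sliding-window specific growth rates, doubling times, one-step growth
    curve burst size and latent period), and a stochastic agent-based
    simulator of growing, aggregating and lysing cells that emits the
    detection streams the pipeline consumes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
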