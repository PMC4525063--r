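Package: spinewell
Title: Coupled Lumbar-Spine Muscle and Intervertebral Disk Simulator
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale quasi-static simulator of the lower lumbar spine
    (L3-S1) coupling a stretch-activated Hill-type transversely isotropic
    hyperelastic muscle law, a 46-fascicle back-muscle network, distributed
    body-weight gravity loading, and one-dimensional osmo-poroelastic
    intervertebral disk columns with strain-dependent permeability.
    Simulates relaxed standing, overnight rest (free disk swelling), and
    rest-then-standing scenarios, and reports per-fascicle strains,
    activations and forces together with intradiscal pressure at the
    nucleus pulposus center.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
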