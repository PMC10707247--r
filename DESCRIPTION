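Package: earmech
Title: Frequency-Domain Mechanical Simulation of the Human Middle Ear
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Harmonic (frequency-domain) simulation of sound transmission
    through the human ossicular chain using a reduced anatomical element
    network. Ships a calibrated normal-ear configuration, a composable
    pathology layer for ossicular malformations (incudostapedial cord
    replacement, stapedial annular ligament stiffening, suspensory ligament
    fixation and ossification, viscoelastic monopodal stapes), an audiology
    layer converting stapes-footplate volume velocity into simulated
    conductive hearing-loss curves (pure-tone average, air-bone gap, slope
    classification), scenario ranking against measured audiograms, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
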