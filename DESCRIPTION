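Package: qcmdfusion
Title: QCM-D Analysis of Vesicle Fusion and Supported Lipid Bilayer Formation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing quartz crystal microbalance with dissipation
    monitoring (QCM-D) experiments that track the transition of adsorbed lipid
    vesicles into supported lipid bilayers (SLBs). Provides closed-form film
    physics (Sauerbrey mass and thickness, rigid and viscoelastic film
    responses, acoustic decay length), a documented CSV dialect for
    multi-overtone frequency/dissipation traces with baseline correction and
    overtone normalization, extraction of the standard trace features (time of
    adsorption, frequency minimum, dissipation maximum, rupture time and
    asymptotes), deformed-vesicle height by multi-overtone extrapolation of
    the dissipation-to-frequency ratio, apparent adsorption and rupture rates,
    outcome classification (complete SLB, partial SLB, supported vesicle
    layer), buffer osmolarity comparison for osmotic-stress experiment design,
    and a seeded kinetic simulator of vesicle adsorption, critical-coverage
    rupture and bilayer spreading that reproduces the characteristic
    multi-overtone fingerprints of each outcome.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
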