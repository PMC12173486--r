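Package: tendonwave
Title: Shear Wave Tensiometry Simulation in Twisted Achilles Subtendons
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to study how helical subtendon twist and differential
    triceps-surae loading modulate transverse (shear) wave propagation in
    the free Achilles tendon.  The package generates tapered elliptical
    three-subtendon hexahedral butterfly meshes with helically wound fibre
    directions, builds gait-cycle loading cohorts with prescribed
    gastrocnemius/soleus stress ratios, simulates transient shear waves
    with a reduced-order model of three coupled tensioned beams, measures
    wave speeds from spatiotemporal displacement maps by directional
    filtering and a Radon transform with Gaussian peak fitting, and fits
    the tensioned-beam relationship between axial stress and squared wave
    speed to recover effective density.  Full-fidelity finite element
    models can be exported as FEBio XML input files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xml2
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
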