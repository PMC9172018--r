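Package: SiOTamponade
Title: Silicone-Oil Tamponade Statics and Saccadic Shear in Parametric Vitreous Chambers
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale model of silicone-oil (SiO) tamponade behaviour in
    emmetropic and highly myopic (posterior staphyloma, with or without an
    encircling scleral band) vitreous chambers. Builds watertight parametric
    chamber meshes, segments the wall into clinically meaningful retinal
    regions, computes the static oil-aqueous equilibrium by volume-conserving
    threshold dynamics with gravity and contact-angle wetting, reports
    per-region SiO-retina contact fractions as a function of fill and posture,
    generates saccadic kinematics, and summarises wall shear stress during a
    saccade with a reduced-order boundary-layer model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, yaml
Suggests: testthat (>= 3.0.0), jsonlite, ggplot2, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
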