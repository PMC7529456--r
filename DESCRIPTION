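Package: cordclose
Title: Biomechanics of Umbilical Artery Closure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Continuum-mechanical model of perinatal umbilical artery
    occlusion. The arterial wall is treated as a thick-walled, bilayered,
    incompressible cylinder with a swollen glycosaminoglycan-rich inner
    layer (neo-Hookean) and a contractile smooth-muscle-rich outer layer
    (neo-Hookean matrix plus four exponential fiber families and a
    parabolic active-tone law). Provides finite-deformation equilibrium
    solutions under luminal pressure, axial stretch, inner-layer swelling
    and smooth-muscle active stress; closure curves of inner radius versus
    active stress; linear (incremental) stability analysis for inward
    circumferential buckling of the inner layer; nonlinear regression of
    passive biaxial pressure-diameter and axial-force data; calibration of
    active-tone magnitude from contraction data; and a synthetic biaxial
    data generator emulating murine ex vivo protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    minpack.lm,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
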