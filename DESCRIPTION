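Package: activemuscle
Title: Hyperelastic Constitutive Models for Active Skeletal Muscle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements and cross-compares four transversely isotropic
    hyperelastic constitutive models for active skeletal muscle tissue: an
    active-stress model (ASE), a generalized active-strain model (GASA), an
    active-strain model (ASA), and a modified generalized active-strain model
    (GASAM). Provides the kinematics of the standard homogeneous load cases
    (uniaxial tension/compression, simple shear, pure shear, along and
    transverse to the fiber direction), force-stretch and time-dependent
    activation functions (tanh ramp and motor-unit twitch superposition),
    explicit (Lambert W), implicit (Newton), and closed-form solvers for the
    activation level, analytic incompressible and nearly incompressible
    nominal stress-stretch responses, staged passive/active parameter
    identification by bounded least squares, and a synthetic stress-stretch
    curve generator for testing fitting pipelines.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    pracma,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
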