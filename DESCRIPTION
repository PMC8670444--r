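Package: frictouch
Title: Fingertip Contact Mechanics and Friction Perception at Initial Touch
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how friction shapes fingertip skin deformation
    at the first instant of contact. Provides an axisymmetric spring-damper
    (Kelvin-Voigt) fingertip model with elastoplastic Coulomb friction, a
    hemisphere-flattening geometric strain model, displacement-field analytics
    (gridding of tracked features, mean divergence, Helmholtz decomposition,
    strain and strain-energy summaries), a contact-image processing chain
    (illumination correction, Otsu real-contact-area measurement, fingerprint
    feature tracking, force-signal conditioning), two-alternative forced-choice
    psychometric fitting with 75 percent threshold extraction, and a fully
    seeded synthetic-data generator with attached ground truth so every stage
    is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    Matrix,
    signal,
    stats,
    grDevices,
    tiff,
    utils,
    yaml
Suggests:
    EBImage,
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
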