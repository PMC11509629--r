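Package: afmblunt
Title: Contact Models and Young's Modulus Estimation for AFM Indentation
    with Blunted Tips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing atomic force microscopy (AFM)
    force-indentation curves acquired with blunted (sphero-conical and
    blunted-pyramidal) indenters. Implements the exact piecewise contact
    models (Hertzian spherical cap below the cap-cone transition, blunted
    cone or pyramid above it), a simplified power-law estimator that maps a
    fitted force-indentation power law directly to the Young's modulus at
    shallow depth (h < 3R), a depth-corrected spherical model, a large-depth
    approximation (h > 3R), classic one-parameter model fits, an automatic
    method selector, a synthetic force-curve simulator with Gaussian noise,
    plain-text curve input/output, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
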