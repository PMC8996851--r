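Package: hadrondose
Title: Biological Dose and RBE Calculation for Ion-Beam Therapy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxelized biological-dose engine for hadrontherapy dosimetry.
    Implements an amorphous-track (Kiefer-Chatterjee) microdosimetry engine
    that produces linear-quadratic survival coefficients for monoenergetic
    ions via the modified microdosimetric kinetic model (mMKM), ASCII
    databases of alpha/beta coefficients per ion species with linear
    interpolation, a synthetic one-dimensional carbon-beam generator for a
    water phantom, spread-out Bragg peak construction by non-negative least
    squares, and per-voxel accumulation of mixed-field survival coefficients
    (Kanai dose-fraction weighting) yielding physical dose, cell survival,
    RBE-weighted biological dose and RBE.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    pracma
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
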