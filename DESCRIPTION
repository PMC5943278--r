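Package: serialfiber
Title: Serial Femtosecond Fiber Diffraction Simulation and Reduction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for single-shot X-ray fiber diffraction from helical
    filaments at free-electron lasers: a Cochran-Crick-Vand layer-line
    simulator for helices and cross-beta amyloid protofibrils with Poisson
    photon noise and detector background; photon-statistics frame
    classification (beam-off / sample-free / hit) and average-background
    construction; per-frame orientation (in-plane rotation and fiber tilt)
    estimation; mapping onto a signed cylindrical reciprocal (R, Z) grid with
    scaling, merging, four-quadrant symmetrization and circularly symmetric
    background subtraction; and layer-line analysis (axial repeat from
    layer-line spacing, equatorial band profiles, peak tables, left/right
    asymmetry). Frames are read and written in CXI-style HDF5.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rhdf5,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
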