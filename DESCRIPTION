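Package: tiettd
Title: Label-Free Protein Concentration and Cell Volume from Brightfield
    Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phase imaging and dye-exclusion volumetry for
    label-free measurement of intracellular protein concentration, water
    content and dry mass in adherent cells. Recovers a relative phase map
    from a pair of mutually defocused brightfield transmission images by
    solving the transport-of-intensity equation (TIE) with a spectral
    inverse Laplacian, converts transmission-through-dye (TTD) images into
    thickness maps and cell volumes via the Beer-Lambert law, calibrates
    the phase channel against silica beads in refractive-index oils and
    the dye channel against a half-ball lens, and fuses both channels into
    per-cell protein concentration (g/ml), water fraction and dry mass
    (pg). Includes a synthetic-data generator (phase phantoms, forward
    defocus model, dye-exclusion and half-ball absorption images) used as
    the testing oracle, plus TIFF/CSV/JSON input-output and a batch driver
    for multi-ROI processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
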