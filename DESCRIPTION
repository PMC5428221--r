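Package: rossfilter
Title: Ross Filter Pair Design and Quasi-Monochromatic Elemental X-Ray Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design of balanced (Ross) filter pairs for polychromatic X-ray
    sources and an end-to-end simulator for quasi-monochromatic elemental
    contrast imaging.  Includes an embedded X-ray attenuation database with
    K-edge discontinuities, a tungsten-anode bremsstrahlung spectrum model,
    Beer-Lambert forward radiography of 2D foil and 3D foam phantoms with
    Poisson noise, the band-subtraction pipeline that isolates the narrow
    energy window between the K-edges of a filter pair, parallel-beam
    filtered back-projection tomography, and contrast quality metrics
    (signal-to-noise ratio, residue and overlap errors).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    tiff,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
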