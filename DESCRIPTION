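Package: ivusseg
Title: Automatic Lumen and Media-Adventitia Segmentation of Intravascular
    Ultrasound Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Automatic detection of the lumen and media-adventitia borders in
    single-frame intravascular ultrasound (IVUS) cross-sections. The method
    decomposes the image with a contourlet transform (Laplacian pyramid plus
    directional filter bank), initializes both borders as circles found by a
    multiresolution circular Hough transform on the low-pass bands, despeckles
    the band-pass directional subbands with Perona-Malik anisotropic
    diffusion, and evolves two reinitialization-free variational level sets to
    the final contours. A polar-domain IVUS phantom simulator with Rayleigh
    speckle, ring-down and guide-wire artifacts provides ground truth for
    validation, and mean distance (MD) / relative mean distance (RMD) contour
    metrics quantify accuracy.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    EBImage,
    jsonlite,
    png,
    tiff,
    stats,
    grDevices,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
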