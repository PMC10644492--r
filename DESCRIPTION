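Package: spikescan
Title: Quantifying Architecture of Two-Ranked Grass Inflorescences from Scanner Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An imaging pipeline for flatbed-scanner RGB images of unilateral
    (two-ranked) grass spikes such as perennial ryegrass. Detects and enumerates
    spikes on a dark background by channel thresholding or scaled Otsu
    thresholding, estimates spike length by four methods (moment ellipse, convex
    hull, Zhang-Suen skeleton, medial axis), splits spikes into spikelets with a
    distance-transform watershed, and extracts geometric, elliptical-Fourier and
    multi-color-space descriptors, plus latent-trait utilities (standardized
    principal components, pairwise-distance separability, feature filtering).
    Includes a synthetic scene generator with exact ground truth so every stage
    is verifiable without external data, a batch driver, and parameter-sweep
    tools.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    jsonlite,
    caret,
    stats,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
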