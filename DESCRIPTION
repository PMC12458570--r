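Package: otomif
Title: Most-Informative-Frame Selection for Otoscopy Videos
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores every frame of an otoscopy video on three axes of
    diagnostic utility -- eardrum visibility (expected eardrum-area score from
    a 3-class view classifier), eardrum coverage (weakly supervised
    segmentation via class activation maps refined by adversarial climbing
    and background subtraction), and image clarity (a Gaussian-mixture model
    of the edge-energy distribution combined with field-of-view-centred focus
    assessment) -- and fuses the three scores by weighted rank into a single
    informative score used to extract the most informative frames. Includes a
    synthetic otoscope-frame generator with full ground truth, a compact
    convolutional classifier with the gradient plumbing the activation-map
    methods require, segmentation evaluation metrics, and an end-to-end
    pipeline with a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    pROC,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
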