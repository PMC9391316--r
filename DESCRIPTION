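Package: particleprint
Title: Morphological Fingerprinting of Subvisible Particle Image Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for classifying and fingerprinting populations of grayscale
    subvisible-particle images such as those produced by backgrounded membrane
    imaging (BMI). Includes a synthetic particle-image generator with
    controllable morphology, 32x32 pre-processing (centered padding/cropping and
    training-set normalization), a small convolutional network trained either as
    a weighted cross-entropy classifier or as a two-dimensional metric embedding
    with the batch-all non-zero triplet loss, bivariate Gaussian kernel density
    "fingerprints" with an unconstrained plug-in bandwidth matrix, highest
    density region contours, and Rosenblatt-transform Kolmogorov-Smirnov
    goodness-of-fit testing with a subset rejection-rate procedure.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
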