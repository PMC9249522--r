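Package: spicnet
Title: Recognition of Pulmonary Nodule Spiculation in CT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for recognising the spiculation sign of
    pulmonary nodules in chest CT. Nodule-centred regions are segmented by
    morphological component analysis (sparse cartoon/texture decomposition
    over an undecimated wavelet frame and a local discrete cosine dictionary)
    refined by a two-pass marker watershed; tri-planar maximum-intensity
    projections summarise local 3D structure; nodule boundaries are unfolded
    into polar pseudo-time series whose protuberant excursions are scored by
    dynamic time warping against a reference database or classified by a
    semi-supervised generative adversarial network with manifold
    regularisation and a feature-matching generator loss. Includes a synthetic
    CT nodule phantom generator, overlap/detection/classification metrics,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    RNifti,
    jsonlite,
    png,
    tiff,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
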