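Package: semmae
Title: Masked Autoencoder Pre-Training and Instance Segmentation for Serial-Section Electron Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Self-supervised pre-training of vision-transformer encoders on 3D serial-section
    electron microscopy (EM) volumes with a masked autoencoder (anisotropic 1x16x16 patch
    tokenization, random / space-only / section-only mask sampling, visible-token encoder and
    lightweight decoder trained with per-patch-normalized masked mean-squared error), and a
    downstream UNETR-style instance-segmentation pipeline: affinity-map or
    binary/contour/distance (BCD) targets, watershed-based instance decoding, and evaluation by
    variation of information, adapted Rand error, and instance average precision. Includes a
    synthetic EM-volume generator so the full pipeline runs at desk scale on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
SystemRequirements: libhdf5
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
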