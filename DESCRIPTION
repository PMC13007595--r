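Package: cineRadStab
Title: Noise Stability of Dynamic Radiomic Feature Curves in Cine Cardiac Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies how stable radiomic feature curves - the trajectory of a
    radiomic feature across the frames of a cardiac cycle - are under image
    noise. Provides a seeded contracting-annulus cine phantom generator with
    configurable Gaussian noise levels and replicates, a self-contained 2D
    radiomic feature engine (first-order, grey level co-occurrence matrix and
    grey level size zone matrix families on raw, Haar-wavelet and local binary
    pattern filtered images), reference-anchored curve normalization, stability
    scoring by mean pairwise mean absolute error (overall and within noise
    level), per-subject feature rankings with a median-rank consensus, subject
    consistency via Spearman correlation, and a per-feature decision-tree
    validation of the stability-accuracy link.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    rpart,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
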