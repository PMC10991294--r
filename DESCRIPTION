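Package: lesionscape
Title: Lesion-Centric Spatial and Single-Cell Transcriptomics Analysis
Version: 0.1.0
Authors@R: person("Maintainer", "Packaged", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing focal brain lesions with spatial and
    single-cell transcriptomics. Provides concentric-ring binning of array
    spots around an annotated lesion core, template-model screening of radial
    gene and gene-set expression gradients, quality control, normalisation,
    highly variable gene selection and graph clustering for both modalities,
    marker ranking with the overestimated-variance t test, Wald condition
    contrasts, exclusive set intersections for shared-signature derivation,
    hypergeometric over-representation, control-binned gene-set scoring,
    probabilistic cell-to-spot mapping with nuclei-count deconvolution, and
    seeded negative-binomial simulators of both modalities with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
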