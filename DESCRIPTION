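Package: plaquescape
Title: Spatial Neighbourhood and Subregion Analysis of Plaque Spatial Transcriptomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing imaging-based single-cell spatial
    transcriptomics of atherosclerotic carotid plaques. Implements
    segmentation-candidate selection from assignment-confidence densities,
    transcript and cell quality control with area normalisation, polygon-based
    tissue subregion assignment and noise-transcript accounting,
    composition-based morphological clustering of samples, radius-based cell
    neighbourhood matrices with Leiden clustering and a permutation
    neighbourhood-enrichment test (Monte-Carlo p-values with Agresti-Coull
    intervals and Benjamini-Hochberg correction), local bivariate Moran's I and
    local Getis-Ord hotspot statistics with conditional permutation inference,
    and macrophage layering analysis along normalised lumen distance. A
    synthetic plaque-tissue generator with planted spatial architecture makes
    the full pipeline testable without access to any sequencing run.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
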