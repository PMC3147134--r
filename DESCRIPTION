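Package: maadose
Title: Quantitative MAA SPECT/CT Volumetry and Y-90 Microsphere Dosimetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative Tc-99m macroaggregated-albumin (MAA)
    SPECT/CT treatment planning of Y-90 microsphere radioembolization.
    Provides a synthetic phantom laboratory (Jaszczak-style cylinders with
    hot spheres and a clinical-like liver/tumor activity distribution, with
    Gaussian point-spread blurring and Poisson counting noise), isocontour
    threshold volume-of-interest segmentation with anatomically guided and
    hot-spot-only threshold fitting, phantom validation statistics (percent
    error, stratified summaries, Bland-Altman limits of agreement with Lin's
    concordance), and the MIRD-based partition dosimetry model used to plan
    injected activity and compute tumor and healthy-liver absorbed doses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
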