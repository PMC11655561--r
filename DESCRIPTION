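Package: engramap
Title: Micro-Topographic Mapping and Statistics for Activated-Neuron
    Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for micro-topographic analysis of activated-neuron
    coordinates in a traced brain region such as the lateral amygdala:
    binning of per-animal (x, y) neuron positions into a common matrix,
    group density and coefficient-of-variance maps, mass-univariate
    per-bin ANOVA with Benjamini-Hochberg false discovery rate control,
    planned-comparison classification of significant bins, and the
    accompanying behavioral statistics for fear-conditioning freezing
    data (inclusion filtering, mixed repeated-measures ANOVA, Tukey HSD,
    noncentral-F power and sample-size computation). A synthetic-data
    module simulates neuron point patterns with localized hotspots and
    freezing cohorts with known ground truth, so the full pipeline runs
    and calibrates without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
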