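Package: sfdihist
Title: Predicting Histological Tissue Fractions from Wide-Field Light-Scattering Maps
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links wide-field light-scattering parameter maps (reduced scattering
    coefficient, phase-function parameter gamma, and scatter power B, as produced
    by spatial frequency domain imaging) to stromal, epithelial, and adipose
    volume fractions quantified from digitized H&E histology slides. Provides
    H&E color deconvolution and saturation-based stain labelling, voxelized
    volume-fraction maps, logistic and Gaussian fraction-versus-property curve
    fitting with prediction intervals, leave-one-out cross-validated fraction
    prediction, threshold-based malignant/benign/fat classification with soft
    classification maps, performance metrics with exact Clopper-Pearson binomial
    confidence intervals, and a synthetic-data generator emulating a 31-specimen
    breast-tissue cohort so the whole pipeline is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
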