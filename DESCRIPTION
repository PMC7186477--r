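Package: dcehabitat
Title: Intratumoral Habitat Radiomics for Breast DCE-MRI
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Habitat-based texture analysis of dynamic contrast-enhanced
    breast MRI. Segments a lesion on subtraction images with spatial fuzzy
    C-means, partitions it into rapid/medium/slow kinetic subregions by
    per-pixel time-to-peak of relative enhancement, extracts a 488-feature
    texture bank (histogram, gray-level co-occurrence, gray-level run-length,
    and discrete wavelet transform features), and classifies binary tumor
    status with fold-wise feature selection (PCA, LASSO, stepwise) and a
    linear support vector machine under leave-one-out cross-validation.
    Includes a synthetic DCE-MRI phantom generator with known lesion masks,
    habitat structure and class effects, plus ROC/DeLong, chi-square/Fisher
    and ICC evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
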