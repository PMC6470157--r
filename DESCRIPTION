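Package: esomech
Title: Ex Vivo Esophageal Tissue Mechanics and Expression Panel Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stepwise strain-cycle organ-bath recordings of
    ex vivo esophageal tissue strips: power-law stiffness fitting of
    tension-strain curves, stiffness and compliance evaluation, decomposition of
    smooth-muscle and extracellular-matrix contributions by cycle subtraction,
    and quantification of contractile-agonist responses. Includes a forward
    constitutive model of a tissue strip (additive extracellular-matrix and
    active-muscle elements with pharmacological activation and step-relaxation
    kinetics) that simulates the force-transducer traces the analysis consumes,
    and a paired-sample statistical workflow for a 96-gene expression panel
    (call-rate filtering, Ward clustering, principal components, paired t-tests
    with Benjamini-Hochberg adjustment, and fold-change set logic).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
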