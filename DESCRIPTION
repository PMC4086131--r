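Package: varmod
Title: Sequence- and Structure-Based Prediction of Functional Missense Variants
Version: 0.1.0
Authors@R:
    person("VarMod", "Maintainers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts whether a non-synonymous protein variant alters protein
    function by combining sequence features (Jensen-Shannon divergence
    conservation, amino-acid mass ratio, charge-group and functional-group
    change) with structural features (distance to ligand-binding and
    protein-protein interface sites, Kabsch-Sander secondary structure,
    Shrake-Rupley solvent accessibility). Features are classified by an
    ensemble of five Platt-calibrated linear-margin classifiers trained with
    protein-grouped five-fold cross-validation and combined by
    validation-accuracy weighting. Includes a synthetic fixture generator so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
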