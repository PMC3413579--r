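Package: linkenhance
Title: Enhanced Death Reporting from Linked Administrative Health Records
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for enhancing the reporting of deaths in a population
    group that is under-reported on death registrations, using evidence
    from linked administrative health records. Implements the derivation
    of independent "units of information" from linked hospital, emergency
    department and birth records (including collapsing transfer-linked
    hospital episodes into stays and mother/father-to-infant status
    inheritance), the "at least one report" and weight-of-evidence
    enhancement classifiers, stratified mortality indicators (median age
    at death, percent increases, indirectly standardised mortality ratios
    with exact gamma confidence intervals), misclassification sensitivity
    analysis, and a synthetic linked-data generator that emulates
    differential reporting sensitivity and record-linkage errors.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
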