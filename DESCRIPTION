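Package: berlinards
Title: Automated Berlin-Criteria Detection of Acute Respiratory Distress Syndrome from Electronic Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based and machine-learning phenotyping of acute respiratory
    distress syndrome (ARDS) from electronic health record extracts. Evaluates
    the four Berlin-definition criteria with explicit temporal logic: validity
    windows around chest-radiograph evidence of bilateral infiltrates,
    qualifying hypoxemia events (PaO2/FiO2 <= 300 mmHg on PEEP >= 5 cmH2O),
    acute-onset checks (early-tracheostomy proxy and an onset horizon after
    the first PEEP >= 5 record), and exclusion of admissions whose respiratory
    failure is attributable to heart failure or fluid overload. Includes
    trainable TF-IDF linear text classifiers for radiology and echocardiogram
    reports, an ICD-9 comparator flag, confusion-matrix evaluation with
    time-window grid search and component ablations, a seeded synthetic-EHR
    generator with known ground truth, a single-admission timeline
    visualization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    glmnet,
    e1071,
    ggplot2,
    patchwork,
    jsonlite,
    yaml,
    optparse,
    stats,
    utils,
    tools,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
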