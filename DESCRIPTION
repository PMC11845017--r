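Package: amftrial
Title: Evaluation of Arbuscular Mycorrhizal Inoculant Pot Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Analysis pipeline for pot-inoculation trials that screen
    arbuscular mycorrhizal fungi (AMF) for plant growth promotion.
    Computes Trouvelot-style mycorrhizal colonization indices (F%, M%,
    m%, a%, A%) from scored root fragments, per-indicator group
    summaries with one-way ANOVA and compact letter displays, percent
    change versus an uninoculated control, and a direction-aware
    min-max membership-function evaluation that ranks inoculants
    across many physiological indicators. Also provides the molecular
    readouts used to validate such trials: a log2 fold-change /
    p-value screen for differentially expressed genes and Livak
    2^-ddCt relative quantification for qPCR plates. Seeded synthetic
    generators emulate the trial design end to end so every stage is
    testable without raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
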