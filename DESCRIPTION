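Package: mndpanel
Title: Gene-Panel Burden and Genotype-Phenotype Analysis for Motor Neuron
    Disease Case-Control Cohorts
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable implementation of a targeted gene-panel genetic
    epidemiology workflow for motor neuron disease (MND) case-control
    cohorts: negative-control-referenced sample quality control for
    amplicon sequencing, rare-variant filtering on consequence, population
    frequency, read depth and allele balance, tiered pathogenicity
    classification combining loss-of-function consequence rules, HGMD
    disease flags and a ten-predictor in-silico ensemble vote, one- and
    two-tailed Fisher exact burden tests against internal controls and a
    depth-adjusted ExAC reference, carrier-union and digenic accounting
    including C9orf72 repeat expansions, and genotype-phenotype
    association via univariate screening, binomial logistic regression
    with Nagelkerke R-squared, and Kaplan-Meier/log-rank survival
    comparison. A fully synthetic cohort simulator with a planted truth
    ledger makes every stage testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    survival
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
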