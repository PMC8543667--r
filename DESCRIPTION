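Package: fpetdopa
Title: Functional PET Quantification of Task-Specific Dopamine Synthesis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantification of task-specific changes in cerebral dopamine
    synthesis from dynamic 6-[18F]FDOPA PET acquired under a bolus plus
    constant infusion protocol. Builds arterial parent and 3-O-methyl
    metabolite input functions from blood sample tables, removes the
    metabolite component from brain time-activity curves via a
    reference-region one-tissue fit, separates per-block task uptake from
    baseline synthesis with a general linear model after temporal low-pass
    filtering, and converts the separated components into net-influx
    constants with the Gjedde-Patlak plot, performance weighting and
    percent signal change. Includes a synthetic kinetics and behavior
    simulator (irreversible two-compartment FDOPA kinetics with
    task-modulated trapping, co-simulated metabolite signal, adaptive
    staircase monetary incentive delay sessions) with recorded ground
    truth for parameter-recovery testing, plus the accompanying behavioral
    analyses (stepwise polynomial reaction-time models, Holm-corrected
    group tests, exact Spearman correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    minpack.lm,
    pracma
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'blood-model.R'
    'synthetic-tac.R'
    'synthetic-mid.R'
    'blood.R'
    'metabolite.R'
    'glm.R'
    'patlak.R'
    'behavior.R'
    'io.R'
    'config.R'
    'synthetic-session.R'
    'pipeline.R'
    'cli.R'
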