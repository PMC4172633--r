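Package: contestRHP
Title: Assessment Strategies in Dyadic Contests from Outcome and Duration Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for asking how fighting ability (resource holding
    potential, RHP) shapes who wins a dyadic contest and how long the
    contest lasts, and for using the answer to distinguish
    self-assessment from mutual assessment of capabilities.  Implements
    a two-step inferential pipeline: (1) screen candidate power measures
    as RHP correlates with binomial mixed-effects logistic regressions
    of contest outcome on relative power difference, using a balanced
    focal/opponent design and crossed random intercepts for contestant
    identity; (2) fit Gaussian linear mixed models of log10 contest
    duration on winner, loser and relative power separately and classify
    the assessment strategy from the sign pattern of the slopes.  The
    mixed-model machinery (Laplace-approximate marginal likelihood for
    the binomial family, profiled REML for the Gaussian family,
    likelihood-ratio chi-square tests and F tests with Satterthwaite
    denominator degrees of freedom) is implemented in the package.  A
    seeded simulator generates dyadic contest tables under war-of-
    attrition, sequential-assessment and cumulative-assessment
    generative models, with five correlated power measures and reusable
    contestant identities, and can emit files in the Correlates of War
    v4.0 dialect so that the ingestion path is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    lme4,
    lmerTest,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
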