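Package: distressnet
Title: Psychometric Network Analysis of Longitudinal Dyadic Distress Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <maintainer@example.org>
Description: Tools for studying parental distress with Kellner Symptom
    Questionnaire subscale scores collected from mother-father dyads at
    repeated time points. Provides a validated long-format cohort container
    with complete-case filtering and role-by-time stratification; classical
    test statistics (Kolmogorov-Smirnov normality, repeated-measures and
    one-way ANOVA with Tukey HSD post hocs, a priori power analysis for the
    correlation test, comparison against published control norms);
    nodewise L1-regularised mixed graphical model estimation with
    cross-validated tuning, AND-rule edge aggregation and node
    predictability; strength and weighted betweenness centrality with
    nonparametric bootstrap stability; walktrap community detection,
    modularity scoring, Fruchterman-Reingold and cross-network average
    layouts; and a synthetic dyadic-cohort generator with planted sparse
    conditional-dependence structure so every stage can be exercised and
    validated without access to private clinical data. A config-driven
    pipeline reproduces the full analysis shape end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
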