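# distressnet

Psychometric network analysis of longitudinal dyadic distress
questionnaires, built for studying how parents of pediatric oncology
patients express distress over the first months after their child's
diagnosis — and for anyone analysing small role-by-time stratified
questionnaire cohorts with mixed graphical models.

## What it computes

The input is a long-format cohort: one row per (dyad, parent role, time
point) with the eight Kellner Symptom Questionnaire subscale scores —
Anxiety, Depression, Somatisation, Hostility (0–17) and Relaxation,
Contentedness, Physical Well-Being, Friendliness (0–6) — plus the child's
sex. Two analysis arms run over the complete-case dyads:

**Classical statistics.** Kolmogorov–Smirnov normality screening,
one-way within-subject repeated-measures ANOVA across T1/T2/T3 with Tukey
HSD post hocs, mother-vs-father one-way ANOVAs per time point,
classification of baseline means against a published control norm, and an
a priori power analysis for the bivariate-normal correlation test
(`power_min_r` inverts the exact power function at the t-based critical
value).

**Network analysis.** For each of the six role × time strata, a pairwise
mixed graphical model over the 9 nodes (8 continuous subscales + the
dichotomous child sex), estimated by nodewise L1-regularised regressions
with seeded 10-fold cross-validation and conservative AND-rule edge
aggregation. An edge between nodes *i* and *j* means the two variables
are conditionally dependent given all others; its weight is the mean of
the two absolute standardized coefficients, signed for
continuous–continuous pairs. Derived per network: node predictability
(R² / CC, nCC, CCmarg), strength and weighted betweenness centrality
(edge length 1/|w|, fractional shortest-path counting), nonparametric
bootstrap stability of both indices, walktrap communities cut at maximum
modularity, and a Fruchterman–Reingold "average layout" shared across
strata, with node sizes encoding percent change from baseline.

Because clinical data of this kind are private, the package includes a
synthetic dyadic cohort generator with planted sparse
conditional-dependence structure (per-stratum precision matrices,
Kronecker-structured couple and time coupling, bounded integer scores,
and the study's dropout pattern), so the whole pipeline is exercisable
and testable end to end. See the methods vignette
(`vignettes/distress-networks.Rmd`) for the model, parameter defaults and
design decisions.

## Worked example

```r
library(distressnet)

gen <- generate_cohort(synthetic_spec())   # the default study design
cc  <- complete_case_filter(gen$cohort)
#> enrolled: 23 | complete pairs: 16 | dropped: 7

power_min_r(16, alpha = 0.05, power = 0.8)
#> [1] 0.6356616
```

With 16 pairs, only correlations of about 0.64 or larger are detectable
at 80% power — the design resolves large effects only. Estimating one
stratum network at that size is honest but sparse:

```r
strata <- stratify(cc$cohort)
estimate_stratum_network(strata$mother_T1, list(seed = 102))$network
#> <network_model> mother T1: 9 nodes, 3 edges, n = 16
```

A better-powered cohort shows the full machinery:

```r
spec300 <- synthetic_spec(n_dyads = 300, dropout = integer(0), seed = 7)
st   <- stratify(generate_cohort(spec300)$cohort)$mother_T1
est  <- estimate_stratum_network(st, list(seed = 102))
head(betweenness_centrality(est$network), 5)
#>                      node degree  strength betweenness betweenness_norm
#> Anxiety           Anxiety      3 0.4292718           7        0.2500000
#> Depression     Depression      1 0.1753559           0        0.0000000
#> Somatisation Somatisation      2 0.3070030           6        0.2142857
#> Hostility       Hostility      0 0.0000000           0        0.0000000
#> Relaxation     Relaxation      1 0.1525083           0        0.0000000
```

Anxiety has the largest strength and betweenness: it is the maternal
baseline hub planted by the generator, and many weighted shortest paths
route through it. `walktrap_cluster(est$network)` then groups the
recovered anxiety neighbourhood into one community (Q = 0.37 for the
chosen partition).

The whole analysis — filter, statistics, six networks, bootstrap,
clusters, layout, JSON + markdown report — runs as one call:

```r
report <- run_pipeline(list(seed = 101L, outdir = "out"))
```

A thin command-line wrapper with `simulate` / `stats` / `networks` /
`report` / `run-all` subcommands is installed at
`inst/cli/distressnet.R`.

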