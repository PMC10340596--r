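---
title: "Modeling parental distress as a psychometric network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling parental distress as a psychometric network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

When a child is diagnosed with cancer, both parents are exposed to a
prolonged, severe stressor. The Kellner Symptom Questionnaire (SQ)
summarises a parent's state on eight subscales — four symptom scales
(Anxiety, Depression, Somatisation, Hostility, scored 0–17) and four
well-being scales (Relaxation, Contentedness, Physical Well-Being,
Friendliness, scored 0–6). Administered to both members of a mother–father
dyad at diagnosis (T1), one month (T2) and three months (T3), it yields a
small longitudinal dyadic dataset.

`distressnet` implements two complementary analysis arms over such data:

1. **Classical statistics** — normality screening, repeated-measures
   ANOVA over time with Tukey HSD post hocs, one-way mother-vs-father
   comparisons, comparison of baseline means against a published control
   norm, and an a priori power analysis for the correlation test.
2. **Psychometric network analysis** — for each of the six role × time
   strata, a pairwise mixed graphical model (MGM) over the 8 continuous
   subscales plus the dichotomous sex of the child, followed by
   centrality, bootstrap stability, walktrap community detection and
   force-directed layouts.

Clinical questionnaire data of this kind are typically private. The
package therefore ships a first-class synthetic cohort generator whose
defaults reproduce the study design the analysis was built for: 23
enrolled dyads, the fathers of 7 dyads missing after T1 (so complete-case
filtering keeps 16 pairs), and a different planted sparse
conditional-dependence graph per stratum.

## The network model

An MGM is a pairwise Markov random field over mixed node types. Absence of
an edge between nodes $i$ and $j$ means conditional independence of the
two variables given all remaining variables. We estimate it nodewise: each
node is regressed on all others with an L1 penalty — Gaussian least
squares for the continuous subscales, logistic regression for the
dichotomous child-sex node — and an edge is kept only when *both*
directed fits select the partner (AND rule), with weight equal to the
mean of the two absolute standardized coefficients. Continuous–continuous
edges carry the shared coefficient sign (edges whose two fits disagree in
sign are dropped and reported as unstable); edges touching the
dichotomous node are reported as unsigned presence/absence, with their
magnitude retained internally so they participate in path-based indices.

### Tuning-parameter selection

The penalty weight $\lambda$ is tuned per node by seeded 10-fold
cross-validation on a grid of 50 log-spaced values from $\lambda_{\max}$
(the smallest penalty that zeroes all coefficients) down to
$10^{-3}\lambda_{\max}$. Two selection rules are available:

* `select = "1se"` (default) — the sparsest $\lambda$ within one standard
  error of the minimum mean held-out loss;
* `select = "min"` — the loss minimum itself.

The one-standard-error rule is the default as a deliberate design choice.
At the sample sizes this package targets (tens to a few hundred rows, 8
predictors), the CV-minimum rule follows the noise in the loss curve and
admits a substantial number of false-positive edges even after AND-rule
aggregation, while the 1-SE rule keeps networks estimated from
independent data nearly empty at a negligible cost in sensitivity. The
test suite verifies both properties on planted-structure and null
cohorts: with chain graphs of partial correlation 0.3 at $n = 500$ the
default estimator recovers at least 90% of planted edges with at most
10% spurious ones, and on fully independent columns it averages at most
2 of the 36 possible edges per network. Cross-validation is exactly the
false-positive-containment device the procedure relies on, and the 1-SE
rule is what makes it deliver that containment here.

All predictors are z-scored within a stratum before penalized fitting and
edge weights are reported on that standardized scale; whether to
standardize is a convention, and reporting standardized weights makes
edges comparable across strata with different score dispersions.

### Predictability

Per node we report how well its neighbours predict it, from an
unpenalized refit on the selected neighbourhood: $R^2$ for continuous
nodes (0 for isolated nodes, clamped to $[0,1]$); for the categorical
node the correct-classification rate CC, the marginal majority-class
accuracy CCmarg, and the normalized accuracy
$nCC = (CC - CCmarg)/(1 - CCmarg)$, which is 0 when the neighbours add
nothing over the intercept. nCC is clamped at 0: on resampled or
degenerate fits the refit can classify slightly worse than the
intercept, and a negative "share of explainable accuracy" has no
interpretation in this decomposition.

## Centrality and stability

* **Strength** — the sum of absolute incident edge weights. The verbal
  shorthand "number of connections" is ambiguous for weighted graphs, so
  the unweighted degree is emitted alongside for transparency.
* **Betweenness** — fractional (Brandes) counting of weighted shortest
  paths through each node, with edge length $1/|w_{ij}|$ (Opsahl's
  distance transform with $\alpha = 1$): stronger conditional
  associations are shorter paths. Reported raw and normalized by
  $(n-1)(n-2)/2$. The test suite pins this definition to an exhaustive
  path-enumeration oracle on all small graphs it generates.

Because the target samples are small, centrality is accompanied by a
nonparametric case-resampling bootstrap: `B` replicates (default 1000;
the pipeline default is 200) redraw rows with replacement and re-run the
*entire* estimation, yielding percentile confidence intervals, a
bootstrap mean, and a rank-stability proportion — the share of replicates
in which a node keeps its full-sample dense rank on the metric. The same
replicates provide per-edge inclusion proportions; edges included in
fewer than half the replicates are flagged non-significant and rendered
gray, a criterion chosen here since inclusion stability is the natural
bootstrap analogue of edge significance. Case resampling (not case
dropping) is used so every replicate estimates the same target.

## Community structure and layouts

Communities are found with the walktrap algorithm on the absolute
weights: random walks of length $t = 4$ (the algorithm's conventional
default; results at these graph sizes are insensitive to $t$), Ward-style
agglomeration of walk distances, and a cut at the dendrogram level of
maximum Newman modularity
$Q = \sum_c (e_c/m - (d_c/2m)^2)$ computed on $|W|$.

Layouts use the Fruchterman–Reingold algorithm (500 iterations, optimal
distance $\sqrt{\text{area}/n}$, seeded initial placement, coordinates
rescaled to the unit square). To make the six stratum networks visually
comparable, a single **average layout** is computed on the element-wise
mean of the absolute weight matrices across all networks and reused for
every stratum, so only edges and node sizes differ between panels. Node
sizes encode the percent change of a subscale's mean score from the same
role's baseline: $1 + (\bar{x}_{Tk} - \bar{x}_{T1})/\bar{x}_{T1}$,
floored at 0.2 so a collapsed mean still renders.

Edge signs are ignored by walks and layouts (magnitudes only); they are
conventionally rendered as green (positive partial association) versus
red (negative), with width proportional to $|w|$.

## The synthetic cohort generator

The generator draws, per dyad, six latent 8-vectors (2 roles × 3 times)
that are marginally $N(0, \Omega_{rt}^{-1})$ for the stratum's planted
precision matrix $\Omega_{rt}$, while sharing standard-normal factors
whose cross-cell correlation is Kronecker-structured: exchangeable with
parameter `dyad_rho` across the couple and AR(1) with parameter
`time_rho` across time. The child's sex (Bernoulli 1/2, constant within a
dyad) shifts designated nodes by ±half the configured effect. Latent
scores are then mapped affinely onto each subscale's integer range,
rounded and clamped.

Defaults, chosen once to mirror the target study design and held fixed:

| parameter | default | rationale |
|---|---|---|
| `n_dyads` | 23 | enrolled couples in the emulated design |
| `dropout` | dyads 17–23, father at T2/T3 | 7 father dropouts after baseline; complete-case filtering then keeps 16 pairs |
| planted partial correlations | 0.3 | a moderate conditional association, detectable but not trivial at these n |
| `dyad_rho` / `time_rho` | 0.3 / 0.4 | moderate within-couple similarity and month-scale persistence typical of distress measures |
| `sex_effect` | 0.5 SD on Somatisation and Contentedness | gives the dichotomous node real neighbours without dominating the graph |
| scale maxima | 17 (symptom), 6 (well-being) | SQ item counts; configurable because administrations vary |

The planted per-stratum topologies echo the qualitative result structure
the analysis is designed to resolve (a maternal anxiety hub at baseline,
a paternal depression hub at one month, a paternal anxiety hub at three
months, and so on); their magnitudes are free parameters, not estimates
of any real cohort.

What the generator deliberately does **not** emulate: marginal score
means and skew of real distress data (latent scores are symmetric around
the scale midpoint), ordinal thresholding (round-and-clamp is transparent
but attenuates associations slightly — the coarser 6-point scales lose
the most, which is why fidelity diagnostics on the latent scores are
exposed via the generator's `latent` output), informative dropout
(missingness is a fixed design pattern, not outcome-dependent), and any
real covariance between the child's sex and illness course. Passing
recovery tests on these cohorts therefore demonstrates correctness of the
estimation machinery under the assumed model class, not robustness to
real-data violations of it.

## Classical arm: numerical choices

* **K-S normality** uses a Gaussian reference with sample-estimated mean
  and SD by default; the asymptotic p value is then conservative (the
  Lilliefors caveat) and a fixed reference can be supplied instead.
* **Repeated-measures ANOVA** is the one-way within-subject
  decomposition $F = MS_{time}/MS_{time\times subject}$ with
  $df = (t-1, (t-1)(n-1))$; no sphericity correction by default (a
  Greenhouse–Geisser option exists behind the `gg` flag). A zero residual
  mean square raises a degenerate-result error rather than returning an
  infinite F.
* **Tukey HSD** uses $q = |\bar{x}_i - \bar{x}_j|/\sqrt{MS_e/n}$ with p
  values from the studentized-range distribution.
* **Power analysis** (`power_min_r`) inverts the power function of the
  two-sided test of a bivariate-normal correlation at the t-based
  critical value. The default method integrates the *exact* sampling
  density of the sample correlation coefficient (evaluated on the log
  scale with a Gauss ``2F1`` series; inversion tolerance $10^{-6}$); a
  bias-corrected Fisher-z approximation is available as
  `method = "fisher-z"`. At `n = 16`, `alpha = 0.05`, `power = 0.8` the
  exact method returns $r \approx 0.636$ — small samples can only
  establish large correlations.
* The significance threshold throughout is 0.05 and no multiplicity
  correction is applied beyond Tukey's procedure, matching common
  practice for this design.

## Pipeline and reproducibility

`run_pipeline()` executes: cohort (synthetic or CSV) → complete-case
filter → classical statistics → six stratum MGMs → predictability →
centrality with bootstrap → walktrap clusters → average layout →
artifacts (`report.json`, `report.md`, per-stratum GraphML and edge/node
CSVs, metrics, predictability, cluster and layout tables). One global
seed derives the stage seeds (cv = seed+1, bootstrap = seed+2, layout =
seed+3), so a config fully determines a run: identical configs produce
byte-identical reports. The JSON and markdown reports carry the same
counts, and the complete-case accounting always satisfies
enrolled = complete + dropped with each of the six strata holding exactly
the complete-dyad count.

## Validation scale

The suite validates the estimator at the sizes where its guarantees are
claimed: edge recovery and false-positive control on cohorts of 500 (20
replicates) and nulls of 200; type-I calibration of the repeated-measures
F over 2000 simulated null cohorts of 16 subjects; betweenness against
brute-force path enumeration on over a hundred random graphs of up to 7
nodes; bootstrap behaviour at B up to 200 on a planted hub design. These
sizes were chosen as the smallest that make the stochastic bounds sharp.

## Known limitations

* Edges are pairwise only ($k = 2$); higher-order interactions and
  time-varying or multilevel network models are out of scope.
* With 16 rows per stratum — the realistic complete-case size — the
  conservative default selection yields sparse networks; that is a
  faithful reflection of what such samples support, not an estimation
  failure. Interpretation at that scale should lean on the bootstrap
  stability output.
* Walktrap on 9-node graphs is sensitive to single edges; community
  counts on sparse strata should be read qualitatively.
* The generator's round-and-clamp discretisation slightly attenuates
  planted associations relative to their latent values (strongest on the
  6-point scales).
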