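---
title: "Methods: the quick-scan handling and hygiene calculator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the quick-scan handling and hygiene calculator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigqsc)
```

## The scoring model

Weaning is the most stressful phase of a pig's productive life: piglets lose
the sow, switch to solid feed and join new social groups, and poor handling
or hygiene at this stage translates into disease, mortality and veterinary
medication expenditure. `pigqsc` implements a multi-criteria evaluation of
post-weaning management built on ten indices: pre-weaning handling, batch
management, biosecurity, water management, feed management, health program,
stockmen training, and the three facility indices — room temperature,
ventilation, and floor type/stocking density.

Each index $i$ is a weighted checklist. A factor $f$ with weight $w_f > 0$
points and a graded response earning a credit fraction
$c_f \in [0, 1]$ contributes $w_f c_f$ points, and

$$S_i = \sum_{f \in i} w_f\, c_f, \qquad \sum_{f \in i} w_f = 10,$$

so each index ranges 0–10 and the farm total $S = \sum_{i=1}^{10} S_i$
ranges 0–100. Each index is read as a potential *limiting factor* in the
sense of Liebig's law of the minimum: a single badly-managed theme can by
itself cap the farm's health and performance, which is why the indices are
kept separate rather than collapsed early.

The three facility indices are evaluated **per post-weaning room**; the
farm-level score of such an index is the unweighted arithmetic mean of its
room scores. Rooms contribute equally regardless of size, because the
assessment is of facilities and routines, not of animal counts.

Responses come in three kinds:

* **binary** — presence/absence of a good practice ($c \in \{0, 1\}$);
* **categorical** — $k$ ordered options with non-decreasing credits fixed at
  $0$ and $1$ at the extremes; the default grading is equally spaced
  ($0, \tfrac{1}{k-1}, \dots, 1$), overridable per option in the schema file;
* **numeric threshold** — a measured quantity compared *inclusively*
  against a bound: water flow $\ge$ 1 L/min, drinkers per piglet $\ge$ 0.1,
  and available floor area $\ge 0.1\ \mathrm{m^2}$ per 10 kg live weight
  (so the boundary value earns full credit). `density_per_10kg()` converts
  an area-per-pig and a live weight into the thresholded unit.

### The schema is data

`default_schema()` ships the ten-index calculator as a YAML document with
factor counts (4, 4, 8, 7, 5, 6, 4, 3, 4, 4). The expert-elicited factor
weights of the original instrument are not publicly tabulated, so the
default splits each index's 10 points equally across its factors —
consistent with the granularity of published index scores, which are
multiples of $10/n_f$ (biosecurity values are multiples of 1.25, batch
management of 2.5, feed management of 2.0). A user holding the original
weights (or any re-calibration) edits the schema file; no code changes.
`validate_schema()` returns all invariant violations as data; unknown keys
anywhere in the file are rejected outright, because silent typos in a
checklist instrument are worse than hard failures.

Three factors that the source instrument marks as three-way choices
(weaning age, temperature regulators, slat material) are categorical; we
also model the heating-system factor with three ordered categories (none /
whole-room / localized) so that the reported rarity of localized heating in
nurseries is representable. All other factors are binary — the instrument
aims for "the simplest possible answer".

### Missing answers

Strict mode (default) refuses to score incomplete assessments and names the
farm, room and factor. Lenient mode scores a missing answer as 0 points
with a warning: under the limiting-factor reading, an unobservable practice
is conservatively treated as absent. Nothing is imputed.

## Benchmarking analytics

`describe_cohort()` reports mean, sample SD, min/max and quartiles.
Because the original analyses were run in SPSS, the default percentile rule
is SPSS's weighted-average definition (position $(n+1)p$; R's `type = 6`);
the common linear-interpolation rule (`type = 7`) is available via
`percentile = "linear"`. Both are oracle-tested; on small cohorts they
genuinely differ, which matters when comparing published quartiles.

`cor_with_p()` / `correlation_table()` produce the validation table: Pearson
$r$ for each of the 11 score rows (10 indices + overall) against 8 KPI
columns, with two-tailed $p$ from $t = r\sqrt{(n-2)/(1-r^2)}$ and stars at
$p \le 0.05 / 0.01 / 0.001$. Cells use pairwise-complete observations and a
degenerate cell (constant column) becomes `NA` with a warning instead of
failing the table. No multiplicity correction is applied across the 88
cells, matching the original analysis; readers should treat isolated single
stars accordingly.

`quartile_groups()` ranks farms by a KPI and contrasts the best quartile
(Q1), middle half (Q2Q3) and worst quartile (Q4), with
$\mathrm{round}(n/4)$ farms in each extreme group (rounding half up — 6/11/6
at $n = 23$; the rounding rule for ties at half is stated because R's
`round()` is round-half-even). Ties at a boundary are broken by stable row
order and flagged.

`compare_groups()` runs one-way ANOVA per outcome and a
**Student–Newman–Keuls** stepwise procedure for the letters. With means
sorted descending, a comparison spanning $p$ ordered means is significant
when

$$q = \frac{\bar y_{\max} - \bar y_{\min}}{\sqrt{MS_W / n_h}} >
q_{1-\alpha}(p,\ \mathrm{df}_W),$$

where $n_h$ is the harmonic mean of the two group sizes (the standard SNK
practice for unequal groups; the 6/11/6 design makes this unavoidable) and
$q_{1-\alpha}$ is the studentized-range quantile. Once a span tests
non-significant, everything inside it is declared homogeneous (the SNK
containment rule), which makes the homogeneous sets contiguous intervals of
the mean ordering; the compact letter display assigns one letter per maximal
homogeneous interval. For two groups the procedure reduces exactly to the
pooled $t$-test ($q = \sqrt 2\,|t|$), and every pair Tukey's HSD separates,
SNK separates too — both identities are exercised in the test suite, along
with a 5,000-replicate complete-null simulation holding the family-wise
error near $\alpha$. Shapiro–Wilk normality checks are computed and
reported but advisory only: they never block the pipeline.

## The synthetic cohort generator

The validation cohort of the original field study (23 commercial farms in
southern Spain) is confidential, so the package ships a generator that
emulates its statistical structure; every end-to-end analysis here runs on
synthetic farms.

Each farm draws a latent management quality $u_i \sim N(0,1)$. A checklist
response is an ordered-logit draw on $u_i$: for a binary factor with base
rate $p_f$ the pass probability is
$\mathrm{logit}^{-1}(\mathrm{logit}(p_f) + \beta u_i)$, and categorical
factors cut a single logistic draw at ordered thresholds whose base
cumulative probabilities give the top option $p_f$ and split the remainder
evenly. Room-level factors add a per-room disturbance
$v_r \sim N(0, \sigma^2_{\mathrm{room}})$ to $u_i$, so rooms within a farm
are correlated but not identical. Rooms per farm follow a discretized
Normal (mean 10.52, SD 5.48, minimum 3), matching the published cohort
description.

Defaults (all overridable in `generator_config()`):

* **base rates** per index equal to the published mean index score divided
  by 10 (e.g. biosecurity 0.511, temperature 0.408, floor 0.803), with
  three factor-level overrides for reported prevalences: localized heating
  0.043, programmed minimum ventilation 0.13, performance-based incentives
  0.05 (nearly absent in the field);
* **slope** $\beta = 0.4$, set so the between-farm SD of the overall score
  matches the published cohort's spread (about 10 points); the simulated
  mean overall score (~55) is checked against the generator's own
  closed-form expectation (`expected_overall_score()`, a numerical
  integral over the latent distribution) rather than against any published
  value;
* **room disturbance** $\sigma_{\mathrm{room}} = 0.5$, giving visibly
  heterogeneous rooms without decoupling them from the farm.

KPIs are then coupled to the **realized overall score**: with standardized
score $z_i$,

$$\mathrm{KPI}_i = \mu + \sigma\left(\rho z_i +
\sqrt{1-\rho^2}\,\varepsilon_i\right), \qquad \varepsilon_i \sim N(0,1),$$

so the population correlation with the score is exactly the configured
$\rho$. Default $\rho$, $\mu$, $\sigma$ come from the published
correlation and descriptive tables (PWSY $\rho = 0.592$, FCR $-0.442$,
post-weaning mortality $-0.437$, total cost $-0.435$, medication cost
$-0.414$, weaned-piglet cost $-0.182$, ADG $0.086$, cost/kg $-0.228$).
Coupling to the latent quality instead (`couple_to = "latent"`) is more
realistic — measurement of management through 49 discrete checklist items
attenuates the correlation — but then configured targets are recovered only
approximately. Mortalities and costs are clipped at zero afterwards, with
the clipped count reported; at the configured marginals clipping touches
well under 1% of draws and does not move the correlations materially.

**Fidelity limits.** KPIs are conditionally independent given the score, so
cross-KPI correlations (e.g. FCR with total cost) are not targeted and come
out weaker than on real farms. Factor responses are conditionally
independent given quality, so real-world bundling of practices (farms with
footbaths also tend to quarantine) is only captured through $u$. Passing
the calibration tests therefore shows the pipeline recovers what it was
configured to produce — not that the generator reproduces the joint
distribution of real farm data.

## Numerical choices and problem sizes

* Weights and scores are carried at full double precision; the 2-decimal,
  half-up rounding of the published tables is applied only at presentation
  (`format_*` functions and reports).
* Index weight sums are validated to $10 \pm 10^{-9}$; score decompositions
  are tested to the same tolerance.
* All simulations are seeded and bit-reproducible; the generator derives
  its assessment and KPI noise streams from one configured seed.
* Test problem sizes: calibration checks use cohorts of 20,000 synthetic
  farms (correlation Monte-Carlo error $\approx 0.006$, checked at
  $\pm 0.02$); coupling recovery uses $n = 50{,}000$ at $\pm 0.015$; the
  SNK complete-null simulation uses 5,000 replicates of three groups of
  five. These sizes keep every Monte-Carlo tolerance at least three
  standard errors wide while the whole suite runs in a few minutes.

## Worked example

```{r example}
cfg <- generator_config(n_farms = 23, seed = 42)
coh <- generate_cohort(cfg)
tbl <- cohort_table(coh)

describe_cohort(tbl, c("overall", "pwsy", "medication_cost"))

ct <- correlation_table(tbl)
format_correlation_table(ct)

grouped <- quartile_groups(tbl, "pwsy")
cmp <- compare_groups(grouped, c("pwsy", "overall", "medication_cost"))
tidy(cmp)
```

```{r figure, fig.width = 7, fig.height = 4}
plot_cohort_scores(coh$scores)
```

## Known limitations

* The calculator assesses routine management; under a severe disease
  outbreak the link between management scores and performance breaks down.
* No animal-based welfare measures are included — by design the instrument
  avoids animal manipulation — so it complements rather than replaces
  welfare protocols.
* The default equal-split weights are a documented stand-in for the
  original expert weighting; absolute scores from different weightings are
  not comparable.
* At a realistic cohort size ($n \approx 23$) individual correlation cells
  carry wide confidence intervals; the package reproduces the analysis
  pipeline, not the precision of any particular dataset.
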