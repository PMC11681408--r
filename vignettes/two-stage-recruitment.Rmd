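---
title: "Two-stage recruitment designs for MRI-screened trials: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage recruitment designs for MRI-screened trials: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmhrecruit)
```

## The problem

Clinical trials that target white-matter hyperintensity (WMH) progression
must enroll people who already carry significant WMH burden on MRI. In
late midlife only a small fraction of the population does — around 10% in
the ARIC community cohort whose published summary tables parameterize this
package — so screening by MRI alone is expensive: at roughly $650 per scan
and a 9.9% yield, enrolling 646 eligible participants means scanning
thousands of people. A two-stage design inserts a cheap prescreen first
(a retinal fundus photograph at about $32.50, or clinical information that
costs nothing to collect) and sends only prescreen-positives to MRI.
`wmhrecruit` computes how many people each stage needs and what it costs,
for the MRI-only and two-stage designs, and provides everything around
that calculation: the risk scores used as prescreens, screening
performance metrics, attrition and two-group extensions, a CHS-grade to
volume conversion for progression analyses, and a synthetic cohort
generator for end-to-end validation.

## The recruitment model

Let $N_T$ be the trial's target enrollment, $p_1$ the fraction of the
population positive at the prescreen, and $p_2$ the fraction of
prescreen-positives with significant WMH on MRI. With attrition rate $a$
(the fraction of MRI-eligible people who ultimately do not enroll), the
expected probability that a recruited person ends up enrolled is
$p_1 p_2 (1-a)$, so the prescreening stage needs

$$N_{\text{pre}} = \left\lceil \frac{N_T}{p_1\, p_2\, (1-a)} \right\rceil,
\qquad
N_{\text{MRI}} = \lceil p_1 N_{\text{pre}} \rceil,$$

and the total cost is $N_{\text{pre}} c_{\text{pre}} + N_{\text{MRI}}
c_{\text{MRI}}$. The MRI-only design is the degenerate case $p_1 = 1$,
$c_{\text{pre}} = 0$, with $p_2$ the population WMH prevalence; the
package tests this identity property over randomized inputs.

Three numerical choices matter here:

* **Rounding is ceiling, at both stages.** No rounding rule is ever
  printed alongside such calculations; ceiling is the only rule that is
  conservative (the expected number of eligible participants never falls
  below the target, since rounding up only adds people) and it reproduces
  every internally consistent row of the published late-midlife
  comparison (e.g. $3800.02 \to 3801$, $2808.75 \to 2809$).
* **Ceilings are guarded**: `ceiling(round(x, 9))`, so a product of
  decimal proportions that is mathematically integral is not bumped a
  whole participant upward by binary floating-point error. Nine decimals
  is far below any meaningful resolution of a sample-size ratio.
* **Currency is exact.** Unit costs are held internally in integer cents
  and stage totals are integer multiples of them, so no floating-point
  drift can appear in a cost column. Costs must therefore be specified to
  whole cents.

### Proportion precision

`design_from_crosstab()` supports two precision policies for the
proportions it derives from a contingency table. `"exact"` (the default)
uses full-precision count ratios — the right choice when you have the
counts. `"paper"` first rounds each proportion to **two significant
figures**, which is the precision at which epidemiological summary tables
conventionally print percentages (7.5%, 13%, 40%, 9.9%, ...). The
published comparison table is reproducible only under this policy: for
instance $646 / 0.099 \to 6526$ scans, whereas the exact ratio
$646/(130/1311)$ gives 6515. One printed row (the combined
clinical-retinal mild–severe row) is internally inconsistent as printed —
its overall sample size (6751) differs from its own prescreening-stage
size (6750), and its printed total does not equal the sum of its printed
parts — so that row is documented as irreproducible and no guess is made
about its intent; the other nine rows reproduce exactly.

## The prescreening scores

The unweighted scores are deliberately simple composites on a 0–3 scale,
with severity labels none/mild/moderate/severe for 0/1/2/3:

* **Retinal**: retinopathy = 3 points (it represents end-stage retinal
  disease, which the other signs usually precede); arteriovenous nicking,
  focal arteriolar narrowing and generalized arteriolar narrowing = 1
  point each; sum truncated at 3.
* **Clinical**: 1 point each for age at or above the cutoff (60 years in
  late midlife; 78 in late life, the cohort's follow-up visit being 18
  years later), hypertension and diabetes.
* **Combined**: the sum of the two, truncated at 3 so the scale stays
  comparable.

The age comparison is implemented as $\ge$ with the operator
configurable: the source descriptions alternate between "older than 60"
and "age ≥ 60 y", and the tabulated prevalences are consistent with the
inclusive form. Severity *ranges* used as prescreen-positivity
thresholds are severe (= 3), moderate–severe (≥ 2) and mild–severe (≥ 1).

### Weighted scores

The weighted variant lets the data say how predictive each feature is.
The estimator is L2-regularized (ridge) logistic regression of WMH status
on the binary features of one predictor set, fitted with `glmnet` at a
fixed penalty $\lambda = 1$ — fixed rather than cross-validated so that
the fit is deterministic and comparable across runs; $\lambda$ is a
config parameter for users who want to tune it. The published account of
the original weighting scheme is not detailed enough to replicate
exactly, so the following interpretation is this package's own and is
flagged as such:

* The **normalized weight** of a feature is its shrunken coefficient on
  the odds-ratio scale, $w_i = e^{\beta_i}$: exactly 1 for an
  uninformative feature, above 1 for a risk feature. We chose this over
  the plausible alternative (absolute coefficients scaled to mean 1)
  because the latter is degenerate under the null: when no feature is
  associated, normalized $|\beta|$ ratios are scale-invariant noise, so
  one feature always appears to dominate no matter how strong the
  shrinkage. On the odds-ratio scale the null collapses all weights to 1,
  which also matches how published weights of this kind cluster near 1
  (e.g. 1.21, 1.19 for the strongest retinal predictors).
* The continuous weighted score of a participant is the weighted sum of
  present features rescaled so the **maximum attainable** sum maps to 3,
  keeping the weighted and unweighted scales comparable.
* The severity **bin** of a weighted score is the score rounded half-up
  to the nearest integer in 0..3. No binning rule is published; this one
  is symmetric and is recorded in the model object as an overridable
  choice.

Because the original cohort data are restricted, the weighted estimator
is validated by parameter recovery rather than by reproducing printed
weights: on synthetic cohorts where exactly one feature is associated
with WMH (odds ratio 5), that feature must receive the largest weight in
at least 19 of 20 seeded replicates, and under a fully null configuration
no weight may exceed twice the mean weight in most replicates.

## WMH measurement and the grade–volume map

Significant WMH burden is defined as CHS grade > 2 where scans were
graded visually, and as WMH volume ≥ 9.3 cm³ where only volumetric
measures exist (the published volumetric equivalent of that grade
cutoff, used for late-life scans). Both cutoffs are configurable.
Volumes are assumed already standardized to a total intracranial volume
of 1500 cm³; the package performs no re-standardization.

For progression analyses, baseline scans graded only on the CHS scale
are converted to estimated volumes with a quadratic OLS fit
$v = a_0 + a_1 g + a_2 g^2$ estimated from scans measured both ways
(`fit_chs_volume_map()`), or with externally supplied coefficients
(`chs_volume_map()`). Negative predictions are clipped to zero — volume
is a physical quantity — with a flag, predictions outside the fitted
grade range warn about extrapolation, and a fit with a negative linear
or quadratic term triggers a monotonicity diagnostic. The map is
implemented grade→volume only, the direction progression analysis needs;
inversion is deliberately not offered. Ten-year progression is then
follow-up volume minus mapped baseline volume, compared across score
categories with a Kruskal–Wallis omnibus test (tie-corrected, chi-square
reference) and planned post hoc rank-sum contrasts of each severity
category against "none" — the contrast set the published figures
suggest, though all-pairwise contrasts are available — with Bonferroni
adjustment by default.

## The synthetic cohort generator

The generator exists because the source cohort is restricted: it
emulates the *published joint structure* — 9.9% significant-WMH
prevalence and the published feature prevalences conditional on WMH
status (retinopathy 17% vs 6.2%, hypertension 66% vs 45%, age ≥ 60 82%
vs 63%, and so on) — so that every stage of the pipeline can be
exercised and validated end to end. Its defaults are those published
margins. Specific choices:

* Features are drawn **conditionally independent given WMH status**.
  Only the margins are published; no co-occurrence structure is
  asserted, and tests only ever claim recovery of the margins the
  generator was given, never that real cohorts are conditionally
  independent. Real retinal and clinical features are correlated (e.g.
  hypertension with retinopathy), so synthetic score *distributions*
  need not match the published score rows exactly — the clinical score,
  whose three features are closest to independence in the published
  table, lands near them.
* Age is generated by drawing the at-or-above-cutoff indicator at its
  conditional probability, then a uniform age within the matching
  10-year band. This hits the conditional age-category probability
  exactly; a clamped Gaussian would not.
* The CHS grade is drawn from a within-status ordinal distribution
  (grades 0–2 for no/low, 3–5 for significant, with fixed default
  probabilities), so grade > cutoff holds **iff** status is significant.
  The within-status distribution is not published and is a free config
  choice.
* The generator's true grade→volume relationship is the quadratic with
  coefficients (0.8, 1.0, 0.65), chosen so grade 3 maps to 9.65 cm³ —
  just above the 9.3 cm³ significance threshold — and grade 2 well
  below it. Baseline volumetric measures add Gaussian noise (default
  σ = 2 cm³, a realistic measurement + conversion error for volumes in
  the 1–30 cm³ range); follow-up volume adds a progression effect per
  retinal severity category (defaults 1/2/3/5 cm³ over ten years,
  increasing with severity as the published progression comparisons
  show) plus noise.
* The seed is mandatory; the same config and seed produce a
  byte-identical cohort CSV, and the generator restores the caller's
  RNG state.

`implied_category_probs()` enumerates the $2^k$ feature combinations to
give the exact severity-by-status distribution the generator implies,
and `recover_design()` checks that simulate → score → tabulate → design
reproduces the analytic design from those implied proportions at large
n. Test and validation problem sizes are chosen to make sampling error
negligible relative to the tolerance being asserted: margin recovery at
n = 1311 (the published cohort size) and n = 100,000, pipeline recovery
at n = 100,000, weighted-model recovery at n = 5,000 per replicate, and
1,000 replicates for the Kruskal–Wallis type-I-error band.

## What passing tests do and do not show

Exact reproduction of the published recruitment rows shows the
calculator implements the same arithmetic the published analysis used,
at the same printed precision. The synthetic-cohort results show the
pipeline is self-consistent — they cannot show that the published
margins transfer to any other population, and the conditional-
independence simplification means synthetic combined-score
distributions slightly understate the clustering of risk features seen
in real cohorts. Recruitment estimates for a real trial should come
from a contingency table for the actual target population, with costs
and attrition set to local values.

## Known limitations

* No power calculation: the trial target (default 646) is an input.
* No cost discounting, site effects, or per-visit cost breakdowns.
* The screening metrics carry no confidence intervals; PPV and NPV
  depend on the underlying prevalence, so they do not transfer across
  populations with different WMH prevalence.
* Multivariate imputation of missing features is out of scope; the
  loader offers exclusion (with a report) or per-column mode imputation
  only, with ties broken toward "absent".

## A worked example

```{r example, eval = FALSE}
library(wmhrecruit)

# designs from the published late-midlife summary tables
design_from_crosstab(aric_midlife_crosstab("clinical"), "severe",
                     cost_prescreen = 0, precision = "paper")

# the full comparison, cheapest first
tabs <- list(retinal = aric_midlife_crosstab("retinal"),
             clinical = aric_midlife_crosstab("clinical"),
             combined = aric_midlife_crosstab("combined"))
full_design_report(tabs, precision = "paper")

# end-to-end on synthetic data
cohort <- simulate_cohort(cohort_config(n = 1311, seed = 1))
ct <- cross_tabulate(cohort, "clinical")
design_from_crosstab(ct, "severe", cost_prescreen = 0)
```
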