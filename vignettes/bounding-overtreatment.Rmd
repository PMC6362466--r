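---
title: "Bounding mastectomy use for overdiagnosed breast cancer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounding mastectomy use for overdiagnosed breast cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(overtreat)
```

## The estimand and why it is only partially identified

Overdiagnosed cancers are screen-detected tumours that would never have been
noticed or caused harm in the patient's lifetime without screening. Treatment
given for them is overtreatment. For a cohort of diagnosed women, write
$M$ for receipt of total mastectomy (simple or modified radical; the most
extensive first-course surgery recorded), $V$ for overdiagnosis, and $X$ for
the observed case characteristics. The estimand is the cohort proportion

$$\Pr(M, V) \;=\; \sum_{x_i} \Pr(M \mid V, X = x_i)\,
  \Pr(V \mid X = x_i)\, \Pr(X = x_i).$$

$V$ is never observed for an individual, so $\Pr(V \mid X)$ is unknown and
the estimand is not point identified. Two ingredients restore partial
identification:

1. **Exchangeability.** Nobody — patient, surgeon, pathologist — can tell an
   overdiagnosed case from a nonoverdiagnosed case with the same observed
   characteristics (if they could, the overdiagnosed one would not be
   treated). Hence $\Pr(M \mid V, X) = \Pr(M \mid \lnot V, X) =
   \Pr(M \mid X)$, which replaces the unobservable first factor by an
   estimable propensity.
2. **A constraint on the amount of overdiagnosis.** Assume a fraction
   $q$ of the full cohort is overdiagnosed. Then the unknown
   $\Pr(V \mid X = x_i) \in [0, 1]$ are free apart from their mean.

Maximizing/minimizing the sum over the feasible $\Pr(V \mid X)$ yields sharp
bounds. The optimum concentrates $\Pr(V\mid X) = 1$ on the cases with the
largest (upper bound) or smallest (lower bound) propensities — the *fill-up*
construction implemented in `bound_overtreatment()`.

A third ingredient sharpens the bounds considerably: cases with
characteristics incompatible with overdiagnosis (aggressive, advanced, or
imminently clinically evident disease) are *ruled out* first, and the assumed
proportion $q$ is rescaled to the eligible remainder,
$q_\text{eligible} = q \cdot n_\text{total} / n_\text{eligible}$
(`rescale_q()`; 30% of a cohort with 75% eligible means 40% of the eligible
cases). A $q$ exceeding the eligible fraction is inconsistent with the
criteria and is an error rather than a silent truncation.

## Tunable parameters

* **Rule-out thresholds** (`ruleout_criteria()`): ≥2 positive lymph nodes,
  tumour diameter ≥4.0 cm, fascia/muscle/chest-wall invasion, skin invasion
  with ulceration, distant metastasis. The node and size thresholds are
  deliberately permissive: a single positive node can be a false positive and
  a 2.0–3.9 cm tumour can occasionally be overdiagnosed, and classifying an
  overdiagnosis as ruled-out would break the validity of the bounds. The
  conservative direction is to rule out too little, which widens but never
  invalidates the interval. `alternative_criteria_sweep()` quantifies the
  effect of stricter choices (e.g. ≥1 node, ≥3.0 cm). Stage is *not* itself a
  rule-out field — exclusion operates on the underlying measurements — so
  stage-NA cases remain eligible while stage III/IV cases are removed via
  nodes, size and metastasis.
* **The overdiagnosis proportion q** (unitless fraction of the full cohort)
  is an *assumption*, swept over a grid. Its ceiling comes from incidence
  trends: if nonoverdiagnosed incidence has not fallen since the
  pre-screening era and screening drives essentially all overdiagnosis, then
  `q_max_from_incidence(rate_early, rate_late)` $= 1 -$ rate ratio. With the
  published age-standardized rates of 230.1 (1980) and 364.6 (2013) per
  100,000 this gives 37%; for DCIS (6.5 to 66.2) it gives 90%.
  `age_standardize()` accepts any standard-population weight vector — no
  particular standard is hard-coded, and pre-standardized rates can be passed
  directly.
* **Propensity model** (`model_spec()`): a probability random forest with
  2500 trees, $\lfloor\sqrt{p}\rfloor$ variables per split, Gini splitting,
  leaf size 1, untuned (so no tuning loop exists); or a cross-fitted
  logistic regression (K = 5); or the oracle pass-through on synthetic data.
  Honesty is non-negotiable: forest predictions are out-of-bag, logistic
  predictions are produced by a model that never saw the case's own outcome.
  The `n_random_splits` field (a cap on candidate splits for multivalue
  variables in some forest implementations) is recorded for provenance but is
  advisory — the ranger backend's Gini splitting has no equivalent control.
* **Sensitivity parameter Λ** (odds ratio ≥ 1): the largest factor by which
  omitted variables or informative missingness could shift any single case's
  mastectomy odds away from its estimate. Λ = 1 is the main analysis; the
  sweep default `c(1, 5, 25)` spans "one strong omitted determinant" to "two
  such variables combined".

## The sensitivity mechanism (a reconstruction)

The omitted-variable analysis is specified by two properties: predictions are
not systematically biased, but omitted information could increase their
*discrimination* while maintaining calibration. We implement the weakest
contract consistent with both: an adversary may replace each eligible
propensity $p_i$ by any $p_i^\*$ with
$|\mathrm{logit}\,p_i^\* - \mathrm{logit}\,p_i| \le \log\Lambda$, subject to
$\sum_i p_i^\* = \sum_i p_i$ (calibration *in the large*; a per-decile
constraint would be stronger and would narrow the intervals, so the global
version is the conservative reading). The fill-up bound is then computed on
the adversarial $p^\*$.

Because the per-case windows $[\mathrm{lo}_i, \mathrm{hi}_i]$ are monotone
transforms of $p_i$, the orderings of $p$, lo and hi coincide, and a
rearrangement argument shows the adversary's optimum keeps the same
extreme-propensity selection as the main analysis and *water-fills* the fixed
propensity mass into (upper bound) or out of (lower bound) the selected
cases. Each inner problem is a box LP with a single equality constraint,
solved exactly by greedy allocation; tests verify equality with an exhaustive
LP oracle on small instances. Consequences asserted by tests: Λ = 1
reproduces the main bounds exactly; intervals are nested in Λ; they are
capped within $[0, q]$; and as $\Lambda \to \infty$ the upper bound
approaches the mass-transport limit $\min(m, \sum_i p_i)/n$. Over equal
multiplicative steps of Λ the incremental widening *diminishes* (saturation
toward that cap) — so a moderate Λ already reveals most of the vulnerability,
and robustness claims should cite the absolute widening, which is monotone.
This mechanism is a documented reconstruction of the stated properties, not a
claim about any particular registry analysis' internals.

## Numerical choices

* **Fractional fill at the q boundary.** $m = q\,n_\text{total}$ is rarely an
  integer; the marginal case receives fractional overdiagnosis weight. This
  equals the LP relaxation over $\Pr(V\mid X) \in [0,1]$, makes both
  endpoints continuous, non-decreasing and 1-Lipschitz in $q$, and differs
  from integer assignment by $O(1/n)$.
* **Ties in propensities** cannot affect the bound values under the
  fractional formulation; the sort is nonetheless stabilized by `case_id` so
  per-case artifacts are byte-reproducible.
* **NA policy.** `"NA"` is an explicit category level everywhere: in the
  covariate schema (missingness can be informative of surgical choice, so
  nothing is imputed), in descriptive tables (an `NA` row with its own risk
  ratio), and in the rule-out logic (an unknown measurement never triggers a
  criterion — the conservative direction). Trend tests exclude the `NA`
  level, scoring the remaining ordered levels with consecutive integers.
* **Risk ratios** use unconditional maximum likelihood with the log-Wald CI
  $\exp(\log\mathrm{RR} \pm 1.96\sqrt{1/a - 1/n_1 + 1/b - 1/n_0})$; this
  convention reproduces published registry tables to their printed precision
  (checked in the tests against shipped marginal counts). Zero cells flag the
  CI undefined instead of fabricating one.
* **Outward rounding.** Reported percentage intervals floor the lower and
  ceil the upper endpoint (5.6–12.4 → 5–13), so presentation can only widen.
* **Large-sample plug-in.** The bounds are plug-in functionals of the
  propensity vector; no sampling CI is attached. Uncertainty is explored
  through the criteria sweep and the Λ analysis instead. At registry scale
  the plug-in error is dominated by those systematic terms.
* **Degenerate inputs.** $q = 0$ gives the point interval $[0, 0]$;
  single-class outcomes are an error for model fitting; an empty eligible set
  only admits $q = 0$.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws a one-row-per-patient case listing: age ≥ 40 with a
realistic age mix, ~21% in situ disease, log-normal tumour sizes, mostly
node-negative invasive disease, registry-style missingness in size, nodes,
grade and receptor status, nine catchment regions, and a race distribution
typical of US registries. Mastectomy is assigned by a logistic model whose
intercept is calibrated to a ~34% marginal rate, increasing in size and stage
and decreasing in age; about three quarters of cases survive the default
rule-out step. Overdiagnosis is assigned by a second logistic model
concentrated on early, small, node-negative, in situ patterns, and its
probability is *masked to zero* for any case meeting the rule-out criteria,
so the generator never contradicts the criteria's premise. With
`exchangeability_violation_delta = 0` (the shipped default,
`scenario_default.yaml`), surgery is conditionally independent of the latent
label given covariates — the key assumption holds *by construction*. A single
master seed drives fixed per-block sub-streams, so adding a covariate block
does not perturb the others, and runs are byte-reproducible.

Passing tests on this generator demonstrate that the estimator is correct
*under its assumptions*: the bounds cover the known truth across replicates,
the propensity model is honest, diagnostics behave. They do **not**
demonstrate that real registry data satisfy exchangeability, that 33
covariates capture surgical decision-making, or that real overdiagnosis
follows any particular covariate pattern. The
`exchangeability_violation_delta` dial and the omitted-covariate tests exist
precisely to probe failures of those assumptions. The generator makes no
claim to reproduce real SEER marginals or any published empirical bound;
first-of-multiple-primaries linkage and longitudinal screening histories are
out of scope (input is assumed one row per patient).

## Problem sizes used in the shipped checks

The default synthetic scenario uses 5,000 cases: large enough that the
eligible fraction, mastectomy rate and bounds are stable to a fraction of a
percentage point, small enough that a 2,500-tree leaf-size-1 probability
forest fits comfortably in memory. Coverage is assessed over 200 replicates
of 5,000 cases with the cross-fitted logistic family (the generating model is
itself logistic, so this also checks the well-specified case); oracle
equivalence is checked exhaustively at ≤ 12 eligible cases for the fill-up
bound and ≤ 10 for the sensitivity bound, where enumeration over subsets is
exact and fast. Forest-size robustness (half/double trees shifting the
shipped-scenario bounds by far less than one percentage point) is checked
once at 2,500 ± trees.

## Known limitations

* The rule-out criteria may misclassify some genuinely overdiagnosed cases in
  patients with short life expectancy whose tumours show advanced features;
  this biases the bounds toward understatement in the elderly.
* The incidence-trend ceiling for $q$ assumes negligible pre-screening-era
  overdiagnosis and non-decreasing background incidence; if either fails, the
  ceiling (and with it the upper bound at $q_\max$) is too low.
* Bounds describe the cohort proportion, not any individual's probability of
  having been overtreated, and carry no information about where within the
  interval the truth lies.
* The sensitivity mechanism is a reconstruction from stated properties
  (bounded per-case logit perturbation, preserved global mean); analyses that
  redistribute probability within strata instead would give different — under
  the arguments above, narrower or equal — intervals.
* The CSV reader deliberately does not parse native registry-export dialects;
  surgery coding is supplied as a configurable code map
  (`default_surgery_code_map()` covers the standard procedure classes).
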