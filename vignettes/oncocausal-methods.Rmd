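---
title: "Causal transportability and milestone treatment effects: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Causal transportability and milestone treatment effects: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oncocausal)
```

# The problem

A physician deciding whether to offer adjuvant pembrolizumab to a patient
with resected renal cell carcinoma (RCC) has, at best, three ingredients: a
randomized trial's hazard ratio (for RCC, KEYNOTE-564's HR of 0.68 for
disease-free survival, estimated exclusively in clear cell histology), a
prognostic nomogram that converts the patient's covariates into a baseline
milestone DFS probability, and biological knowledge about whether the
trial's relative effect plausibly applies to this patient at all. The
package operationalizes the chain that joins them:

1. **Selection diagrams** encode which variables shift between the trial
   population and the patient in clinic, and an *S-admissibility* check
   decides whether an adjustment set licenses transporting the trial's
   effect.
2. An **exponential milestone calculator** turns (baseline probability,
   milestone time, hazard ratio) into a treated probability and an absolute
   risk reduction (ARR).
3. A **potential-outcomes simulator** with IPTW estimators demonstrates,
   on synthetic cohorts with known truth, why randomization (or correct
   weighting) is what makes step 2's hazard ratio causally interpretable.
4. A **scenario pipeline** strings these together into per-patient
   recommendations with an ARR threshold and explicit "not estimable"
   outcomes.

# Graphs and the transport criterion

A `causal_graph` holds variable nodes and *selection nodes*. Selection
nodes are not variables: they are graphical markers whose outgoing arrows
flag variables whose distribution differs between populations. Arrows
*into* a selection node would encode sampling (selection) bias, a different
phenomenon; such documents are rejected at parse time, keeping the package
squarely in transportability territory.

## d-separation semantics

The blocking rules are full Pearl d-separation: a chain or fork is blocked
when its middle node is conditioned on; a collider blocks *unless* it or
one of its descendants is conditioned on. Informal statements of
"blocking regardless of arrow direction" omit the collider subtlety; we
implement the complete semantics deliberately, because conditioning on a
collider (or its descendant) genuinely opens a path, and the
S-admissibility search below depends on that behaviour — the test suite
contains a constructed counterexample where *enlarging* an adjustment set
destroys admissibility.

Two independent routes to the same criterion coexist in the package:

* the production implementation restricts the graph to the ancestors of
  the queried sets, moralizes (marries parents of common children), drops
  directions, deletes the conditioning set, and tests connectivity;
* the witness machinery (and the test-suite oracle) enumerates simple
  skeleton paths and applies the blocking rules edge by edge.

`s_admissible()` runs both — the verdict from the moral graph, the open
witness paths from enumeration — and refuses to return if they disagree.
Path enumeration is exponential in the worst case, so it guards on a
25-node budget; clinical diagrams are far below it.

## S-admissibility and its boundary choices

An adjustment set Z is S-admissible for treatment X and outcome Y when,
after deleting every arrow into X (the do-operator surgery), all selection
nodes are d-separated from Y given Z together with X. Design choices worth
recording:

* **Selection nodes are never adjustment variables.** They are not
  variables; they appear in queries only as path endpoints.
* **Descendants of treatment.** The back-door criterion
  (`satisfies_backdoor()`) vetoes adjustment sets containing descendants
  of treatment, as the criterion requires. For S-admissibility no such
  veto is applied: the criterion is stated purely as a d-separation
  property of the surgically modified graph, and the surgery already
  removes the arrows that make post-treatment adjustment hazardous in the
  back-door setting. The two functions therefore agree with each other
  only on adjustment sets free of treatment descendants, and the
  equivalence property in the test suite samples from that region.
* **Back-door paths for treatment sets** are taken to be simple paths that
  do not pass through other treatment nodes; the first edge must point
  into the treatment node.
* **Minimal-set search.** Because admissibility is not monotone, a set is
  inclusion-minimal only if *no* proper subset is admissible, so
  `minimal_admissible_sets()` examines every subset size in ascending
  order (exhaustive over at most 20 candidates) and ties are broken by
  cardinality, then lexicographic node order.
* **Figure fixtures** encode each shipped diagram exactly as drawn — for
  instance the two-mediator diagram keeps the arrows from the biomarkers
  into the treatment choice even though other diagrams randomize the
  treatment; fixtures are not harmonized with one another.

# The milestone calculator

An exponential (constant-hazard) model is the simplest time-to-event
distribution and the one implicitly assumed by a reported hazard ratio
with a single milestone probability: `S(t) = exp(-h t)`, mean `1/h`,
median `ln(2)/h`. Given a control milestone probability `S0` at `t` and a
hazard ratio `HR`,

```
h0 = -ln(S0) / t,   h1 = HR * h0,   S1 = exp(-h1 t) = S0^HR,
ARR = 100 * (S1 - S0)  [percentage points].
```

**Precision.** Published worked examples round the intermediate hazard
(0.03675, 0.02499) before re-exponentiating. The package computes at full
precision and rounds only at display; both routes agree to the one-decimal
percentages the examples print, and the tests assert those printed values
at ±0.1 point.

**Units.** Probabilities are fractions in (0, 1) everywhere in code;
percent is a display concern. ARR is reported in percentage points.

**Interval handling.** Trial hazard ratios come with confidence intervals,
but the decision chain propagates point estimates. `treated_milestone()`
optionally accepts the interval endpoints and reports the ARRs obtained by
plugging them in. This is labelled a naive plug-in range — it is not a
delta-method confidence interval, and the printed output says so.

```{r calculator}
treated_milestone(0.414, 24, 0.68, hr_ci = c(0.53, 0.87))
```

Calibration against six published adjuvant-trial arms (immune checkpoint,
chemotherapy and targeted agents) shows the one-parameter model predicts
reported treated-arm milestones within five percentage points:

```{r calibration}
adjuvant_calibration()[, c("label", "estimated_pct", "reported_pct",
                           "difference_pct")]
```

The signed difference column is computed between the one-decimal displays,
matching how such tables are read.

# The potential-outcomes simulator

Each simulated subject carries covariates `Z`, a true propensity
`e(Z) = Pr(X = 1 | Z)`, *both* potential outcomes, the assigned treatment
and the observed outcome. Consistency is structural (`y` is copied from
`y1` or `y0`), positivity is checked on every cohort, and SUTVA is encoded
as independence across subjects. The estimand is
`psi = E[Y^1] - E[Y^0]`, computed in closed form from each scenario's
configuration.

## What the shipped scenarios emulate — and what they do not

* `rct` / `rct_unbalanced`: coin-flip (or 2:1) assignment, a standard
  normal prognostic covariate, outcome on the log-survival-time scale with
  mean log time 3.3 (about 27 months, matching the hazards in the
  calculator examples) and treatment shift `tau = 0.3857 = -ln(0.68)`,
  the log-time displacement equivalent of hazard ratio 0.68; noise SD 0.8.
* `confounded`: binary prognosis (half the population each), treatment
  probability 0.7 for good and 0.3 for poor prognosis, prognosis effect
  0.9 on log time. The naive difference in means is biased by exactly
  `0.9 × (0.7 − 0.3) = 0.36` — a closed form the tests verify.
* `innocent_bystander`: an inert agent (`tau = 0`) given preferentially
  (0.75 vs 0.25) to good-prognosis patients; the naive comparison shows a
  spurious benefit of 0.5 while stratified and weighted analyses centre at
  zero.
* `milestone`: a binary 24-month DFS indicator with per-stratum hazards
  0.03675 and 0.0167 per month and hazard ratio 0.68, tying the simulator
  to the calculator's arithmetic.

These cohorts are deliberately idealized: no censoring, no measurement
error, exactly correct propensity model form, and independent potential
outcomes given covariates. Passing tests therefore demonstrate estimator
properties (unbiasedness, the Hajek/arm-means identity, bias reduction
with estimated propensities) under the assumptions, not robustness to
their violation in real registries.

## Estimators and numerical choices

* Horvitz–Thompson IPTW: mean of `y x / e − y (1 − x) / (1 − e)`;
  equals the difference of arm means exactly only when the realized arms
  balance. The Hajek variant normalizes weights within arms and equals the
  arm-mean difference for *any* realized allocation under a constant
  propensity; both are provided and the distinction is documented rather
  than resolved.
* Standard errors are empirical variances of per-subject contributions
  over the square root of n (linearized for Hajek); a seeded bootstrap is
  available for the Hajek variant.
* `estimate_propensity()` is a maximum-likelihood logistic fit with
  fitted probabilities clipped to [0.01, 0.99] by default (configurable);
  the clipped fraction is reported. Perfect separation raises a
  convergence error that advises the remedy rather than silently returning
  degenerate weights.
* Seeding: one integer seed drives three substreams (covariates,
  assignment, noise) via fixed offsets, so any cohort replays exactly.

# The scenario pipeline

`transport_route()` is a pure function of (histology, baseline presence):

* clear cell with a baseline estimate → **additive** route. No biological
  reason to expect effect modification, so the general
  risk-plus-effect-modification diagram collapses to the additive risk
  diagram (fixture `6A`; adjustment `{Z}` is verified S-admissible on
  every call).
* any other histology with a baseline → **effect_modified** (fixture
  `8A`, adjustment `{Z, B}`): the immune microenvironment mediates the
  treatment effect and differs by histology, so the trial's hazard ratio
  does not transport; a sensitivity grid of hypothetical hazard ratios is
  required.
* no baseline estimate → **not_estimable**: the gap is observational (a
  prognostic model covering the patient's features), not experimental.

**Grid reporting rule.** On the effect-modified route the report shows the
treated probability and ARR at the *largest* (most conservative) hazard
ratio in the grid. If even that conservative ARR clears the threshold, the
verdict is "plausible under sensitivity" — favourable under every
considered effect size, yet not formally estimable. If even the *smallest*
(best-case) hazard ratio fails the threshold, the treatment is not
recommended under any considered scenario. A straddling grid also yields
"do not recommend": without experimental data the conservative reading
governs. This single rule reproduces the three published off-trial
verdicts (papillary type I at HR 0.5, papillary type II at HR 0.84 —
stored with its construction `0.68 + (1 − 0.68)/2` in the fixture notes —
and chromophobe at HR 0.5).

**Threshold.** The default ARR threshold of 5 percentage points in
24-month DFS reflects a judgement about offsetting grade ≥3 toxicity
(18.9% vs 1.2% in the reference trial) and cost; no quantitative
toxicity-benefit trade-off is modelled, so the threshold stays a single
user-settable scalar. Raising it can only demote recommendations — a
monotonicity the tests assert.

**Baselines are inputs.** The pipeline never computes a baseline
probability: nomogram output enters as data, mirroring how the nomogram is
an external oracle. One bundled patient carries a nomogram value the
literature deems implausible (91.3% for sarcomatoid chromophobe disease,
against observational reports of under 50%); the fixture routes it to
"not estimable" with both external-data flags rather than propagate a
number nobody believes. Similarly, the first bundled patient's nomogram
display rounds to 41.1% while the decision chain uses 41.4%; the fixture
carries 0.414 and records the discrepancy in its notes.

```{r pipeline}
reports <- lapply(keynote564_patients(), evaluate_scenario)
cat(report_table(reports, format = "text"), sep = "\n")
```

# Problem sizes used in the checks

The test suite compares the moral-graph d-separation engine with the
path-enumeration oracle on 650 random DAGs of up to 8 nodes (150 in the
unit block, 500 in the acceptance block), validates the minimal-set search
against an exhaustive subset oracle on 12 random five-variable selection
diagrams, and exercises the estimators with 1000 replicate cohorts of
n = 500 for the known-propensity unbiasedness check plus 300 replicates
with estimated propensities. These sizes give Monte-Carlo standard errors
small enough to detect the designed biases (0.36 and 0.5) by an order of
magnitude while keeping the whole suite in the tens of seconds.

# Known limitations

* No identification algorithm: the package checks *given* adjustment sets
  (and searches candidate pools); it does not derive identification
  formulas, handle latent projections, counterfactual graphs or cyclic
  models.
* The calculator is exponential-only; no Weibull or Cox baseline, no
  fitting to time-to-event data. A reported hazard ratio plus one
  milestone is exactly the information it consumes.
* ARR uncertainty is the naive hazard-ratio-endpoint plug-in; proper
  interval propagation for the decision chain is future work.
* Overall survival, salvage-therapy confounding and dynamic regimes are
  out of scope; the outcome is a single milestone probability.
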