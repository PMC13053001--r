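---
title: "Modelling costs and waiting times of community teledermatology referral pathways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling costs and waiting times of community teledermatology referral pathways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermflow)
```

## The service being modelled

Urgent suspected skin cancer (USC, formerly "2-week wait") referrals in the
NHS are conventionally seen in a face-to-face (F2F) consultant clinic. In a
community-based store-and-forward teledermatology model, a Band 3 health
care assistant photographs the lesion at a community diagnostic centre
(a 20-minute appointment), a consultant dermatologist reviews the images
remotely (about 4.97 minutes), and the patient is then discharged, recalled
for a F2F follow-up, or listed for a diagnostic biopsy.

`dermflow` represents each service as an *arm* made of lettered pathways:

* intervention (teledermatology): **A** discharge after remote review,
  **B** F2F follow-up then discharge, **C** follow-up then biopsy,
  **D** direct biopsy, **E** biopsy scheduled but cancelled;
* comparator (standard care): **F** discharge after the F2F consultation,
  **G** biopsy after the consultation.

C, D and G are *biopsy-reliant*: they end in a histopathological diagnosis
before the result is communicated. The clinical meaning of B, C and D is
represented purely structurally (stage lists in the configuration); the
shipped interpretation is consistent with the ordering of the unit costs
(55 < 219 < 371 < 542 GBP) and is fully overridable. Routing is purely
probabilistic — no lesion-triage logic is modelled.

Two pathway distributions are shipped per arm, because the cost analysis
and the simulation of the evaluated service were based on different data
windows: `referral_distribution(arm, "cca")` (costing; the intervention
percentages sum to 99% as printed and are used without renormalisation)
and `referral_distribution(arm, "des")` (simulation).

## Cost comparison analysis

The mean direct cost per referral of an arm is the dot product of its
pathway proportions with the per-pathway unit costs,
$\bar{c} = \sum_i p_i c_i$, and the incremental saving is
$\Delta = \bar{c}_{\mathrm{comparator}} - \bar{c}_{\mathrm{intervention}}$
(positive = saving). With the shipped table this gives 261.49 − 213.25 =
48.24 GBP per referral.

```{r cost}
p <- cost_model_params()
arm_mean_cost(p$dist_comparator, p$unit_costs) -
  arm_mean_cost(p$dist_intervention, p$unit_costs)
```

**Probabilistic sensitivity analysis.** Only the existence of standard
errors on staff involvement is documented for the original analysis, not
their sizes. The default uncertainty specification is therefore: each
pathway unit cost is drawn from a normal distribution centred on its
baseline value with SE equal to 12% of the cost, truncated at zero;
pathway proportions are held fixed. This centres the PSA on the
deterministic estimate; with 1000 iterations the mean saving lands near
£48 with a 95% interval spanning roughly £0–£95, and a cost reduction is
observed in about 95% of iterations. Setting `psa_se_frac = 0` collapses
every iteration to the deterministic saving exactly, which the test suite
uses as an invariant. The CI is the 2.5/97.5 percentile interval.

**Deterministic sensitivity analysis.** `run_dsa()` re-evaluates the
deterministic saving with one parameter at each bound. Parameters are
addressed by label: a unit cost (`"unit_cost.G"`), the combined share of
biopsy-reliant pathways in an arm (`"biopsy_share.intervention"`, which
rescales within the biopsy and non-biopsy groups proportionally), or the
cohort size. A reported scenario in which offsetting all biopsies saves up
to £135 per referral cannot be reconstructed from the printed unit costs
alone (no replacement of the C/D costs by any cheaper pathway's cost
yields it), so it is left as a user-defined scenario rather than
hard-coded.

**Hypothesis test.** "Unpaired t test" is ambiguous; Welch's
unequal-variance variant is the default (`var_equal = TRUE` gives
Student's). Currency is reported to 2 decimal places; internal arithmetic
is unrounded.

## Discrete event simulation

Each referral is an agent. Arrivals over a 365-day horizon follow a
nonhomogeneous Poisson process with piecewise-constant monthly intensity
(`monthly_weights`, normalised to sum to 12; the default is uniform
because the seasonal profile of the original data is not published — a
12-weight vector is accepted in the configuration). Arrivals stop at day
365 but the simulation runs to drain, so every agent contributes to the
endpoint means; there is no warm-up discard, matching a service launched
from empty.

An agent's pathway determines an alternating sequence of *delays*
(unstaffed waits, lognormal by default) and *services* (staffed
activities). Services queue first-come first-served within a priority
class for a server of the required role. All referrals are USC, so a
single priority class is the default; the priority field is retained and
configurable. Staff work 08:30–18:30 on weekdays; at weekends
`floor(0.7 × count)` staff are available (the floor means a single-handed
service has no weekend cover), and GPs are never rostered at weekends.
Service durations are minutes-scale and assumed not to span a rota
window. Time is held internally in fractional days, and every endpoint
timestamp is measured from the patient's own referral instant.

Three endpoints are recorded: clinical diagnosis (end of the remote review
or F2F consultation), histopathological diagnosis (biopsy-reliant
pathways only; reported as absent, never zero, when no patients are
eligible), and diagnosis communication (pathway exit; letter, email,
telephone or F2F, drawn from a per-pathway method mix). The engine
pre-samples all patient-level randomness before the event loop, so a seed
fully determines the log and capacity changes leave the sampled histories
untouched — which is also what makes the congestion-monotonicity property
testable pathwise.

Assumptions inherited from the modelled service: 100% retention, no
no-shows, no mortality, capacity limited only by staff (no rooms or
equipment), fixed staffing levels. Staffing counts for the original
service are not published; the defaults are sized so that baseline
utilisation stays below about 0.2, and `check_utilization()` warns above
0.95. Annual volume defaults to 3000 referrals/arm/year (the comparator
cohort of 4011 referrals accrued over roughly 16 months), with the
intervention matched for comparability.

## Calibration to published aggregates

Stage-level delay distributions were never published; only aggregate
waiting times were ([`anchor_set()`]): per-arm clinical-diagnosis means
(7.38 / 17.29 d), histopathology means (66.42 / 129.21 d), weighted
communication means (18.97 / 73.16 d) and per-pathway communication means
(A = 8 d, combined C&D = 52.4 d, G = 131.1 d). Whether the per-pathway
means were inputs or outputs of the original simulation is ambiguous; they
are treated here as calibration anchors.

The missing pathway communication means follow from the weighted-average
identity: F = (73.16 − 0.48 × 131.1)/0.52 ≈ 19.68 d, and B ≈ 12.81 d with
the tie rule E = B (pathway E carries 1% of referrals, so the tie choice
is numerically negligible).

Analytic assignment then distributes each anchor over its chain: the
referral-to-triage delays sum to the clinical anchor minus staffed service
time (split 2:1 between image-capture wait and review wait in the
intervention); the intervention's communication delay is shared across
pathways at the pathway A margin, 8 − 7.38 = 0.62 d (the one free scale in
that arm — the comparator's communication delays are fully pinned by
19.68 − 17.29 and 131.1 − 129.21); and each pathway tail absorbs the rest
of its target, split across follow-up/biopsy/histopathology waits in fixed
ratios (0.15/0.35/0.5 for C, 0.4/0.6 for D, 0.35/0.65 for G) chosen to
place most of the biopsy-chain wait in the histopathology stage, the
documented bottleneck. All ratios are configurable and none is anchored
individually.

Under rota windows and queueing the analytic assignment leaves a small
positive bias (roughly 0.2–0.5 d per staffed stage), which
`calibrate_arm()` removes by simulation. Because every endpoint mean is
additive in its upstream delay means with unit slope, each iteration
simulates the arm, measures the group residuals (shared triage chain,
shared communication delay, per-pathway tails) and rescales each group's
means by a common factor absorbing its residual — a Newton step with a
known slope, which converges in one or two iterations and is preferred
here over bracketing a scale factor by bisection, which spends several
simulations locating what the additivity already gives. Residuals of
low-volume pathways are measured with appreciable Monte Carlo error, so
the replication count doubles each iteration (3, 6, 12) and a group is
accepted when its residual is within `tolerance` (0.1 d by default) or
twice its own simulation SE. Delay means are floored at 0.02 d; a
correction that hits the floor flags the target as infeasible.

One genuine inconsistency in the published aggregates: the intervention's
combined C&D communication mean (52.4 d) is *smaller* than its
histopathology mean (66.42 d), although communication follows
histopathology. No monotone configuration can satisfy both, so
calibration supports two profiles — `"communication"` anchors the C/D
chains at 52.4 d (used for communication-endpoint analyses) and
`"histopathology"` anchors them at 66.42 d (used for the histopathology
increment). Both endpoints are always reported independently and never
forced consistent. The comparator anchors are mutually consistent, so one
comparator configuration serves both profiles.

## Synthetic cohorts

`generate_cohort()` draws age from a normal distribution with mean 61.5
and SD 17.6 years truncated at 18 — the source cohort is adult USC
referrals, and no minimum age is published, so majority age is used —
and sex female with probability 0.575. The generator emulates the
published marginal demographics and pathway mix only: it does not model
lesion characteristics, comorbidity, correlation between age and pathway,
deprivation, or site effects. Passing tests therefore demonstrate that the
pipeline reproduces the published *aggregates* under the stated
assumptions, not that it would reproduce patient-level outcomes of any
real cohort; demographic-dependent quantities such as exact CI widths from
the original records are out of reach by construction.

## Numerical choices and degenerate inputs

* Delay family: lognormal with CV 0.5 by default (non-negative,
  right-skewed, a common choice for service waits); gamma and fixed are
  available. `cv = 0` is an exact point mass, and in that limit the
  communication method mix is made method-independent so a deterministic
  configuration is exactly reproducible.
* Event ties are broken by event creation order, which makes the engine
  deterministic and FCFS within identical timestamps.
* Replication seeds are derived from the master seed by one
  `sample.int()` draw; arms use independent streams (whether the original
  analysis used common random numbers across arms is unstated).
* Weighted SEs propagate as $\sqrt{\sum_i p_i^2 \mathrm{se}_i^2}$;
  incremental CIs use a normal approximation on combined SEs.
* An arm distribution must sum to 1 within 0.015 — wide enough to accept
  printed percentage tables that sum to 99% after rounding, which are
  then used as printed.
* Problem sizes used by the shipped analyses and the test suite: 1000 PSA
  iterations and five 1-year replications at 3000 referrals/arm/year
  (about 15,000 patients per arm pooled), the scale of the original
  evaluation.

## Known limitations

Histopathology processing is modelled as an unstaffed delay, so histology
capacity cannot itself congest; the per-communication-method delay means
are calibrated stand-ins (the original per-method table is not available);
staffing, seasonality and the biopsy-chain split ratios are defaults, not
published values; and the cost model is a cost comparison only — no
utilities, no cost-effectiveness ratio, and no false-negative or long-term
treatment costs, which the original analysis also excluded on both arms.
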