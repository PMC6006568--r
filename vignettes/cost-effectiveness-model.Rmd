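---
title: "A decision-tree cost-effectiveness model for emergency-department brief interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A decision-tree cost-effectiveness model for emergency-department brief interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicea)
```

## The evaluation problem

`bicea` models a screening-plus-brief-intervention programme for
substance use in emergency departments from a societal perspective
(provider costs plus patient out-of-pocket costs). Three strategies are
compared for every patient screened: a control condition (screening and
an information leaflet), a single motivational-interviewing session
(MI), and MI followed by four weekly problem-solving-therapy sessions
(MI-PST). Outcomes are mean reductions in ASSIST
substance-involvement scores and CES-D depression scores between
baseline and three-month follow-up, measured among follow-up completers
(an available-case analysis; no imputation). All costs and outcomes
fall within one year, so neither is discounted inside the model.

## Ingredients costing

Provider costs are entered as an ingredients ledger: one row per
resource with a unit cost, a quantity rule resolved against cohort
counts (per person screened, per enrolled participant, per counsellor,
lump sum), a variable/fixed class, and an allocation mode. Capital
outlays (counselling rooms, furniture, training) are annuitized: the
annual equivalent cost of an outlay $K$ with useful life $n$ years at
discount rate $r$ is $K / AF$ with

$$AF = \frac{1 - (1+r)^{-n}}{r}, \qquad AF \to n \text{ as } r \to 0.$$

The default rate is 3% per year, the conventional choice for
comparability across evaluations. The packaged ledger stores each
capital row in the form it was published — an already-annuitized annual
figure — but `cost_ledger()` equally accepts raw purchase prices
(`cost_form: raw-capital`) and annuitizes them on load. Useful lives in
the packaged configuration are 5 years for furniture, 20 for building
space, and 3 for counsellor training (retraining being expected within
three years). Money is kept at full precision internally and rounded
only in reports.

Two reading ambiguities in the published ledger are worth flagging. The
counselling-room row is read as the annual total across the three
facilities, not per facility: the per-facility reading overshoots the
reconstructed screening cost per participant by a wide margin. And the
supervisor fidelity-check row equals the counsellor salary row to the
cent (25,973.53), which looks like a typesetting duplication; both rows
are loaded as printed but are independent configuration entries, so
either can be changed without touching the other.

## Allocating costs to components

Direct items — screening tools, manuals, flyers — are charged to the
patients who consume them (the MI manual is charged to both arms that
receive an MI session, and the leaflet to all enrolled participants,
split by arm size). Every other cost is split across screening, MI and
MI-PST in proportion to counsellor patient-contact minutes: minutes per
session type times the number of sessions delivered. With the packaged
session profile this gives 27,360 / 3,390 / 16,930 minutes (57/7/36% of
47,680). Conservation holds exactly: component pools plus direct costs
sum to the ledger total.

Screening costs are then spread over *enrolled* participants — the
yield of screening — and charged equally to the three arms; each arm's
own pool is spread over its participants. Patient-borne costs
(transport at a mean US$0.96 per visit) attach only to MI-PST
participants, who must travel back weekly.

Capacity utilization compares delivered contact hours (47,680 minutes =
795 h) with available counsellor hours. Available hours are a
configuration input (4,905 h, equivalent to 5 counsellors spending 6 h
per day with patients over the delivery period including routine
leave); the package does not attempt to derive a working-day calendar
from a leave policy, which the source material does not give.

## The decision tree

Each strategy's tree has chance nodes for screening result
(`p_positive`), acceptance (`p_accept`) and — for MI-PST —
session-by-session attendance. Because the whole screening pool is
already loaded onto enrolled participants, screen-negative and refusing
patients carry zero *additional* cost and zero intervention effect at
their leaves; the accepted-patient leaf carries the per-enrolled
screening cost, the arm's direct items, counsellor time at the pooled
per-minute rate, and (MI-PST) per-visit patient costs. Rollback is the
probability-weighted sum over root-to-leaf paths.

Two modelling choices deserve emphasis:

* **Dropout handling (the strongest assumption).** MI-PST dropouts pay
  for the sessions they actually attended, with attendance branch
  probabilities taken from the observed retention counts
  (109 → 87 → 77 → 69 → 65), but they are assigned the arm's *completer*
  mean reduction, because no dropout-specific effect is observed. The
  expected attendance cost across branches reproduces the MI-PST cost
  pool exactly, so rollback conserves the costing.
* **Flow rounding.** The published per-screened-patient table is
  reproducible only with report-rounded flow probabilities (0.19,
  0.63); the exact count ratios (531/2736 = 0.194, 332/531 = 0.625)
  give values about 1.5% higher. Both conventions are first-class
  (`flow_mode = "rounded"` or `"exact"`); `"rounded"` is the default in
  the packaged replication configuration, while `"exact"` is the
  sensible choice for new analyses. A related oddity: the published
  report rounds 62.5% *up* to 63% but prints the 54.8% follow-up
  proportion as 54%; the model layer uses standard rounding throughout
  and only the report-level figure truncates.

ICERs are computed from unrounded expected values and only rounded for
display. The frontier routine orders strategies by expected cost,
removes strictly dominated options (no cheaper, no more effective),
then removes extendedly dominated ones until pairwise ICERs are
non-decreasing in effectiveness. With the packaged three-strategy
configuration extended dominance never triggers, but scenario sweeps
can create dominated orderings, so the logic is implemented and
property-tested against an independent greedy lower-convex-hull oracle.

## Sensitivity analysis

The one-way and scenario analyses vary three drivers, each reported as
incremental cost, incremental outcome and ICER versus control:

* **Screening positivity** and **acceptance**, each swung ±25%
  relative to base. Throughput scenarios scale the cohort counts from
  the base counts, so the identity scenario reproduces the base case to
  floating-point identity. The fixed cost base (counsellor salaries,
  supplies, capital) stays constant while patient numbers change —
  busier counsellors mean a smaller fixed-cost slice per patient —
  whereas variable costs are constant per patient and direct items
  follow their quantity rules.
* **Excess capacity**, swung −25% and to the zero-excess extreme.
  This is operationalized as higher patient throughput against the same
  fixed cost base: fixed pools are rescaled by
  $(1 - e_0)/(1 - e)$ for base excess $e_0$ and target $e$, so zero
  excess multiplies fixed unit costs by the base utilization (≈ 0.16).
  Total fixed spend is conserved — only its per-patient apportionment
  changes. The +25% swing (0.84 → 1.05) is infeasible, since excess
  capacity of one means no throughput at all; `one_way_series()`
  returns an `NA` row with a warning for such grid points and the
  standard suite omits it.
* **An extreme uptake scenario**: universal acceptance with full PST
  completion. Positivity stays at base — the analysis does not bundle a
  positivity change into the uptake scenario.

Probabilities pushed past one by a multiplier are clipped with a
warning. Numeric values for these scenarios are deliberately reported
by the package itself rather than compared against any published
figure; only the qualitative findings (zero excess gives the largest
cost savings; universal uptake lowers per-patient costs and raises
outcomes; lower positivity shrinks both incremental cost and effect and
worsens cost-effectiveness) are asserted in the tests.

## The synthetic cohort generator

`generate_cohort()` emulates the structure the analysis assumes, so the
pipeline can be exercised end-to-end without patient-level trial data:

* Screening positivity is drawn per patient; positives receive baseline
  scores inside the moderate/high ASSIST band of their primary
  substance (11–39 for alcohol, 4–39 for other drugs), negatives inside
  the low band, so classification consistency holds by construction.
* Scores are truncated normal. Published tables give means and SDs
  only, so the *latent* means are calibrated numerically (via the
  truncated-normal mean identity, and for follow-up scores by
  integrating the doubly truncated conditional over the baseline
  distribution) so that the *realized* truncated means equal the
  targets. This makes parameter recovery unbiased; realized SDs shrink
  somewhat under truncation, a documented approximation.
* Baseline–follow-up correlation is not reported in the source tables;
  the default of 0.5 is an assumption and is configurable.
* Loss to follow-up is missing-completely-at-random by default, with a
  missing-not-at-random knob (`followup_score_shift`) for robustness
  experiments. MI-PST attendance is sequential per-session retention
  fitted to the observed counts; the count data do not identify a
  richer mechanism.
* Transport costs are a mixture: 85% walk (zero cost), payers draw
  gamma costs per attended visit with the overall mean calibrated to
  US$0.96 per visit.

`strive_fixture()` is the deterministic counterpart: a patient-level
table whose aggregate counts equal the study flow *exactly* and whose
completer score summaries match the published means and SDs exactly by
two-point moment matching. Its scores are synthetic — two-point
distributions, not plausible patient trajectories — which is precisely
what makes it useful as a regression fixture and useless as data.

What passing tests on synthetic cohorts do and do not show: they verify
that the estimators recover the generating parameters and that the
pipeline's arithmetic is right; they cannot validate the behavioural
assumptions (dropout effects, correlation, attendance mechanism)
against real patients.

## Problem sizes and numerical choices

The test suite generates cohorts of up to 10,000 screened patients for
parameter recovery (within two standard errors, seed-fixed) and checks
the frontier against a brute-force hull oracle on 1,000 random
instances of up to six strategies; both complete in seconds. Annuity
identities are verified to 1e-9 relative over randomized inputs; the
identity scenario is checked to 1e-12. Ties on the frontier
(equal-cost, equal-effect strategies) are left on the frontier with an
undefined ICER flagged rather than broken arbitrarily; zero incremental
effect never emits an ICER.

## Known limitations

* The cost reconstruction carries ledger-reading assumptions (room
  cost per facility vs total; the duplicated supervisor row); headline
  per-participant figures reproduce to within ~2%, and the published
  "full completion" MI-PST average (US$184) is approximated at ≈ US$180
  from actual-attendance time shares.
* No cost-utility (QALY) extension, no probabilistic sensitivity
  analysis, no hypothesis testing on trial outcomes, and no modelling
  of high-risk referral costs — all outside the model's scope.
* Judgements about value for money require comparing the ICERs to an
  external willingness-to-pay threshold, which the package deliberately
  does not supply.
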