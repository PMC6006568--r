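# bicea

Decision-tree cost-effectiveness analysis of brief substance-use
interventions delivered in emergency departments.

## The problem

Emergency departments in resource-poor settings see a high volume of
patients whose injuries and illness are linked to alcohol and other drug
use. A screening-plus-brief-intervention programme puts lay counsellors in
the department to screen waiting patients with the ASSIST (Alcohol,
Smoking and Substance Involvement Screening Test), and offers those at
moderate or high risk either a single session of motivational
interviewing (MI) or MI followed by four weekly sessions of problem
solving therapy (MI-PST), against a control condition that receives an
information leaflet. Deciding whether such a programme is worth funding
requires an economic evaluation: what does each strategy cost per patient
screened, what reduction in substance-involvement (ASSIST) and depression
(CES-D) scores does it buy, and what is the price of each additional unit
of benefit?

`bicea` implements that evaluation as a reusable, testable pipeline:

* **Ingredients costing** — a ledger of unit costs and quantity rules
  (staff, supplies, capital), with capital outlays annuitized at a
  discount rate *r* over useful life *n* via the annuity factor
  `AF = (1 − (1+r)^−n) / r`, and currency conversion for ledgers priced
  in South African rand.
* **Time-share allocation** — counsellor patient-contact minutes per
  session type allocate all non-direct costs to the screening, MI and
  MI-PST components; direct items (screeners, manuals, flyers) are
  charged to the patients who consume them. Capacity utilization compares
  delivered contact hours with available counsellor hours.
* **Decision tree** — each strategy's chance structure over screening
  result, acceptance, and (for MI-PST) session-by-session attendance,
  rolled back to the expected cost `E[C] = Σ P(leaf)·c(leaf)` and
  expected effect per screened patient.
* **ICER frontier** — strategies ordered by expected cost, strictly and
  extendedly dominated options flagged, and the incremental
  cost-effectiveness ratio `ICER = ΔC / ΔE` computed against the
  preceding strategy on the frontier.
* **Sensitivity analysis** — one-way swings of screening positivity,
  acceptance and counselling excess capacity (±25%), plus extreme
  scenarios (universal acceptance with full completion; zero excess
  capacity), all re-deriving flow, pools, tree and comparisons.
* **Synthetic cohorts** — a patient-level generator (truncated-normal
  scores calibrated so the realized means hit the target summaries,
  sequential PST attendance, transport-cost mixtures) plus a
  deterministic moment-matched fixture, so the whole pipeline runs
  end-to-end without any trial data.

Everything takes and returns tidy data frames, so stages chain with the
pipe; results provide `tidy()`, `glance()` and `autoplot()` methods.

## Worked example

The packaged `strive_config()` encodes a three-facility South African
emergency-department study (2012/13 USD, converted at ZAR 10.3952 per
US$1): 2736 patients screened, 531 (19%) positive, 332 (63%) enrolled
into control/MI/MI-PST arms of 110/113/109.

```r
library(bicea)
report <- run_pipeline(strive_config())
print(report)
```

```
== Cost-effectiveness report ==

Counsellor time (minutes and share):
  component minutes share grand_total_minutes
1 screening   27360    57               47680
2 mi           3390     7               47680
3 mi_pst      16930    36               47680

Capacity: 795 of 4905 available hours (16%)

Average cost per participant (US$):
  arm     cost_screening cost_intervention cost_patient total
1 control           94.8              0.08         0     94.9
2 mi                94.8             34.6          0    129.
3 mi_pst            94.8            180.           2.62 277.

Expected cost / effect per screened patient and ICERs:
  scale: assist
  strategy  cost effect status      comparator delta_cost delta_effect  icer
1 control   11.4   0.88 on-frontier <NA>            NA           NA      NA
2 mi        15.5   0.92 on-frontier control          4.14         0.03  119.
3 mi_pst    33.2   1.06 on-frontier mi              17.7          0.14  129.
```

Reading this: counsellors spent 47,680 contact minutes, 57% of it
screening, using only 16% of their available time. Screening cost about
US$95 per enrolled participant and the MI session about US$35 more. Per
patient *screened*, expected costs are ≈ US$11/16/33 for
control/MI/MI-PST; each extra unit of ASSIST-score reduction costs
≈ US$119 moving from control to MI, and ≈ US$129 moving from MI to
MI-PST (≈ US$20 and US$33 on the CES-D depression scale). Sensitivity
scenarios come from `sensitivity_suite(strive_config())` or
`one_way_series()`; patient-level runs from
`run_pipeline(strive_config(), records = generate_cohort(cohort_params(), seed = 1))`.

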