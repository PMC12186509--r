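---
title: "Modelling the hospital and payer economics of all-virtual hospital-at-home care"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the hospital and payer economics of all-virtual hospital-at-home care}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vwecon)
```

## The problem

All-virtual hospital-at-home ("virtual ward") programs discharge acutely ill
patients home with oral or inhalational therapy, remote vital-sign monitoring
and daily virtual visits, in lieu of an inpatient stay. Clinically this
shortens length of stay; financially it cuts both ways. The hospital avoids
the *variable* cost of each inpatient bed-day, but it also forgoes the
revenue that the avoided or shortened admission would have generated — and
how much revenue depends entirely on who pays. `vwecon` implements this
cost-consequence model from both perspectives:

* **Hospital perspective** — a ledger of avoided variable costs, lost
  revenue by reimbursement mechanism, and program fixed costs, by payer
  class; scenario projections over payer mixes and variable-cost levels;
  break-even and reimbursement-neutrality solvers.
* **Payer perspective** — per-case cost with and without the program, with
  quality-of-life weighting, under a fixed program reimbursement, and the
  reimbursement threshold at which the payer is cost-neutral.

The base-case inputs are the first program year at a large urban safety-net
hospital: 876 patients, 3,504 avoided bed-days, $2,945 average variable cost
per bed-day, and $682,547 of program fixed costs ($518,000 staffing for 2.0
FTE nurses and 0.5 FTE hospitalist, plus $164,547 of durable medical
equipment).

## Hospital-perspective accounting

Each payer group g contributes one ledger row obeying the identity

$$\text{net}_g \;=\; \text{variable avoided}_g \;-\; \text{lost revenue}_g
\;-\; \text{fixed}_g,$$

and totals are component-wise sums, so the identity holds at every level.
Lost revenue is stored as a non-negative magnitude; the minus sign is a
display convention.

Fixed costs are allocated per capita: group g receives
$F \cdot n_g / N$ rounded to whole dollars, with a largest-remainder
correction so the allocation sums to $F$ exactly. This reproduces the
published fixed-cost cells to the dollar, including the Tricare/VA cell
whose raw share ($2{,}337.49) would otherwise round ambiguously.

```{r table1}
ledger <- la_general_ledger()
cohort_totals(ledger)[, c("net", "net_per_case")]
```

One numerical subtlety: the published group rows are individually rounded to
whole dollars, and their lost-revenue cells sum to $1 less than the
published total-row cell. `cohort_totals()` is a pure sum of its rows
(yielding $5,599,423 from the rounded rows), while `la_general_table1()`
also carries the published total-row input cells, whose identity yields the
published $5,599,422. Per-patient nets are unaffected ($6,392 either way).

### Lost-revenue rules

Revenue rules are per reimbursement mechanism, with all rate values
(contracting facts that vary by hospital) taken as configuration:

* **DRG-based (Medicare).** An admission crossing at least 2 midnights
  retains its case payment (base rate × DRG relative weight + DSH add-on).
  An avoided admission, or one shortened below 2 midnights, forfeits the
  case payment; avoided days additionally forgo the daily per-diem
  component. Midnights are counted as whole midnights crossed. For stays
  shortened but still ≥ 2 midnights, we model a residual per-diem loss of
  `per_diem × days_avoided`; setting `per_diem = 0` recovers the strict
  reading in which such stays lose nothing. The model exposes this as a
  parameter because payment practice differs by contract.
* **Per-diem (FFS Medicaid) and flat daily rate (commercial, Tricare/VA,
  out-of-plan managed care).** Lost revenue is simply rate × days avoided.
* **Capitated (in-plan managed care) and uninsured.** Admissions generate no
  revenue, so avoiding them loses none — these classes are where the program
  is unambiguously cost-saving, which is why the sign of the program's net
  effect is driven almost entirely by payer mix.

## Scenario engine

Scenario projections work from *per-patient rates* — each ledger component
divided by its group's patient count at full precision. Projection is
linear: class nets are `fraction × n × net_pp`. Three reference mixes are
built in (`standard_payer_mixes()`): the safety-net base case (1.6%
commercial incl. Tricare/VA, 13.8% Medicare, 77.2% Medicaid, 7.4%
uninsured), a typical US mix (45/35/10/10), and a halved-commercial,
tripled-Medicaid variant. For the third mix we use the fractions
{22.5, 17.5, 40, 20}% implied by the published scenario's dollar cells,
which conflict with that table's printed percent labels (30/30 for the last
two classes); the dollar cells are internally consistent and the labels are
not. The commercial scenario rate is the commercial-only per-patient rate;
the Tricare/VA grouping affects only count bucketing.

```{r table2}
rates <- scenario_rates(ledger)
project_mix(rates, standard_payer_mixes()$typical_us, 1000)
```

Variable-cost sensitivity multiplies only the variable-avoided component by
a factor (grid 0.5–1.5). Two solvers are closed-form, because the model is
linear:

* **Two-class break-even.** With only commercial (net < 0) and uninsured
  (net > 0) patients, total net is zero at
  $x = \dfrac{\text{net}_{unins}}{\text{net}_{unins}-\text{net}_{comm}}$
  — 29.6% commercial at base variable costs.
* **Reimbursement neutrality.** With relative payment weights w (default 1
  for commercial and Medicare, 0.5 for Medicaid, 0 for uninsured), the
  per-patient reimbursement restoring zero net is
  $R = \max(0, -\text{net})/(n \sum_c w_c m_c)$: $13,198 at the typical US
  mix, from $21,084 (variable costs 50% lower) to $5,312 (50% higher). A
  net-positive cohort (the safety-net mix) needs no reimbursement.

```{r neutrality}
neutrality_threshold_table(rates)
```

## Payer perspective

A hospitalization costs the payer side $T$ (modelled $20,000–$45,000),
split into hospital billing $H$ and lost productivity $W$ by a
constant-difference rule $H = (T+d)/2$, $W = (T-d)/2$ with $d = \$5{,}000$.
The literature base-case components (≈$16,900 billing, ≈$13,300 lost wages
and out-of-pocket costs, plus $200–$300 of urgent-care follow-up) motivate
the $5,000 difference; the constant-difference rule is the computational
definition because it is the unique linear family consistent with the
entire published grid of per-case cells across all six totals and all three
assumption sets. The ≈$400 gap between the narrative component sum and the
$30,000 base total (urgent-care costs in or out) is inherited from the
source and left unresolved; urgent-care cost is carried as metadata only.

With the program, the payer bears $(1-r_H)H + (1-r_W)W$ with base-case
reductions $r_H = 0.75$ (hospital billing; sensitivity 0.60–0.90) and
$r_W = 0.30$ (wage recovery; 0.15–0.45). Quality-of-life weighting divides
costs by the QoL score of the care setting: 0.7 (or 0.75) in hospital, 0.9
(or 0.85) at home — home care is both cheaper and higher-QoL, so adjusted
savings are larger.

Two orderings of reimbursement and QoL division are exposed explicitly
because the published tables use both: under a *fixed* reimbursement the
payment is added before the division, $(c_w + R)/q_1$; the *neutrality*
threshold equates quality-weighted totals, $R = T/q_0 - c_w/q_1$. Both
round-trip exactly ($c_w + R = T$; $c_w/q_1 + R = T/q_0$). One published
sensitivity row (90%/45% reductions with QoL 0.7/0.9) instead follows
$(T-c_w)/q_0$, inconsistent with the other three QoL rows of the same
tables; we implement the uniform formula and do not reproduce that row.

```{r table3}
payer_cost_table(total_costs = c(20000, 30000, 45000))
```

## Synthetic cohort generator

Patient-level data behind the base-case ledger are not published, so the
package generates synthetic encounters with the study year's statistical
structure, making the revenue rules and aggregation testable end-to-end.
Defaults are the study conditions: n = 876; payer fractions 13.8/77.2/1.3/
0.3/7.4%; mean 4 bed-days saved (truncated-normal, SD 2, rounded to whole
days); DRG relative weight lognormal with mean 1.27 and SD 0.66 (the
reported case-mix moments); 0.61 urgent-care visits per patient (Poisson);
and a 55% probability that enrollment precedes admission (ED 46% +
observation 8% + urgent care 2%), in which case the admission is avoided
entirely; otherwise the inpatient stay is shortened but kept ≥ 2 midnights.
The days-saved SD and the rate schedules are not published; SD 2 is our
choice of a realistic dispersion, and the default rates were set so cohort
expectations land near the ledger's per-patient magnitudes. Demographics
(age, sex) are cosmetic. All draws come from one seeded stream: identical
spec + seed gives byte-identical cohorts, and the caller's RNG state is
restored.

`calibrate_cohort_spec()` fits the generator to a target ledger in closed
form: class mean days = variable avoided per patient ÷ daily variable cost;
class daily rate = lost revenue per patient ÷ mean days; for Medicare the
expected DRG case payment (`avoid_prob × (base × E[w] + DSH)`) is
subtracted first and the residual per-diem fitted, erroring when the target
is infeasible (case payments alone exceed target losses). Because zero
truncation inflates the days mean, calibration stores the pre-truncation
draw mean whose truncated expectation equals the target (solved with
`uniroot` on the truncated-normal mean), so recovery is unbiased.

An exact-quota fixture mode assigns payer counts (and avoided-admission
counts within class) by largest remainder rather than sampling, for tests
that need the mix noise removed while keeping day/weight draws stochastic.

What passing tests show — and what they do not: the generator emulates
group-level financial structure (mix, days, case-mix, mechanism-specific
losses). It does not emulate diagnosis mix, within-class payer
heterogeneity, correlation between severity and days saved, or seasonal
enrollment, so end-to-end agreement with the ledger validates the
accounting pipeline, not any clinical claim about real cohorts.

## Numerical conventions and problem sizes

* All currency is carried at full double precision and rounded only at
  reporting boundaries, half away from zero ("half-up"), to whole dollars;
  percents likewise to whole points (break-even fractions to 0.1 pp). The
  published cells are whole dollars with up to ≈$40 of the source's own
  rounding noise in derived cells; scenario tests therefore use a ±$150
  per-cell band where cells are derived, and exact equality where verified.
* Fixed-cost allocation and payer quotas use largest-remainder from floors,
  ties by input order, guaranteeing exact sums.
* Degenerate inputs error early: empty cohorts, zero-patient groups in
  per-patient rates, factors ≤ 0, mixes not summing to 1, QoL scores
  outside (0, 1], neutrality with an all-zero weighted mix, break-even
  without a sign change.
* Law-of-large-numbers checks run at n = 10,000 with four replicate cohorts
  averaged, placing every asserted component's Monte-Carlo standard error
  at ≲ 0.9% against the 2% recovery band; the smallest classes (expected
  counts 130 and 30 at that n) are checked with a tight-dispersion spec
  instead, where the band is statistically meaningful. The full test suite
  runs in well under a minute.

## Known limitations

* Days saved enter group accounting only through dollar components; when
  printed dollars and printed bed-days disagree (3,504 × $2,945 ≠ the
  published variable-cost total), dollars govern and days are descriptive —
  per-group bed-day counts are not recoverable from the source.
* No bed-backfill revenue is imputed for freed capacity (a deliberately
  conservative, worst-case hospital stance), and Medicaid payment
  arrangements vary by state, limiting generalisability of the per-diem
  rule.
* The payer model has no QALY life-year accounting or discounting; QoL
  scores scale costs only.
* Matched-control construction, length-of-stay estimation and clinical
  outcomes are upstream inputs, out of scope here.
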