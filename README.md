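# vwecon — hospital and payer economics of all-virtual hospital-at-home care

All-virtual hospital-at-home ("virtual ward") programs replace inpatient
stays with remote monitoring and virtual visits. They reliably save
*variable* hospital costs — but they also destroy inpatient *revenue*, and
how much depends on who pays. A DRG-paying Medicare admission avoided is a
whole case payment forgone; a capitated or uninsured admission avoided loses
nothing. `vwecon` is a cost-consequence and budget-impact model of this
trade-off for health-services researchers, hospital finance teams and
payers, built around the first-year ledger of a large urban safety-net
hospital program (876 patients, 3,504 avoided bed-days).

The core accounting is a per-payer-group ledger obeying

    net_g = variable_avoided_g − lost_revenue_g − fixed_g

with fixed program costs allocated per capita (largest-remainder to whole
dollars), and mechanism-specific lost-revenue rules:

| mechanism | lost revenue for an avoided / shortened admission |
|---|---|
| DRG-based (Medicare) | base × DRG weight + DSH if < 2 midnights kept, plus per-diem × days avoided |
| per-diem (FFS Medicaid), flat daily rate (commercial, Tricare/VA) | rate × days avoided |
| capitated, uninsured | 0 |

On top of the ledger sit a scenario engine (payer-mix projections,
variable-cost sensitivity, closed-form break-even and
reimbursement-neutrality solvers), a payer-perspective per-case cost model
with quality-of-life weighting, and a seeded synthetic-cohort generator with
closed-form calibration so the whole pipeline is testable end-to-end without
patient-level data. See the vignette
(`vignettes/virtual-ward-economics.Rmd`) for the model details.

## Worked example

```r
library(vwecon)

ledger <- la_general_ledger()      # base-case ledger by payer class
dplyr::select(cohort_totals(ledger), -days_saved)
#> # A tibble: 1 × 7
#>   payer n_patients lost_revenue variable_avoided fixed_alloc     net net_per_case
#>   <chr>      <dbl>        <dbl>            <dbl>       <dbl>   <dbl>        <dbl>
#> 1 total        876      4025304         10307274      682547 5599423         6392
```

At its own safety-net payer mix (77% Medicaid, 7% uninsured) the hospital
nets about **$5.60 million**, or **$6,392 per enrolled patient**: avoided
variable costs ($10.31M) dwarf lost revenue ($4.03M) because most avoided
admissions paid little or nothing. Project the same per-patient rates onto
a typical US payer mix and the sign flips:

```r
rates <- scenario_rates(ledger)
project_mix(rates, standard_payer_mixes()$typical_us, 1000)
#>   payer      fraction n_patients        net net_dollars
#> 1 commercial     0.45        450 -11699550    -11699550
#> 2 medicare       0.35        350  -1450131.    -1450131
#> 3 medicaid       0.1         100    837958.      837958
#> 4 uninsured      0.1         100   1093388.     1093388
#> 5 total          1          1000 -11218336.   -11218336
```

A 1,000-patient program now *loses* about $11.22M, almost all of it
commercial lost revenue. The neutrality solver asks what per-patient
program reimbursement (full weight for commercial/Medicare, half for
Medicaid, none for uninsured) would make the hospital whole, across the
variable-cost sensitivity grid:

```r
neutrality_threshold_table(rates)
#>   factor reimbursement_per_patient
#> 1   0.5                      21084
#> 2   0.75                     17141
#> 3   1                        13198
#> 4   1.25                      9255
#> 5   1.5                       5312
```

**$13,198 per patient** at base variable costs — roughly half a typical
payer's cost of the hospitalization itself, which is why the payer-side
model (`payer_cost_table()`, `payer_neutrality_table()`) finds such a
payment leaves payers cost-neutral or better: without the program a
hospitalization costs payers $20,000–$45,000 per case, and with it 55–58%
less (more than 65% after quality-of-life weighting).

A thin CLI wraps the same functions (`inst/cli/vwecon`): subcommands
`reproduce-paper`, `ledger`, `mix-scenarios`, `breakeven`, `neutrality`,
`payer-costs`, `simulate`, configured by a YAML file
(`inst/extdata/default-config.yaml`).

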