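test_that("cohort generation is seed-deterministic and honors size and quota modes", {
  spec <- cohort_spec(n_patients = 300, seed = 42)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)

  other <- generate_cohort(spec, seed = 43)
  expect_false(identical(a, other))

  empty <- generate_cohort(cohort_spec(n_patients = 0))
  expect_equal(nrow(empty), 0)

  # byte-identical CSV under identical spec + seed
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(a, f1)
  write_cohort_csv(generate_cohort(spec), f2)
  expect_identical(readLines(f1), readLines(f2))

  # exact quota reproduces the study counts at the study size
  q <- generate_cohort(cohort_spec(n_patients = 876, exact_quota = TRUE,
                                   seed = 1))
  expect_equal(as.integer(table(q$payer)[table1_expected$payer]),
               table1_expected$n_patients)
})

test_that("multinomial payer counts land within sampling error of the study mix", {
  spec <- cohort_spec(n_patients = 876, seed = 2024)
  coh <- generate_cohort(spec)
  counts <- table(factor(coh$payer, levels = payer_levels()))
  expected <- 876 * spec$mix[payer_levels()]
  # 4 sigma binomial bands
  sigma <- sqrt(876 * spec$mix * (1 - spec$mix))[payer_levels()]
  expect_true(all(abs(counts - expected) <= 4 * sigma + 1))
  # structural invariants
  expect_true(all(coh$days_avoided >= 0))
  expect_true(all(coh$los_with_program <= coh$los_without_program))
  expect_true(all(coh$drg_weight > 0))
})

test_that("aggregation equals hand summation on a small cohort and keeps the ledger identity", {
  enc <- hand_cohort()
  sched <- hand_schedules()
  params <- cost_parameters()
  ledger <- aggregate_cohort(enc, params, sched)

  # brute-force oracle per class
  lost <- oracle_lost_revenue(enc, sched)
  for (p in unique(enc$payer)) {
    idx <- enc$payer == p
    row <- ledger[ledger$payer == p, ]
    expect_equal(row$n_patients, sum(idx))
    expect_equal(row$days_saved, sum(enc$days_avoided[idx]))
    expect_equal(row$lost_revenue, sum(lost[idx]))
    expect_equal(row$variable_avoided,
                 sum(enc$days_avoided[idx]) * params$daily_variable_cost)
  }
  expect_equal(ledger$net,
               ledger$variable_avoided - ledger$lost_revenue - ledger$fixed_alloc)
  expect_equal(sum(ledger$fixed_alloc), params$total_fixed)

  # all-uninsured cohort loses nothing
  unins <- patient_encounters(rep("uninsured", 5), 3:7, rep(0, 5))
  lu <- aggregate_cohort(unins, params, sched)
  expect_equal(lu$lost_revenue, 0)

  # zero-days cohort: variable avoided 0, net = -fixed
  still <- patient_encounters(rep("medicaid", 4), rep(0, 4), rep(0, 4))
  ls <- aggregate_cohort(still, params, sched)
  expect_equal(ls$variable_avoided, 0)
  expect_equal(ls$net, -ls$fixed_alloc)
})

test_that("calibration is closed-form feasible and errors on impossible targets", {
  spec <- cohort_spec()
  target <- la_general_ledger()
  fitted <- calibrate_cohort_spec(spec, target)

  rates <- per_case_rates(target)
  medi <- rates[rates$payer == "medicaid", ]
  target_days <- medi$variable_avoided_pp / 2945
  # draw mean is shifted below the target to undo the zero-truncation bias
  expect_lt(fitted$mean_days_saved[["medicaid"]], target_days)
  expect_lt(target_days - fitted$mean_days_saved[["medicaid"]], 0.5)
  expect_equal(fitted$rate_schedules$medicaid$rate,
               medi$lost_revenue_pp / target_days)

  # zero-lost target fits a zero rate
  z <- group_ledger("commercial", 10, lost_revenue = 0,
                    variable_avoided = 29450, fixed_alloc = 100)
  fz <- calibrate_cohort_spec(spec, z)
  expect_equal(fz$rate_schedules$commercial$rate, 0)

  # Medicare infeasible when expected DRG case payments exceed the target
  rich <- cohort_spec(rate_schedules = modifyList(
    default_rate_schedules(),
    list(medicare = medicare_rate_schedule(1e6, 0, 0))
  ))
  expect_error(calibrate_cohort_spec(rich, target), "infeasible Medicare")

  # uninsured cannot lose revenue
  bad <- group_ledger("uninsured", 5, lost_revenue = 100,
                      variable_avoided = 0, fixed_alloc = 0)
  expect_error(calibrate_cohort_spec(spec, bad), "cannot lose revenue")
})

test_that("a calibrated spec recovers target per-patient components at large n", {
  target <- la_general_ledger()
  # tight-dispersion spec: isolates the calibration identity from draw noise,
  # so the 2% band sits several standard errors out even for the smallest
  # class (tricare_va, expected count 30 at n = 10,000)
  spec <- cohort_spec(n_patients = 10000, sd_days = 0.25,
                      drg_weight_sd = 0.2, seed = 7, exact_quota = TRUE)
  fitted <- calibrate_cohort_spec(spec, target)
  coh <- generate_cohort(fitted)
  ledger <- aggregate_cohort(coh, cost_parameters(), fitted$rate_schedules)

  got <- per_case_rates(ledger)
  want <- per_case_rates(target)
  for (p in want$payer) {
    g <- got[got$payer == p, ]
    w <- want[want$payer == p, ]
    expect_lt(abs(g$variable_avoided_pp - w$variable_avoided_pp),
              0.02 * max(w$variable_avoided_pp, 1))
    expect_lt(abs(g$lost_revenue_pp - w$lost_revenue_pp),
              0.02 * max(w$lost_revenue_pp, 1))
  }
})

test_that("generated cohorts flow into the ledger and scenario engines without identity violations", {
  spec <- calibrate_cohort_spec(cohort_spec(n_patients = 876, seed = 11),
                                la_general_ledger())
  coh <- generate_cohort(spec)
  ledger <- aggregate_cohort(coh, cost_parameters(), spec$rate_schedules)
  expect_equal(ledger$net,
               ledger$variable_avoided - ledger$lost_revenue - ledger$fixed_alloc)
  tot <- cohort_totals(ledger)
  expect_equal(tot$net, sum(ledger$net))
  rates <- per_case_rates(ledger)
  expect_equal(rates$net_pp,
               rates$variable_avoided_pp - rates$lost_revenue_pp - rates$fixed_pp)

  # projecting per-patient rates equals summing patient-level nets
  lost <- patient_lost_revenue(coh, spec$rate_schedules)
  patient_net <- coh$days_avoided * 2945 - lost -
    cost_parameters()$total_fixed / nrow(coh)
  mix_hat <- payer_mix(setNames(ledger$n_patients / nrow(coh), ledger$payer))
  proj <- project_mix(rates, mix_hat, nrow(coh))
  # tolerance: fixed-cost allocation rounds to whole dollars per class
  expect_lt(abs(proj$net[proj$payer == "total"] - sum(patient_net)), 5)
})
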