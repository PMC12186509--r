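# Published base-case ledger cells, used across tests as frozen expectations.
table1_expected <- tibble::tibble(
  payer = c("medicare", "medicaid", "commercial", "tricare_va", "uninsured"),
  n_patients = c(121, 676, 11, 3, 65),
  lost_revenue = c(1876585, 1670311, 444152, 34256, 0),
  variable_avoided = c(1469533, 7861619, 166734, 48040, 761348),
  fixed_alloc = c(94279, 526714, 8571, 2337, 50646),
  net = c(-501331, 5664594, -285989, 11447, 710702),
  net_per_case = c(-4143, 8380, -25999, 3816, 10934)
)

# Small hand-built mixed cohort for brute-force oracles: one row per case of
# interest (avoided / shortened / zero-day; every mechanism).
hand_cohort <- function() {
  patient_encounters(
    payer = c("medicare", "medicare", "medicare", "medicaid", "medicaid",
              "commercial", "tricare_va", "uninsured", "uninsured", "medicaid"),
    los_without_program = c(4, 5, 3, 6, 0, 4, 5, 7, 0, 3),
    los_with_program    = c(0, 3, 2, 0, 0, 0, 2, 0, 0, 3),
    drg_weight = c(1.5, 1.0, 0.8, 1, 1, 1, 1, 1, 1, 1),
    flat_rate = 0,
    mechanism = c("drg_based", "drg_based", "drg_based", "per_diem", "per_diem",
                  "flat_daily_rate", "flat_daily_rate", "none", "none",
                  "capitated")
  )
}

hand_schedules <- function() {
  list(
    medicare = medicare_rate_schedule(6000, dsh_addon = 1000, per_diem = 800),
    medicaid = per_diem_rate(500),
    commercial = flat_daily_rate(2000),
    tricare_va = flat_daily_rate(1200)
  )
}

# Brute-force per-encounter lost revenue, written independently of the
# package's dispatch path (explicit per-row enumeration of the rules).
oracle_lost_revenue <- function(enc, sched) {
  vapply(seq_len(nrow(enc)), function(i) {
    row <- enc[i, ]
    days <- row$los_without_program - row$los_with_program
    switch(row$mechanism,
      drg_based = {
        s <- sched$medicare
        drg <- if (row$los_with_program < 2) {
          s$base_payment_rate * row$drg_weight + s$dsh_addon
        } else 0
        drg + s$per_diem * days
      },
      per_diem = sched[[row$payer]]$rate * days,
      flat_daily_rate = sched[[row$payer]]$rate * days,
      capitated = 0,
      none = 0
    )
  }, numeric(1))
}
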