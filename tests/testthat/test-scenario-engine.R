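base_rates <- scenario_rates(la_general_ledger())
mixes <- standard_payer_mixes()

test_that("payer mixes validate fractions and sums", {
  expect_error(payer_mix(c(commercial = 0.5, medicare = 0.4)), "sum to 1")
  expect_error(payer_mix(c(commercial = 1.2, medicare = -0.2)), "\\[0, 1\\]")
  expect_error(payer_mix(c(hmo = 1)), "unknown payer")
  for (m in mixes) expect_equal(sum(m), 1)
})

test_that("scaling variable costs touches only the variable component", {
  sc <- scale_variable_costs(base_rates, 1)
  expect_equal(sc$net_pp, base_rates$net_pp)

  sc5 <- scale_variable_costs(base_rates, 0.5)
  expect_equal(sc5$lost_revenue_pp, base_rates$lost_revenue_pp)
  expect_equal(sc5$fixed_pp, base_rates$fixed_pp)
  expect_equal(sc5$variable_avoided_pp, base_rates$variable_avoided_pp / 2)
  # commercial per-patient net at half variable costs
  expect_equal(round_dollar(sc5$net_pp[sc5$payer == "commercial"]), -33578)
  expect_error(scale_variable_costs(base_rates, 0), "positive")
})

test_that("mix projection reproduces the published typical-mix cells", {
  proj <- project_mix(base_rates, mixes$typical_us, 1000)
  cell <- function(p) proj$net_dollars[proj$payer == p]
  expect_equal(cell("medicare"), -1450131)
  expect_equal(cell("medicaid"), 837958)
  expect_equal(cell("uninsured"), 1093388)
  # commercial and total carry the source table's own rounding noise
  expect_equal(cell("commercial"), -11699547, tolerance = 5 / 11699547)
  expect_equal(cell("total"), -11218333, tolerance = 5 / 11218333)

  # scaled cells within the stated per-cell tolerance of the printed grid
  printed <- list(
    "0.5" = c(commercial = -15110015, medicare = -3575489,
              medicaid = 256477, uninsured = 507736),
    "0.75" = c(commercial = -13404781, medicare = -2512810,
               medicaid = 547217, uninsured = 800562),
    "1.25" = c(commercial = -9994314, medicare = -387452,
               medicaid = 1128698, uninsured = 1386124),
    "1.5" = c(commercial = -8289080, medicare = 675227,
              medicaid = 1419438, uninsured = 1679040)
  )
  for (f in names(printed)) {
    pf <- project_mix(scale_variable_costs(base_rates, as.numeric(f)),
                      mixes$typical_us, 1000)
    for (p in names(printed[[f]])) {
      expect_lt(abs(pf$net_dollars[pf$payer == p] - printed[[f]][[p]]), 150)
    }
  }
})

test_that("mix projection is linear in cohort size and mix fractions", {
  p1 <- project_mix(base_rates, mixes$typical_us, 1000)
  p2 <- project_mix(base_rates, mixes$typical_us, 2000)
  expect_equal(p2$net, 2 * p1$net)
  p0 <- project_mix(base_rates, mixes$typical_us, 0)
  expect_equal(p0$net, rep(0, 5))

  # total is the mix-weighted combination of pure single-class cohorts
  pures <- vapply(c("commercial", "medicare", "medicaid", "uninsured"),
    function(p) {
      m <- setNames(as.numeric(p == c("commercial", "medicare", "medicaid",
                                      "uninsured")),
                    c("commercial", "medicare", "medicaid", "uninsured"))
      proj <- project_mix(base_rates, payer_mix(m), 1000)
      proj$net[proj$payer == "total"]
    }, numeric(1))
  combo <- sum(pures * as.numeric(mixes$typical_us))
  expect_equal(combo, p1$net[p1$payer == "total"])
})

test_that("two-class break-even fraction matches published values and verifies as a root", {
  expect_equal(round_half_up(100 * breakeven_commercial_fraction(base_rates), 1),
               29.6)
  expect_equal(round_half_up(100 * breakeven_commercial_fraction(base_rates, 0.5), 1),
               13.1)

  grid <- c(0.5, 0.75, 1, 1.25, 1.5)
  fracs <- vapply(grid, function(f) breakeven_commercial_fraction(base_rates, f),
                  numeric(1))
  expect_equal(round_half_up(100 * fracs, 1), c(13.1, 21.2, 29.6, 38.4, 47.7))
  # strictly increasing in the variable-cost factor
  expect_true(all(diff(fracs) > 0))

  # root verification: evaluating the two-class mix at x gives |net| < $1/1000
  for (i in seq_along(grid)) {
    sc <- scale_variable_costs(base_rates, grid[i])
    nets <- setNames(sc$net_pp, sc$payer)
    total <- 1000 * (fracs[i] * nets["commercial"] +
                       (1 - fracs[i]) * nets["uninsured"])
    expect_lt(abs(total), 1)
  }

  # symmetry: +x and -x nets break even at 50%
  sym <- tibble::tibble(
    payer = c("commercial", "uninsured"),
    variable_avoided_pp = c(0, 200), lost_revenue_pp = c(100, 0),
    fixed_pp = c(0, 100), net_pp = c(-100, 100)
  )
  expect_equal(breakeven_commercial_fraction(sym), 0.5)

  # no interior root when both classes have the same sign
  pos <- sym
  pos$net_pp <- c(50, 100)
  pos$lost_revenue_pp <- c(0, 0)
  pos$variable_avoided_pp <- c(50, 200)
  expect_error(breakeven_commercial_fraction(pos), "no break-even")
})

test_that("hospital-neutrality reimbursement hits published thresholds and round-trips to zero net", {
  R <- hospital_neutrality_reimbursement(base_rates, mixes$typical_us)
  expect_equal(round_dollar(R), 13198)
  expect_equal(round_dollar(hospital_neutrality_reimbursement(
    base_rates, mixes$typical_us, factor = 0.5)), 21084)
  expect_equal(round_dollar(hospital_neutrality_reimbursement(
    base_rates, mixes$typical_us, factor = 1.5)), 5312)

  # net-positive cohort needs no reimbursement
  expect_equal(hospital_neutrality_reimbursement(base_rates, mixes$la_general), 0)

  # round-trip: adding R * weight per patient restores total net to 0 +/- $1
  w <- neutrality_weights()
  for (f in c(0.5, 1, 1.5)) {
    Rf <- hospital_neutrality_reimbursement(base_rates, mixes$typical_us,
                                            factor = f)
    proj <- project_mix(scale_variable_costs(base_rates, f),
                        mixes$typical_us, 1000)
    total <- proj$net[proj$payer == "total"]
    revenue <- 1000 * sum(w * as.numeric(mixes$typical_us)) * Rf
    expect_lt(abs(total + revenue), 1)
  }

  # unreachable when nobody pays
  w0 <- neutrality_weights(0, 0, 0, 0)
  expect_error(
    hospital_neutrality_reimbursement(base_rates, mixes$typical_us, w0),
    "unreachable"
  )
})

test_that("scenario table covers all mixes, factors, and break-even rows", {
  tab <- mix_scenario_table(base_rates, mixes, c(0.5, 1), n_total = 1000)
  expect_setequal(unique(tab$scenario),
                  c(names(mixes), "breakeven_two_class"))
  expect_equal(sum(tab$scenario == "breakeven_two_class"), 4)
  be <- tab[tab$scenario == "breakeven_two_class" & tab$factor == 1, ]
  expect_equal(sort(be$percent), sort(c(29.6, 70.4)))
  # complementary percentages sum to 100
  expect_equal(sum(be$percent), 100)
})
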