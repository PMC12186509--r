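#' Payer-perspective model assumptions
#'
#' Parameters of the payer-perspective per-case cost model. A hospitalization
#' costs the payer side `total_cost` (hospital billing plus patient/caregiver
#' lost wages and out-of-pocket costs). The split of that total is governed by
#' a constant difference `split_difference`: hospital billing exceeds lost
#' productivity by exactly that amount at every total (the base-case
#' literature components, about $16,900 billing and $13,300 lost wages at a
#' $30,000 total, motivate the $5,000 default). The program reduces hospital
#' billing by fraction `hosp_reduction` (base 0.75, sensitivity 0.60–0.90) and
#' recovers fraction `wage_recovery` of lost wages (base 0.30, sensitivity
#' 0.15–0.45). Quality-of-life scores divide costs: `qol_hospital` (0.7 or
#' 0.75) for in-hospital care, `qol_home` (0.9 or 0.85) for home care.
#' Urgent-care follow-up costs ($213–$321 per visit) are carried as metadata;
#' they are part of the narrative base-case total, not a separate table term.
#'
#' @param total_cost payer cost of one hospitalization without the program,
#'   USD (modelled range 20,000–45,000).
#' @param split_difference hospital billing minus lost productivity, USD.
#' @param hosp_reduction fraction of hospital billing avoided by the program.
#' @param wage_recovery fraction of lost wages/out-of-pocket costs recovered.
#' @param qol_hospital,qol_home quality-of-life scores (0 = death,
#'   1 = normal function).
#' @param urgent_care_cost USD per urgent-care visit (metadata, range).
#' @return a `payer_assumptions` list.
#' @export
payer_assumptions <- function(total_cost = 30000, split_difference = 5000,
                              hosp_reduction = 0.75, wage_recovery = 0.30,
                              qol_hospital = 0.7, qol_home = 0.9,
                              urgent_care_cost = c(213, 321)) {
  assert_nonneg(total_cost)
  assert_nonneg(split_difference)
  assert_scalar_prob(hosp_reduction)
  assert_scalar_prob(wage_recovery)
  if (qol_hospital <= 0 || qol_home <= 0 || qol_hospital > 1 || qol_home > 1) {
    stop("quality-of-life scores must lie in (0, 1]", call. = FALSE)
  }
  if (qol_hospital > qol_home) {
    stop("`qol_hospital` cannot exceed `qol_home`: home care is the ",
         "higher-quality state in this model", call. = FALSE)
  }
  if (any(total_cost <= split_difference)) {
    stop("`total_cost` must exceed `split_difference`", call. = FALSE)
  }
  structure(
    list(
      total_cost = total_cost, split_difference = split_difference,
      hosp_reduction = hosp_reduction, wage_recovery = wage_recovery,
      qol_hospital = qol_hospital, qol_home = qol_home,
      urgent_care_cost = urgent_care_cost
    ),
    class = "payer_assumptions"
  )
}

#' Split a total payer cost into hospital billing and lost productivity
#'
#' Constant-difference split: `H = (T + d) / 2`, `W = (T - d) / 2`, so that
#' `H + W = T` and `H - W = d` at every total.
#'
#' @param total_cost T, USD (vectorised).
#' @param split_difference d, USD.
#' @return tibble with columns `hospital_billing` and `lost_productivity`.
#' @export
#' @examples
#' split_total_cost(30000, 5000) # 17500 / 12500
split_total_cost <- function(total_cost, split_difference = 5000) {
  assert_nonneg(total_cost)
  assert_nonneg(split_difference)
  if (any(total_cost <= split_difference)) {
    stop("`total_cost` must exceed `split_difference`", call. = FALSE)
  }
  tibble::tibble(
    hospital_billing = (total_cost + split_difference) / 2,
    lost_productivity = (total_cost - split_difference) / 2
  )
}

#' Payer cost per case with the program
#'
#' With the program, the payer side bears `(1 - hosp_reduction)` of hospital
#' billing and `(1 - wage_recovery)` of lost productivity:
#' `cost_with = (1 - rH) * H + (1 - rW) * W`.
#'
#' @param a [payer_assumptions()]; `total_cost` may be a vector.
#' @return USD per case, full precision.
#' @export
#' @examples
#' payer_cost_with_program(payer_assumptions(total_cost = 20000)) # 8375
payer_cost_with_program <- function(a) {
  s <- split_total_cost(a$total_cost, a$split_difference)
  (1 - a$hosp_reduction) * s$hospital_billing +
    (1 - a$wage_recovery) * s$lost_productivity
}

#' Quality-of-life cost adjustment
#'
#' Expresses a cost per unit of quality of life by dividing it by the QoL
#' score of the care setting (without-program costs by the hospital score,
#' with-program costs by the home score).
#'
#' @param cost USD (vectorised).
#' @param q QoL score in (0, 1].
#' @return quality-adjusted cost, USD.
#' @export
qol_adjust <- function(cost, q) {
  if (any(q <= 0)) stop("QoL score must be positive", call. = FALSE)
  cost / q
}

#' Payer cost per case under a fixed program reimbursement
#'
#' Adds a per-case program reimbursement R to the with-program cost. In the
#' quality-adjusted variant the reimbursement is added before the QoL
#' division (the payment buys the home-care episode, so it is scaled by the
#' same home QoL score).
#'
#' @param a [payer_assumptions()].
#' @param reimbursement R, USD per case (>= 0).
#' @return tibble with `unadjusted` and `qol_adjusted` costs (full precision).
#' @export
#' @examples
#' payer_cost_with_reimbursement(payer_assumptions(total_cost = 20000), 15000)
payer_cost_with_reimbursement <- function(a, reimbursement) {
  assert_nonneg(reimbursement)
  base <- payer_cost_with_program(a)
  tibble::tibble(
    unadjusted = base + reimbursement,
    qol_adjusted = (base + reimbursement) / a$qol_home
  )
}

#' Reimbursement threshold for payer cost neutrality
#'
#' The per-case reimbursement at which the payer is indifferent between the
#' program and an ordinary hospitalization. Unadjusted:
#' `R = T - cost_with`. Quality-adjusted, the comparison is between
#' quality-weighted costs, and the reimbursement enters after the QoL
#' division: `R = T / q_hospital - cost_with / q_home`. Both forms satisfy
#' the round-trip `cost_with(+R) = comparison cost` exactly.
#'
#' @param a [payer_assumptions()].
#' @param qol_adjusted logical; quality-adjusted threshold?
#' @return tibble with `reimbursement` (USD, full precision) and
#'   `percent_of_cost` (share of the matching without-program cost, rounded
#'   to whole percent).
#' @export
#' @examples
#' payer_neutrality_reimbursement(payer_assumptions(total_cost = 20000)) # 11625 (58)
payer_neutrality_reimbursement <- function(a, qol_adjusted = FALSE) {
  with_prog <- payer_cost_with_program(a)
  if (qol_adjusted) {
    without <- a$total_cost / a$qol_hospital
    r <- without - with_prog / a$qol_home
  } else {
    without <- a$total_cost
    r <- without - with_prog
  }
  tibble::tibble(
    reimbursement = r,
    percent_of_cost = round_half_up(100 * r / without)
  )
}

#' Percent change of with-program vs without-program cost
#'
#' `100 * (cost_with / cost_without - 1)`, rounded to the nearest whole
#' percent (half away from zero), negative when the program saves money.
#'
#' @param cost_with,cost_without USD per case; `cost_without` must be > 0.
#' @return signed whole percent.
#' @export
#' @examples
#' savings_percent(8375, 20000) # -58
savings_percent <- function(cost_with, cost_without) {
  if (any(cost_without <= 0)) {
    stop("`cost_without` must be positive", call. = FALSE)
  }
  round_half_up(100 * (cost_with / cost_without - 1))
}

#' Payer-perspective cost table (base-case layout)
#'
#' Reproduces the base-case payer table: with-program cost per case, with and
#' without QoL adjustment; the same under a fixed per-case reimbursement; and
#' the payer-neutrality reimbursement thresholds. Each cell carries the
#' whole-dollar value and the percent change against the matching
#' without-program cost (T unadjusted, T / q_hospital quality-adjusted);
#' neutrality rows report the threshold and its percent of that cost.
#'
#' @param total_costs grid of without-program totals, USD.
#' @param a [payer_assumptions()] providing all other parameters.
#' @param reimbursement fixed per-case reimbursement block, USD.
#' @return long tibble with columns `block`, `adjustment`, `total_cost`,
#'   `value` (whole dollars) and `percent`.
#' @export
payer_cost_table <- function(total_costs = seq(20000, 45000, by = 5000),
                             a = payer_assumptions(),
                             reimbursement = 15000) {
  rows <- lapply(total_costs, function(T) {
    ai <- payer_assumptions(
      total_cost = T, split_difference = a$split_difference,
      hosp_reduction = a$hosp_reduction, wage_recovery = a$wage_recovery,
      qol_hospital = a$qol_hospital, qol_home = a$qol_home,
      urgent_care_cost = a$urgent_care_cost
    )
    cw <- payer_cost_with_program(ai)
    cw_q <- qol_adjust(cw, ai$qol_home)
    without_q <- qol_adjust(T, ai$qol_hospital)
    reimb <- payer_cost_with_reimbursement(ai, reimbursement)
    neu <- payer_neutrality_reimbursement(ai, qol_adjusted = FALSE)
    neu_q <- payer_neutrality_reimbursement(ai, qol_adjusted = TRUE)
    tibble::tibble(
      block = rep(c("no_reimbursement", "fixed_reimbursement", "neutrality"),
                  each = 2),
      adjustment = rep(c("unadjusted", "qol_adjusted"), times = 3),
      total_cost = T,
      value = round_dollar(c(cw, cw_q, reimb$unadjusted, reimb$qol_adjusted,
                             neu$reimbursement, neu_q$reimbursement)),
      percent = c(
        savings_percent(cw, T), savings_percent(cw_q, without_q),
        savings_percent(reimb$unadjusted, T),
        savings_percent(reimb$qol_adjusted, without_q),
        neu$percent_of_cost, neu_q$percent_of_cost
      )
    )
  })
  dplyr::bind_rows(rows)
}

#' Payer-neutrality sensitivity table
#'
#' Neutrality reimbursement thresholds across assumption sets: for each
#' (hospital-reduction, wage-recovery) pair, the unadjusted threshold and the
#' quality-adjusted thresholds for each QoL score pair.
#'
#' @param total_costs grid of without-program totals, USD.
#' @param reduction_sets list of `c(hosp_reduction, wage_recovery)` pairs.
#' @param qol_pairs list of `c(qol_hospital, qol_home)` pairs.
#' @param split_difference USD, as in [payer_assumptions()].
#' @return long tibble: `hosp_reduction`, `wage_recovery`, `adjustment`,
#'   `total_cost`, `value` (whole dollars), `percent`.
#' @export
payer_neutrality_table <- function(total_costs = seq(20000, 45000, by = 5000),
                                   reduction_sets = list(c(0.60, 0.15), c(0.90, 0.45)),
                                   qol_pairs = list(c(0.7, 0.9), c(0.75, 0.85)),
                                   split_difference = 5000) {
  rows <- list()
  for (set in reduction_sets) {
    for (T in total_costs) {
      a0 <- payer_assumptions(
        total_cost = T, split_difference = split_difference,
        hosp_reduction = set[1], wage_recovery = set[2]
      )
      neu <- payer_neutrality_reimbursement(a0, qol_adjusted = FALSE)
      rows[[length(rows) + 1]] <- tibble::tibble(
        hosp_reduction = set[1], wage_recovery = set[2],
        adjustment = "unadjusted", total_cost = T,
        value = round_dollar(neu$reimbursement), percent = neu$percent_of_cost
      )
      for (q in qol_pairs) {
        aq <- payer_assumptions(
          total_cost = T, split_difference = split_difference,
          hosp_reduction = set[1], wage_recovery = set[2],
          qol_hospital = q[1], qol_home = q[2]
        )
        neu_q <- payer_neutrality_reimbursement(aq, qol_adjusted = TRUE)
        rows[[length(rows) + 1]] <- tibble::tibble(
          hosp_reduction = set[1], wage_recovery = set[2],
          adjustment = sprintf("qol_%s_vs_%s", q[1], q[2]), total_cost = T,
          value = round_dollar(neu_q$reimbursement),
          percent = neu_q$percent_of_cost
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}
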