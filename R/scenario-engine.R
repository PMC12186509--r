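#' Payer mixes
#'
#' A payer mix is a set of admission fractions over the four scenario payer
#' classes (Tricare/VA patients are grouped with commercial for scenario
#' purposes). Fractions must lie in \[0, 1\] and sum to 1 within 1e-9.
#'
#' @param fractions named numeric vector of fractions by payer class.
#' @return a validated named numeric vector of class `payer_mix`.
#' @export
#' @examples
#' payer_mix(c(commercial = 0.45, medicare = 0.35, medicaid = 0.10, uninsured = 0.10))
payer_mix <- function(fractions) {
  if (is.list(fractions)) fractions <- unlist(fractions)
  bad <- setdiff(names(fractions), payer_levels())
  if (length(bad)) {
    stop("unknown payer class(es) in mix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (any(fractions < 0 | fractions > 1)) {
    stop("mix fractions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("mix fractions must sum to 1 (got ", format(sum(fractions)), ")",
         call. = FALSE)
  }
  structure(fractions, class = "payer_mix")
}

#' Named scenario payer mixes
#'
#' Three reference mixes: the study hospital's own (safety-net) mix with
#' Tricare/VA folded into commercial; a typical US mix (45% commercial, 35%
#' Medicare, 10% Medicaid, 10% uninsured, from national inpatient-day
#' analyses); and a halved-commercial/Medicare, tripled-Medicaid/self-pay
#' variant \{22.5, 17.5, 40, 20\}% whose fractions are those implied by the
#' published scenario's dollar cells.
#'
#' @return named list of `payer_mix` objects.
#' @export
standard_payer_mixes <- function() {
  list(
    la_general = payer_mix(c(
      commercial = 0.016, medicare = 0.138, medicaid = 0.772, uninsured = 0.074
    )),
    typical_us = payer_mix(c(
      commercial = 0.45, medicare = 0.35, medicaid = 0.10, uninsured = 0.10
    )),
    half_commercial_triple_medicaid = payer_mix(c(
      commercial = 0.225, medicare = 0.175, medicaid = 0.40, uninsured = 0.20
    ))
  )
}

#' Relative reimbursement weights for hospital neutrality
#'
#' A candidate program reimbursement pays the full per-patient amount for
#' commercial and Medicare patients, half for Medicaid, and nothing for
#' uninsured patients.
#'
#' @param commercial,medicare,medicaid,uninsured weights in \[0, 1\].
#' @return named numeric vector of weights.
#' @export
neutrality_weights <- function(commercial = 1, medicare = 1, medicaid = 0.5,
                               uninsured = 0) {
  w <- c(commercial = commercial, medicare = medicare, medicaid = medicaid,
         uninsured = uninsured)
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]", call. = FALSE)
  w
}

#' Per-patient rates for scenario projections
#'
#' Collapses the five-class base-case rates to the four scenario classes:
#' the commercial scenario rate is the commercial-only per-patient rate
#' (Tricare/VA grouping affects count bucketing only, not the rate).
#'
#' @param ledgers a `group_ledger` tibble, default the study base case.
#' @return a `per_patient_rates` tibble over the four scenario classes.
#' @export
scenario_rates <- function(ledgers = la_general_ledger()) {
  rates <- per_case_rates(ledgers)
  keep <- c("commercial", "medicare", "medicaid", "uninsured")
  out <- rates[match(keep, rates$payer), ]
  if (any(is.na(out$payer))) {
    stop("ledger must contain commercial, medicare, medicaid and uninsured rows",
         call. = FALSE)
  }
  out
}

#' Scale the variable-cost component of per-patient rates
#'
#' One-way sensitivity on daily variable cost: multiplies only
#' `variable_avoided_pp` by `factor` (the published grid is 0.5, 0.75, 1,
#' 1.25, 1.5), leaving lost revenue and fixed allocation untouched, and
#' recomputes the per-patient net.
#'
#' @param rates a `per_patient_rates` tibble.
#' @param factor positive scale factor.
#' @return rates tibble with scaled `variable_avoided_pp` and updated `net_pp`.
#' @export
scale_variable_costs <- function(rates, factor) {
  if (length(factor) != 1 || !is.finite(factor) || factor <= 0) {
    stop("`factor` must be a single positive number", call. = FALSE)
  }
  rates$variable_avoided_pp <- rates$variable_avoided_pp * factor
  rates$net_pp <- rates$variable_avoided_pp - rates$lost_revenue_pp - rates$fixed_pp
  rates
}

#' Project per-patient rates onto a payer mix
#'
#' Net hospital savings or losses for `n_total` program patients distributed
#' across payer classes by `mix`: each class contributes
#' `fraction * n_total * net_pp`. Arithmetic is kept at full precision;
#' dollar rounding is applied in the returned report columns only.
#'
#' @param rates a `per_patient_rates` tibble.
#' @param mix a [payer_mix()].
#' @param n_total number of program patients (default 1000).
#' @return tibble of per-class rows plus a `total` row, with unrounded `net`
#'   and whole-dollar `net_dollars`.
#' @export
#' @examples
#' project_mix(scenario_rates(), standard_payer_mixes()$typical_us, 1000)
project_mix <- function(rates, mix, n_total = 1000) {
  mix <- payer_mix(unclass(mix))
  assert_nonneg(n_total)
  active <- names(mix)[mix > 0]
  missing <- setdiff(active, rates$payer)
  if (length(missing)) {
    stop("no per-patient rates for payer class(es): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  idx <- match(names(mix), rates$payer)
  net_pp <- rates$net_pp[idx]
  net_pp[is.na(net_pp) & mix == 0] <- 0
  per_class <- tibble::tibble(
    payer = names(mix),
    fraction = as.numeric(mix),
    n_patients = as.numeric(mix) * n_total,
    net = as.numeric(mix) * n_total * net_pp
  )
  total <- tibble::tibble(
    payer = "total", fraction = sum(per_class$fraction),
    n_patients = n_total, net = sum(per_class$net)
  )
  out <- dplyr::bind_rows(per_class, total)
  out$net_dollars <- round_dollar(out$net)
  out
}

#' Break-even commercial fraction in a two-class extreme mix
#'
#' Extreme-case analysis: a cohort containing only commercially insured
#' patients (the largest per-patient loss) and uninsured patients (the
#' largest per-patient gain). Total net is linear in the commercial fraction
#' x, so the break-even point is closed-form:
#' `x = net_unins / (net_unins - net_comm)`. Requires a sign change
#' (commercial net negative, uninsured net positive) for an interior root.
#'
#' @param rates a `per_patient_rates` tibble.
#' @param factor variable-cost scale factor applied before solving.
#' @return the break-even commercial fraction in (0, 1), full precision; use
#'   `round_half_up(100 * x, 1)` for the reported percent.
#' @export
#' @examples
#' round_half_up(100 * breakeven_commercial_fraction(scenario_rates()), 1) # 29.6
breakeven_commercial_fraction <- function(rates, factor = 1) {
  rates <- scale_variable_costs(rates, factor)
  net_comm <- rates$net_pp[rates$payer == "commercial"]
  net_unins <- rates$net_pp[rates$payer == "uninsured"]
  if (length(net_comm) != 1 || length(net_unins) != 1) {
    stop("rates must contain commercial and uninsured rows", call. = FALSE)
  }
  if (!(net_comm < 0 && net_unins > 0)) {
    stop("no break-even in (0, 1): need commercial net < 0 < uninsured net ",
         "at this variable-cost factor", call. = FALSE)
  }
  net_unins / (net_unins - net_comm)
}

#' Per-patient reimbursement for hospital cost neutrality
#'
#' Solves for the program reimbursement R per patient such that net savings
#' plus weighted reimbursement revenue break even:
#' `R = max(0, -total_net) / (n_total * sum(weight * mix))`. Classes pay
#' `R * weight` (default: full R for commercial and Medicare, half for
#' Medicaid, nothing for uninsured). A cohort already net-positive needs no
#' reimbursement and returns 0.
#'
#' @param rates a `per_patient_rates` tibble.
#' @param mix a [payer_mix()].
#' @param weights [neutrality_weights()].
#' @param n_total cohort size used for the projection (R is per patient and
#'   independent of `n_total` up to rounding).
#' @param factor variable-cost scale factor.
#' @return reimbursement per patient, USD, full precision.
#' @export
#' @examples
#' round_dollar(hospital_neutrality_reimbursement(
#'   scenario_rates(), standard_payer_mixes()$typical_us
#' )) # 13198
hospital_neutrality_reimbursement <- function(rates, mix,
                                              weights = neutrality_weights(),
                                              n_total = 1000, factor = 1) {
  rates <- scale_variable_costs(rates, factor)
  proj <- project_mix(rates, mix, n_total)
  total_net <- proj$net[proj$payer == "total"]
  if (total_net >= 0) return(0)
  w <- weights[names(mix)]
  wmix <- sum(w * as.numeric(mix))
  if (wmix <= 0) {
    stop("neutrality unreachable: weighted mix is zero but net is negative",
         call. = FALSE)
  }
  -total_net / (n_total * wmix)
}

#' Payer-mix x variable-cost sensitivity table
#'
#' Builds the full deterministic sensitivity grid: for each named mix and
#' each variable-cost factor, the per-class and total net outcomes for
#' `n_total` patients; appended break-even rows give the maximum commercial
#' fraction (and complementary uninsured fraction) for net-zero outcome in
#' the two-class extreme mix.
#'
#' @param rates a `per_patient_rates` tibble.
#' @param mixes named list of [payer_mix()] (default [standard_payer_mixes()]).
#' @param factors variable-cost scale grid.
#' @param n_total patients per scenario.
#' @return long tibble with columns `scenario`, `payer`, `factor`, `net`
#'   (whole dollars) and, for break-even rows, `percent`.
#' @export
mix_scenario_table <- function(rates, mixes = standard_payer_mixes(),
                               factors = c(0.5, 0.75, 1, 1.25, 1.5),
                               n_total = 1000) {
  rows <- list()
  for (mx_name in names(mixes)) {
    for (f in factors) {
      proj <- project_mix(scale_variable_costs(rates, f), mixes[[mx_name]], n_total)
      rows[[length(rows) + 1]] <- tibble::tibble(
        scenario = mx_name, payer = proj$payer, factor = f,
        net = proj$net_dollars, percent = NA_real_
      )
    }
  }
  for (f in factors) {
    x <- breakeven_commercial_fraction(rates, f)
    rows[[length(rows) + 1]] <- tibble::tibble(
      scenario = "breakeven_two_class",
      payer = c("commercial", "uninsured"),
      factor = f, net = NA_real_,
      percent = round_half_up(c(100 * x, 100 * (1 - x)), 1)
    )
  }
  dplyr::bind_rows(rows)
}

#' Hospital-neutrality thresholds over the variable-cost grid
#'
#' @param rates a `per_patient_rates` tibble.
#' @param mix a [payer_mix()] (default typical US).
#' @param weights [neutrality_weights()].
#' @param factors variable-cost scale grid.
#' @param n_total projection cohort size.
#' @return tibble with `factor` and whole-dollar `reimbursement_per_patient`.
#' @export
neutrality_threshold_table <- function(rates,
                                       mix = standard_payer_mixes()$typical_us,
                                       weights = neutrality_weights(),
                                       factors = c(0.5, 0.75, 1, 1.25, 1.5),
                                       n_total = 1000) {
  r <- vapply(
    factors,
    function(f) hospital_neutrality_reimbursement(rates, mix, weights, n_total, f),
    numeric(1)
  )
  tibble::tibble(
    factor = factors,
    reimbursement_per_patient = round_dollar(r)
  )
}
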