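#' Rate schedules for lost-revenue rules
#'
#' The hospital forgoes different revenue for an avoided or shortened
#' admission depending on the payer's reimbursement mechanism. Rate values
#' (base payment rate, DSH add-on, per-diems, flat daily rates) are local
#' contracting facts and therefore configuration inputs, not constants.
#'
#' @param base_payment_rate hospital base Medicare payment rate, USD.
#' @param dsh_addon disproportionate-share add-on per admission, USD.
#' @param per_diem daily Medicare per-diem component, USD/day.
#' @return `medicare_rate_schedule()` returns a `medicare_rate_schedule`
#'   object. DRG payment for an encounter is
#'   `base_payment_rate * drg_weight + dsh_addon`.
#' @name rate-schedules
#' @export
medicare_rate_schedule <- function(base_payment_rate, dsh_addon = 0,
                                   per_diem = 0) {
  assert_nonneg(base_payment_rate)
  assert_nonneg(dsh_addon)
  assert_nonneg(per_diem)
  structure(
    list(base_payment_rate = base_payment_rate, dsh_addon = dsh_addon,
         per_diem = per_diem),
    class = "medicare_rate_schedule"
  )
}

#' @rdname rate-schedules
#' @param rate USD per day.
#' @export
per_diem_rate <- function(rate) {
  assert_nonneg(rate)
  structure(list(rate = rate), class = c("per_diem_rate", "daily_rate"))
}

#' @rdname rate-schedules
#' @export
flat_daily_rate <- function(rate) {
  assert_nonneg(rate)
  structure(list(rate = rate), class = c("flat_daily_rate", "daily_rate"))
}

#' Synthetic patient encounter records
#'
#' An encounter captures the counterfactual inpatient stay a program patient
#' would have had (`los_without_program`), the inpatient days actually used
#' (`los_with_program`, 0 for a fully avoided admission), and the fields the
#' revenue rules need. Lengths of stay are counted as midnights crossed
#' (integer days).
#'
#' @param payer payer class labels.
#' @param los_without_program counterfactual inpatient days (midnights).
#' @param los_with_program inpatient days actually used.
#' @param drg_weight DRG relative weight (used for Medicare).
#' @param flat_rate class-specific daily rate, USD/day (per-diem and
#'   flat-rate mechanisms).
#' @param urgent_care_visits 30-day urgent-care follow-up visits.
#' @param mechanism reimbursement mechanism; defaults per payer class.
#' @return a tibble of encounters with `days_avoided` computed.
#' @export
patient_encounters <- function(payer, los_without_program, los_with_program,
                               drg_weight = 1, flat_rate = 0,
                               urgent_care_visits = 0,
                               mechanism = payer_mechanism(payer)) {
  assert_nonneg(los_without_program)
  assert_nonneg(los_with_program)
  if (any(los_with_program > los_without_program)) {
    stop("`los_with_program` cannot exceed `los_without_program`",
         call. = FALSE)
  }
  tibble::tibble(
    payer = payer,
    mechanism = mechanism,
    los_without_program = los_without_program,
    los_with_program = los_with_program,
    days_avoided = los_without_program - los_with_program,
    drg_weight = drg_weight,
    flat_rate = flat_rate,
    urgent_care_visits = urgent_care_visits
  )
}

#' Lost revenue for Medicare (DRG-based) encounters
#'
#' Medicare pays a DRG case rate (base rate x DRG relative weight, plus the
#' DSH add-on) for inpatient stays crossing at least 2 midnights. An avoided
#' admission, or one shortened below 2 midnights, forfeits the whole case
#' payment plus the per-diem component for the avoided days; a stay shortened
#' but still crossing 2 midnights retains the DRG payment and loses only the
#' per-diem component (`per_diem = 0` recovers a strict no-loss reading).
#'
#' @param schedule a [medicare_rate_schedule()].
#' @param encounters encounter tibble (see [patient_encounters()]).
#' @return numeric vector of forgone revenue, USD (non-negative magnitudes).
#' @export
#' @examples
#' s <- medicare_rate_schedule(6000, dsh_addon = 1000, per_diem = 800)
#' e <- patient_encounters("medicare", 4, 0, drg_weight = 1.5)
#' lost_revenue_medicare(s, e) # 6000*1.5 + 1000 + 800*4 = 13200
lost_revenue_medicare <- function(schedule, encounters) {
  stopifnot(inherits(schedule, "medicare_rate_schedule"))
  assert_nonneg(encounters$days_avoided, "days_avoided")
  drg_forfeited <- encounters$los_with_program < 2
  drg_loss <- ifelse(
    drg_forfeited,
    schedule$base_payment_rate * encounters$drg_weight + schedule$dsh_addon,
    0
  )
  drg_loss + schedule$per_diem * encounters$days_avoided
}

#' Lost revenue at a daily rate
#'
#' Per-diem (FFS Medicaid) and flat-daily-rate (commercial, Tricare/VA,
#' out-of-plan managed care) mechanisms lose exactly the daily rate for each
#' avoided bed-day.
#'
#' @param rate a [per_diem_rate()] / [flat_daily_rate()], or a plain USD/day
#'   number.
#' @param days_avoided avoided bed-days (>= 0).
#' @return forgone revenue, USD.
#' @export
lost_revenue_per_diem <- function(rate, days_avoided) {
  r <- if (inherits(rate, "daily_rate")) rate$rate else rate
  assert_nonneg(r, "rate")
  assert_nonneg(days_avoided)
  r * days_avoided
}

#' Lost revenue for capitated and uninsured encounters
#'
#' Capitated (per-member-per-month) plans and uninsured patients generate no
#' admission revenue, so avoiding their admissions loses none. Calling this
#' on a revenue-bearing mechanism is an error, to guard against payer
#' misclassification.
#'
#' @param encounters encounter tibble.
#' @return a zero for every encounter.
#' @export
lost_revenue_zero <- function(encounters) {
  bearing <- setdiff(unique(encounters$mechanism), c("capitated", "none"))
  if (length(bearing)) {
    stop("lost_revenue_zero called for revenue-bearing mechanism(s): ",
         paste(bearing, collapse = ", "), call. = FALSE)
  }
  rep(0, nrow(encounters))
}

#' Dispatch lost revenue per encounter
#'
#' Routes each encounter to the rule for its reimbursement mechanism. Cohort
#' totals are plain sums of the per-patient values.
#'
#' @param encounters encounter tibble.
#' @param schedules named list of rate schedules keyed by payer class (the
#'   `medicare` entry must be a [medicare_rate_schedule()]); classes whose
#'   mechanism is `capitated` or `none` need no entry. For per-diem and
#'   flat-rate mechanisms, an encounter-level `flat_rate > 0` overrides the
#'   schedule.
#' @return numeric vector, one USD value per encounter.
#' @export
patient_lost_revenue <- function(encounters, schedules = list()) {
  mech <- encounters$mechanism
  out <- numeric(nrow(encounters))
  zero <- mech %in% c("capitated", "none")
  out[zero] <- lost_revenue_zero(encounters[zero, , drop = FALSE])

  drg <- mech == "drg_based"
  if (any(drg)) {
    sched <- schedules[["medicare"]]
    if (is.null(sched)) {
      stop("no Medicare rate schedule configured for drg_based encounters",
           call. = FALSE)
    }
    out[drg] <- lost_revenue_medicare(sched, encounters[drg, , drop = FALSE])
  }

  daily <- mech %in% c("per_diem", "flat_daily_rate")
  if (any(daily)) {
    sub <- encounters[daily, , drop = FALSE]
    rate <- sub$flat_rate
    need <- !(rate > 0)
    if (any(need)) {
      looked <- vapply(sub$payer[need], function(p) {
        s <- schedules[[p]]
        if (is.null(s)) {
          stop(sprintf("no rate schedule configured for payer '%s'", p),
               call. = FALSE)
        }
        if (inherits(s, "daily_rate")) s$rate else as.numeric(s)
      }, numeric(1))
      rate[need] <- looked
    }
    out[daily] <- lost_revenue_per_diem(rate, sub$days_avoided)
  }
  out
}
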