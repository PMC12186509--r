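#' Default rate schedules for the synthetic cohort
#'
#' The source study does not publish its contracted rates; these defaults are
#' chosen so that the synthetic cohort's expected per-patient lost revenue is
#' of the same magnitude as the study ledger implies, and they are exactly
#' recoverable by [calibrate_cohort_spec()].
#'
#' @return named list of rate schedules keyed by payer class.
#' @export
default_rate_schedules <- function() {
  list(
    medicare = medicare_rate_schedule(
      base_payment_rate = 12000, dsh_addon = 1500, per_diem = 1530
    ),
    medicaid = per_diem_rate(625),
    commercial = flat_daily_rate(7800),
    tricare_va = flat_daily_rate(2100)
  )
}

#' Specification of a synthetic patient cohort
#'
#' Defines the statistical structure of a simulated program year: cohort
#' size, payer mix, avoided bed-days per patient (truncated-normal, rounded
#' to whole days), DRG relative weights (lognormal with the study's case-mix
#' moments), the probability that enrollment happens before admission (so the
#' admission is avoided entirely rather than shortened), urgent-care
#' follow-up intensity, and the rate schedules feeding the revenue rules.
#'
#' Defaults are the study-year conditions: 876 patients; payer fractions
#' 13.8% Medicare, 77.2% Medicaid, 1.3% commercial, 0.3% Tricare/VA, 7.4%
#' uninsured; mean 4 bed-days saved per patient; case-mix index mean 1.27,
#' SD 0.66; 0.61 urgent-care visits per patient; 55% of patients enrolled
#' before admission (ED 46% + observation 8% + urgent care 2%).
#'
#' @param n_patients cohort size.
#' @param mix named fractions over the five payer classes (sum to 1).
#' @param mean_days_saved mean avoided bed-days: scalar, or named per class.
#' @param sd_days SD of the days-saved draw before truncation/rounding.
#' @param drg_weight_mean,drg_weight_sd moments of the DRG-weight lognormal.
#' @param avoid_prob probability an enrollee's admission is avoided entirely.
#' @param urgent_care_rate mean urgent-care follow-up visits per patient.
#' @param rate_schedules named list of rate schedules (see
#'   [default_rate_schedules()]).
#' @param medicaid_capitated_frac fraction of Medicaid patients on in-plan
#'   capitated managed care (no revenue loss); the FFS remainder pays the
#'   per-diem. Default 0: the configured Medicaid per-diem is interpreted as
#'   the blended effective rate.
#' @param exact_quota logical; fixture mode: assign payer classes by exact
#'   largest-remainder quota instead of a multinomial draw, and quota the
#'   avoided-admission count within each class.
#' @param seed integer seed making generation reproducible.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 876,
                        mix = c(medicare = 0.138, medicaid = 0.772,
                                commercial = 0.013, tricare_va = 0.003,
                                uninsured = 0.074),
                        mean_days_saved = 4, sd_days = 2,
                        drg_weight_mean = 1.27, drg_weight_sd = 0.66,
                        avoid_prob = 0.55, urgent_care_rate = 0.61,
                        rate_schedules = default_rate_schedules(),
                        medicaid_capitated_frac = 0,
                        exact_quota = FALSE, seed = 1L) {
  if (n_patients < 0) stop("`n_patients` must be >= 0", call. = FALSE)
  bad <- setdiff(names(mix), payer_levels())
  if (length(bad)) {
    stop("unknown payer class(es) in mix: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(mix) - 1) > 1e-9) stop("mix must sum to 1", call. = FALSE)
  if (is.null(names(mean_days_saved))) {
    mean_days_saved <- stats::setNames(
      rep(mean_days_saved[1], length(mix)), names(mix)
    )
  }
  assert_nonneg(mean_days_saved)
  assert_nonneg(sd_days)
  if (drg_weight_mean <= 0 || drg_weight_sd < 0) {
    stop("DRG weight distribution needs mean > 0 and SD >= 0", call. = FALSE)
  }
  assert_scalar_prob(avoid_prob)
  assert_scalar_prob(medicaid_capitated_frac)
  assert_nonneg(urgent_care_rate)
  structure(
    list(
      n_patients = n_patients, mix = mix,
      mean_days_saved = mean_days_saved, sd_days = sd_days,
      drg_weight_mean = drg_weight_mean, drg_weight_sd = drg_weight_sd,
      avoid_prob = avoid_prob, urgent_care_rate = urgent_care_rate,
      rate_schedules = rate_schedules,
      medicaid_capitated_frac = medicaid_capitated_frac,
      exact_quota = exact_quota, seed = as.integer(seed)
    ),
    class = "cohort_spec"
  )
}

# lognormal meanlog/sdlog from arithmetic mean and SD
lognormal_params <- function(mean, sd) {
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  sdlog2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

# mean of max(N(m, sd), 0), the days-saved draw before integer rounding
truncated_day_mean <- function(m, sd) {
  if (sd == 0) return(pmax(m, 0))
  m * stats::pnorm(m / sd) + sd * stats::dnorm(m / sd)
}

# pre-truncation normal mean whose zero-truncated expectation equals `target`
invert_day_mean <- function(target, sd) {
  if (sd == 0 || target == 0) return(target)
  stats::uniroot(function(m) truncated_day_mean(m, sd) - target,
                 lower = target - 6 * sd - 1, upper = target + 1,
                 tol = 1e-10)$root
}

quota_counts <- function(n, mix) {
  raw <- n * mix
  cnt <- floor(raw)
  res <- n - sum(cnt)
  if (res > 0) {
    take <- order(raw - cnt, decreasing = TRUE)[seq_len(res)]
    cnt[take] <- cnt[take] + 1
  }
  stats::setNames(as.integer(cnt), names(mix))
}

#' Generate a synthetic patient cohort
#'
#' Draws `n_patients` encounters under the spec's distributions, all from one
#' seeded RNG stream: identical spec + seed gives an identical cohort. Days
#' saved are truncated-normal draws rounded to whole days (>= 0); patients
#' enrolled before admission have `los_with_program = 0` (avoided admission),
#' the rest keep an inpatient stay of at least 2 midnights. Demographic
#' fields (age, sex) are generated for realism and carry no financial role.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional override of `spec$seed`.
#' @return encounter tibble (see [patient_encounters()]) with extra columns
#'   `patient_id`, `age`, `sex`.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  empty <- patient_encounters(character(0), numeric(0), numeric(0))
  empty$patient_id <- integer(0)
  empty$age <- numeric(0)
  empty$sex <- character(0)
  if (n == 0) return(empty)

  # single seeded stream; caller's RNG state restored on exit
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  classes <- names(spec$mix)
  payer <- if (spec$exact_quota) {
    rep(classes, times = quota_counts(n, spec$mix))
  } else {
    sample(classes, n, replace = TRUE, prob = spec$mix)
  }

  mechanism <- payer_mechanism(payer)
  if (spec$medicaid_capitated_frac > 0) {
    medi <- which(payer == "medicaid")
    cap <- medi[runif(length(medi)) < spec$medicaid_capitated_frac]
    mechanism[cap] <- "capitated"
  }

  mu_days <- spec$mean_days_saved[payer]
  days <- pmax(0, round(rnorm(n, mean = mu_days, sd = spec$sd_days)))

  avoided <- if (spec$exact_quota) {
    # fixture mode: quota the avoided-admission count within each class too
    av <- logical(n)
    for (p in unique(payer)) {
      idx <- which(payer == p)
      k <- round(spec$avoid_prob * length(idx))
      if (k > 0) av[idx[sample(length(idx), k)]] <- TRUE
    }
    av
  } else {
    runif(n) < spec$avoid_prob
  }
  los_with <- ifelse(avoided, 0, 2 + rpois(n, 1))
  los_without <- los_with + days

  lp <- lognormal_params(spec$drg_weight_mean, spec$drg_weight_sd)
  drg_weight <- rlnorm(n, lp$meanlog, lp$sdlog)

  enc <- patient_encounters(
    payer = payer,
    los_without_program = los_without,
    los_with_program = los_with,
    drg_weight = drg_weight,
    flat_rate = 0,
    urgent_care_visits = rpois(n, spec$urgent_care_rate),
    mechanism = mechanism
  )
  enc$patient_id <- seq_len(n)
  enc$age <- pmax(18, round(rnorm(n, 54, 15)))
  enc$sex <- sample(c("male", "female"), n, replace = TRUE,
                    prob = c(0.618, 0.382))
  enc
}

#' Aggregate encounters into per-payer group ledgers
#'
#' Bridges the patient-level revenue rules to the group-ledger accounting:
#' per payer class it sums patients, avoided days, dispatched lost revenue,
#' and avoided variable cost (`days x daily_variable_cost`), then allocates
#' total program fixed cost per capita across the represented classes.
#'
#' @param encounters encounter tibble from [generate_cohort()] or built by
#'   hand with [patient_encounters()].
#' @param params [cost_parameters()].
#' @param schedules named list of rate schedules.
#' @return a `group_ledger` tibble, one row per represented payer class, in
#'   `payer_levels()` order.
#' @export
aggregate_cohort <- function(encounters, params = cost_parameters(),
                             schedules = default_rate_schedules()) {
  if (nrow(encounters) == 0) {
    stop("empty cohort: nothing to aggregate", call. = FALSE)
  }
  encounters$lost <- patient_lost_revenue(encounters, schedules)
  grp <- encounters %>%
    dplyr::group_by(.data$payer) %>%
    dplyr::summarise(
      n_patients = dplyr::n(),
      days_saved = sum(.data$days_avoided),
      lost_revenue = sum(.data$lost),
      .groups = "drop"
    )
  grp <- grp[order(match(grp$payer, payer_levels())), ]
  fixed <- allocate_fixed_costs(
    params$total_fixed, stats::setNames(grp$n_patients, grp$payer)
  )
  rows <- lapply(seq_len(nrow(grp)), function(i) {
    group_ledger(
      payer = grp$payer[i], n_patients = grp$n_patients[i],
      days_saved = grp$days_saved[i], lost_revenue = grp$lost_revenue[i],
      variable_avoided = grp$days_saved[i] * params$daily_variable_cost,
      fixed_alloc = fixed[[grp$payer[i]]]
    )
  })
  as_group_ledger(dplyr::bind_rows(rows))
}

#' Calibrate a cohort spec to target group ledgers
#'
#' Closed-form moment matching: for each target class, the target mean
#' days-saved is `variable_avoided_pp / daily_variable_cost`, and the class
#' daily rate is `lost_revenue_pp / mean_days`. For Medicare the DRG case
#' payment expected under the spec
#' (`avoid_prob * (base_rate * mean_weight + dsh)`) is subtracted first and
#' the residual per-diem fitted:
#' `per_diem = (lost_pp - avoid_prob * (base * w_mean + dsh)) / mean_days`.
#' Because the generator truncates the days draw at zero (which inflates its
#' mean), the fitted spec stores the pre-truncation draw mean whose truncated
#' expectation equals the target, so the generated cohort is unbiased for the
#' target. Infeasible targets (implying a negative rate) are an error.
#' Aggregating a large cohort from the fitted spec recovers the target
#' per-patient components up to sampling error.
#'
#' @param spec a [cohort_spec()] providing distributions and the Medicare
#'   base rate / DSH assumptions.
#' @param target a `group_ledger` tibble with `n_patients > 0` per row.
#' @param params [cost_parameters()] (for the daily variable cost).
#' @return the fitted `cohort_spec`.
#' @export
calibrate_cohort_spec <- function(spec, target, params = cost_parameters()) {
  stopifnot(inherits(spec, "cohort_spec"))
  target <- as_group_ledger(target)
  rates <- per_case_rates(target)
  mean_days <- spec$mean_days_saved
  schedules <- spec$rate_schedules
  for (i in seq_len(nrow(rates))) {
    p <- rates$payer[i]
    md <- rates$variable_avoided_pp[i] / params$daily_variable_cost
    if (md < 0) stop("infeasible target: negative implied days", call. = FALSE)
    mean_days[p] <- invert_day_mean(md, spec$sd_days)
    lost_pp <- rates$lost_revenue_pp[i]
    mech <- payer_mechanism(p)
    if (mech %in% c("none", "capitated")) {
      if (lost_pp > 0) {
        stop(sprintf("infeasible target: payer '%s' cannot lose revenue", p),
             call. = FALSE)
      }
      next
    }
    if (lost_pp == 0) {
      daily <- 0
    } else if (md == 0) {
      stop(sprintf("infeasible target: payer '%s' loses revenue with 0 days", p),
           call. = FALSE)
    } else if (mech == "drg_based") {
      sched <- schedules[["medicare"]]
      drg_component <- spec$avoid_prob *
        (sched$base_payment_rate * spec$drg_weight_mean + sched$dsh_addon)
      per_diem <- (lost_pp - drg_component) / md
      if (per_diem < 0) {
        stop("infeasible Medicare target: expected DRG case payments alone ",
             "exceed the target lost revenue; lower `avoid_prob`, the base ",
             "rate or the DSH add-on", call. = FALSE)
      }
      schedules$medicare <- medicare_rate_schedule(
        sched$base_payment_rate, sched$dsh_addon, per_diem
      )
      next
    } else {
      daily <- lost_pp / md
    }
    schedules[[p]] <- if (mech == "per_diem") per_diem_rate(daily) else flat_daily_rate(daily)
  }
  spec$mean_days_saved <- mean_days
  spec$rate_schedules <- schedules
  spec
}

#' Write a generated cohort to CSV
#'
#' Byte-stable output: identical spec + seed give identical files.
#'
#' @param encounters encounter tibble.
#' @param path output file.
#' @export
write_cohort_csv <- function(encounters, path) {
  readr::write_csv(encounters, path)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("payer", "mechanism", "los_without_program", "los_with_program",
              "days_avoided", "drg_weight", "flat_rate", "urgent_care_visits")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("cohort file missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  tibble::as_tibble(df)
}
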