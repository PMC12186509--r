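config_keys <- c("costs", "rates", "mixes", "neutrality_weights",
                 "payer_model", "scenario", "cohort", "seed", "verbose")

#' Default run configuration
#'
#' All defaults reproduce the published base case. The structure mirrors the
#' YAML config accepted by [load_run_config()]:
#' `costs` (daily_variable, staffing, dme), `rates` (per payer class),
#' `mixes` (named payer mixes), `neutrality_weights`, `payer_model`
#' (split_difference, hosp_reduction, wage_recovery, qol_hospital, qol_home,
#' reimbursement, total_cost_grid), `scenario` (n_total, scale_grid),
#' `cohort` (generator parameters) and `seed`.
#'
#' @return nested list of class `run_config`.
#' @export
default_run_config <- function() {
  structure(list(
    costs = list(daily_variable = 2945, staffing = 518000, dme = 164547),
    rates = list(
      medicare = list(base_payment_rate = 12000, dsh_addon = 1500,
                      per_diem = 1530),
      medicaid = list(per_diem = 625),
      commercial = list(flat_daily_rate = 7800),
      tricare_va = list(flat_daily_rate = 2100)
    ),
    mixes = lapply(standard_payer_mixes(), function(m) as.list(unclass(m))),
    neutrality_weights = as.list(neutrality_weights()),
    payer_model = list(
      split_difference = 5000, hosp_reduction = 0.75, wage_recovery = 0.30,
      qol_hospital = 0.7, qol_home = 0.9, reimbursement = 15000,
      total_cost_grid = seq(20000, 45000, by = 5000)
    ),
    scenario = list(n_total = 1000, scale_grid = c(0.5, 0.75, 1, 1.25, 1.5)),
    cohort = list(
      n_patients = 876, mean_days_saved = 4, sd_days = 2,
      drg_weight_mean = 1.27, drg_weight_sd = 0.66,
      avoid_prob = 0.55, urgent_care_rate = 0.61
    ),
    seed = 20220901,
    verbose = FALSE
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file and merges it over [default_run_config()]; keys absent
#' from the file keep their defaults, and unknown top-level keys are rejected
#' (a typo in a config should fail loudly, not silently fall back).
#'
#' @param path YAML file path.
#' @return a `run_config` list.
#' @export
load_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(unclass(default_run_config()), user)
  class(cfg) <- "run_config"
  cfg
}

config_cost_parameters <- function(cfg) {
  cost_parameters(
    daily_variable_cost = cfg$costs$daily_variable,
    staffing_cost = cfg$costs$staffing,
    dme_total = cfg$costs$dme
  )
}

config_schedules <- function(cfg) {
  r <- cfg$rates
  out <- list()
  if (!is.null(r$medicare)) {
    out$medicare <- medicare_rate_schedule(
      r$medicare$base_payment_rate %||% 0,
      r$medicare$dsh_addon %||% 0,
      r$medicare$per_diem %||% 0
    )
  }
  if (!is.null(r$medicaid)) out$medicaid <- per_diem_rate(r$medicaid$per_diem %||% 0)
  for (p in c("commercial", "tricare_va")) {
    if (!is.null(r[[p]])) out[[p]] <- flat_daily_rate(r[[p]]$flat_daily_rate %||% 0)
  }
  out
}

config_cohort_spec <- function(cfg) {
  ch <- cfg$cohort
  cohort_spec(
    n_patients = ch$n_patients, mean_days_saved = ch$mean_days_saved,
    sd_days = ch$sd_days, drg_weight_mean = ch$drg_weight_mean,
    drg_weight_sd = ch$drg_weight_sd, avoid_prob = ch$avoid_prob,
    urgent_care_rate = ch$urgent_care_rate,
    rate_schedules = config_schedules(cfg),
    seed = cfg$seed
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
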