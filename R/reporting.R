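#' Render a result table to disk
#'
#' Writes a computed table as CSV (always, full precision so a parse-back is
#' lossless) and optionally as an aligned plain-text rendering with
#' display-rounded dollars, a leading minus for losses, and a configurable
#' thousands separator.
#'
#' @param result a tibble.
#' @param path output path (CSV); the text rendering, if requested, goes to
#'   `paste0(path, ".txt")`.
#' @param format `"csv"` or `"text"` (text also writes the CSV).
#' @param big_mark thousands separator for the text rendering.
#' @return the CSV path, invisibly.
#' @export
render_table <- function(result, path, format = c("csv", "text"),
                         big_mark = ",") {
  format <- match.arg(format)
  readr::write_csv(result, path)
  if (format == "text") {
    disp <- result
    for (col in names(disp)) {
      if (is.numeric(disp[[col]])) {
        disp[[col]] <- formatC(round_dollar(disp[[col]]), format = "d",
                               big.mark = big_mark)
        disp[[col]][disp[[col]] == "NA"] <- ""
      }
    }
    lines <- utils::capture.output(print(as.data.frame(disp), row.names = FALSE))
    writeLines(lines, paste0(path, ".txt"))
  }
  invisible(path)
}

#' Run the full base-case reproduction
#'
#' Executes the whole model from a configuration and writes CSV analogues of
#' the four published result tables plus the hospital-neutrality thresholds:
#'
#' * `table1.csv` — base-case hospital ledger by payer group (with the
#'   published total row),
#' * `table2.csv` — payer-mix x variable-cost sensitivity grid with the
#'   two-class break-even rows,
#' * `table3.csv` — payer-perspective base-case cost table,
#' * `table4.csv` — payer-neutrality sensitivity table,
#' * `neutrality.csv` — hospital-neutrality reimbursement by variable-cost
#'   factor,
#' * `synthetic_cohort.csv` — a seeded synthetic cohort (calibrated to the
#'   base-case ledger) demonstrating the patient-level pipeline,
#' * `manifest.json` — config digest, seed, file list.
#'
#' @param config a `run_config` (default [default_run_config()]).
#' @param out_dir output directory, created if needed; `NULL` computes
#'   without writing.
#' @return named list of the computed tibbles, invisibly when writing.
#' @export
run_full_reproduction <- function(config = default_run_config(),
                                  out_dir = NULL) {
  params <- config_cost_parameters(config)
  table1 <- la_general_table1(params)
  rates <- scenario_rates(la_general_ledger(params))
  mixes <- lapply(config$mixes, function(m) payer_mix(unlist(m)))
  grid <- config$scenario$scale_grid
  n_total <- config$scenario$n_total
  table2 <- mix_scenario_table(rates, mixes, grid, n_total)
  weights <- unlist(config$neutrality_weights)
  neutrality <- neutrality_threshold_table(
    rates, mixes$typical_us, weights, grid, n_total
  )
  pm <- config$payer_model
  a <- payer_assumptions(
    split_difference = pm$split_difference, hosp_reduction = pm$hosp_reduction,
    wage_recovery = pm$wage_recovery, qol_hospital = pm$qol_hospital,
    qol_home = pm$qol_home
  )
  table3 <- payer_cost_table(pm$total_cost_grid, a, pm$reimbursement)
  table4 <- payer_neutrality_table(pm$total_cost_grid,
                                   split_difference = pm$split_difference)

  spec <- calibrate_cohort_spec(config_cohort_spec(config),
                                la_general_ledger(params), params)
  cohort <- generate_cohort(spec, seed = config$seed)
  cohort_ledger <- aggregate_cohort(cohort, params, spec$rate_schedules)

  out <- list(
    table1 = table1, table2 = table2, table3 = table3, table4 = table4,
    neutrality = neutrality, synthetic_cohort = cohort,
    synthetic_ledger = cohort_ledger
  )
  if (is.null(out_dir)) return(out)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  for (nm in names(out)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    render_table(out[[nm]], f)
    files <- c(files, basename(f))
  }
  manifest <- list(
    package = "vwecon",
    seed = config$seed,
    config_digest = digest_config(config),
    files = files
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out)
}

# order-independent digest of the config content (no external digest dep)
digest_config <- function(config) {
  canon <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA)
  raw <- as.integer(charToRaw(as.character(canon)))
  # polynomial rolling hash mod 2^31 - 1 (exact in double arithmetic)
  h <- 0
  for (b in raw) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("poly31:%08x", as.integer(h))
}
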