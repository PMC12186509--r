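#' Payer classes and reimbursement mechanisms
#'
#' The model distinguishes five payer classes, each tied to the reimbursement
#' mechanism that determines how much inpatient revenue the hospital forgoes
#' when an admission is avoided or shortened:
#'
#' * `medicare` — DRG-based: payment = base rate x DRG relative weight, plus
#'   disproportionate-share (DSH) add-on and a daily per-diem component.
#' * `medicaid` — fee-for-service per-diem (flat reimbursable cost per day);
#'   in-plan capitated managed-care patients generate no admission revenue and
#'   are modelled with the `capitated` mechanism.
#' * `commercial`, `tricare_va` — flat daily rate the hospital charges the plan.
#' * `uninsured` — no revenue, mechanism `none`.
#'
#' @name payer-classes
NULL

#' @rdname payer-classes
#' @return `payer_levels()` returns the five payer class labels in ledger order.
#' @export
payer_levels <- function() {
  c("medicare", "medicaid", "commercial", "tricare_va", "uninsured")
}

#' @rdname payer-classes
#' @return `mechanism_levels()` returns the recognised reimbursement mechanisms.
#' @export
mechanism_levels <- function() {
  c("drg_based", "per_diem", "flat_daily_rate", "capitated", "none")
}

default_mechanisms <- c(
  medicare   = "drg_based",
  medicaid   = "per_diem",
  commercial = "flat_daily_rate",
  tricare_va = "flat_daily_rate",
  uninsured  = "none"
)

#' @rdname payer-classes
#' @param label payer class label, one of `payer_levels()`.
#' @param mechanism reimbursement mechanism; defaults to the class's usual one.
#' @return `payer_class()` returns a validated `payer_class` object with
#'   `$label` and `$mechanism`.
#' @export
#' @examples
#' payer_class("medicaid")                 # FFS per-diem by default
#' payer_class("medicaid", "capitated")    # in-plan managed care: no revenue
payer_class <- function(label, mechanism = NULL) {
  label <- match.arg(label, payer_levels())
  mechanism <- if (is.null(mechanism)) {
    unname(default_mechanisms[[label]])
  } else {
    match.arg(mechanism, mechanism_levels())
  }
  if (label == "uninsured" && mechanism != "none") {
    stop("uninsured patients have mechanism 'none': no revenue is generated",
         call. = FALSE)
  }
  structure(list(label = label, mechanism = mechanism), class = "payer_class")
}

#' @export
print.payer_class <- function(x, ...) {
  cat(sprintf("<payer_class> %s (%s)\n", x$label, x$mechanism))
  invisible(x)
}

#' @rdname payer-classes
#' @param payer character vector of payer labels.
#' @return `payer_mechanism()` returns the default mechanism for each label.
#' @export
payer_mechanism <- function(payer) {
  bad <- setdiff(unique(payer), payer_levels())
  if (length(bad)) {
    stop("unknown payer class(es): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  unname(default_mechanisms[payer])
}
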