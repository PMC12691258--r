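#' Unit costs of a repeated-test screening protocol
#'
#' @param fit_unit_cost Cost of one cheap test round (default 5 currency
#'   units, the worked FIT price).
#' @param colonoscopy_unit_cost Cost of one confirmatory procedure (default
#'   500).
#' @param n_fit_rounds Number of test rounds in the protocol (default 4).
#' @param currency Currency label carried through to reports (default
#'   `"USD"`); purely cosmetic.
#' @return An object of class `cost_params`.
#' @export
cost_params <- function(fit_unit_cost = 5, colonoscopy_unit_cost = 500,
                        n_fit_rounds = 4, currency = "USD") {
  assert_nonneg(fit_unit_cost, "fit_unit_cost")
  assert_nonneg(colonoscopy_unit_cost, "colonoscopy_unit_cost")
  n_fit_rounds <- assert_count(n_fit_rounds, "n_fit_rounds")
  structure(list(fit_unit_cost = fit_unit_cost,
                 colonoscopy_unit_cost = colonoscopy_unit_cost,
                 n_fit_rounds = n_fit_rounds, currency = currency),
            class = "cost_params")
}

#' Total cost of the screening protocol versus full confirmatory screening
#'
#' `protocol_total = cohort_size * n_fit_rounds * fit_unit_cost +
#' urgent_count * colonoscopy_unit_cost`, compared against performing the
#' confirmatory procedure on the whole cohort. All totals are rounded to
#' cents; the inputs used in practice are integers, so the arithmetic is
#' exact in double precision at these magnitudes.
#'
#' @param cohort_size Number of people screened, `>= 0`.
#' @param urgent_count Number of confirmatory procedures triggered, `>= 0`.
#' @param params A [cost_params()].
#' @return An object of class `cost_report`: `fit_total`,
#'   `colonoscopy_total`, `protocol_total`, `full_screen_total`, `savings`,
#'   plus the inputs.
#' @examples
#' protocol_cost(100000, 96, cost_params())  # 2,048,000 vs 50,000,000
#' @export
protocol_cost <- function(cohort_size, urgent_count, params = cost_params()) {
  assert_nonneg(cohort_size, "cohort_size")
  assert_nonneg(urgent_count, "urgent_count")
  stopifnot(inherits(params, "cost_params"))
  fit_total <- round(cohort_size * params$n_fit_rounds * params$fit_unit_cost, 2)
  colonoscopy_total <- round(urgent_count * params$colonoscopy_unit_cost, 2)
  protocol_total <- round(fit_total + colonoscopy_total, 2)
  full_screen_total <- round(cohort_size * params$colonoscopy_unit_cost, 2)
  structure(list(
    cohort_size = cohort_size, urgent_count = urgent_count, params = params,
    fit_total = fit_total, colonoscopy_total = colonoscopy_total,
    protocol_total = protocol_total, full_screen_total = full_screen_total,
    savings = round(full_screen_total - protocol_total, 2)
  ), class = "cost_report")
}

#' Cost of an additional colonoscopy tier
#'
#' Incremental cost of extending confirmatory procedures to a further tier
#' of `n_patients` (e.g. the two-positive retest tier).
#'
#' @param n_patients Number of additional procedures, `>= 0`.
#' @param params A [cost_params()].
#' @return Incremental cost, rounded to cents.
#' @export
tier_cost <- function(n_patients, params = cost_params()) {
  assert_nonneg(n_patients, "n_patients")
  round(n_patients * params$colonoscopy_unit_cost, 2)
}

#' @export
print.cost_report <- function(x, ...) {
  cur <- x$params$currency
  fmt <- function(v) formatC(v, format = "f", digits = 2, big.mark = ",")
  cat("Protocol cost report\n")
  cat(sprintf("  %d-round tests on %s people: %s %s\n", x$params$n_fit_rounds,
              format_count(x$cohort_size, 0), cur, fmt(x$fit_total)))
  cat(sprintf("  %s urgent colonoscopies:      %s %s\n",
              format_count(x$urgent_count, 0), cur, fmt(x$colonoscopy_total)))
  cat(sprintf("  protocol total:   %s %s\n", cur, fmt(x$protocol_total)))
  cat(sprintf("  full screening:   %s %s\n", cur, fmt(x$full_screen_total)))
  cat(sprintf("  savings:          %s %s\n", cur, fmt(x$savings)))
  invisible(x)
}
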