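#' Triage tier thresholds
#'
#' Defines the rule mapping a profile's posterior to an action tier:
#' `urgent` (posterior at or above `urgent_threshold`: prioritise for
#' confirmatory colonoscopy), `elevated` (posterior at least
#' `elevated_multiplier` times a reference prevalence: retest or schedule),
#' otherwise `routine` (defer). The default 4% urgent threshold captures
#' exactly the all-positive and one-negative depth-4 profiles in the worked
#' cohorts (posteriors 81.1%/9.2%, 72.0%/4.6%, 78.4%/6.4%) while excluding
#' every lower row.
#'
#' @param urgent_threshold Posterior probability at/above which a profile is
#'   urgent, in `(0, 1]`. Default 0.04.
#' @param elevated_multiplier Fold increase over `reference_prevalence`
#'   marking the retest tier, `> 1`. Default 10.
#' @param reference_prevalence Reference prevalence for the elevated tier;
#'   `NULL` means "use the root cohort's prevalence".
#' @return An object of class `tier_spec`.
#' @export
tier_spec <- function(urgent_threshold = 0.04, elevated_multiplier = 10,
                      reference_prevalence = NULL) {
  if (!is.numeric(urgent_threshold) || urgent_threshold <= 0 || urgent_threshold > 1)
    stop("`urgent_threshold` must lie in (0, 1]", call. = FALSE)
  if (!is.numeric(elevated_multiplier) || elevated_multiplier <= 1)
    stop("`elevated_multiplier` must exceed 1", call. = FALSE)
  if (!is.null(reference_prevalence)) assert_prob(reference_prevalence, "reference_prevalence")
  structure(list(urgent_threshold = urgent_threshold,
                 elevated_multiplier = elevated_multiplier,
                 reference_prevalence = reference_prevalence),
            class = "tier_spec")
}

#' Assign action tiers to aggregated profiles
#'
#' Maps each aggregated outcome profile to a tier and computes the headline
#' triage counts. Two integerisation renderings are emitted because
#' fractional expected headcounts must become whole patients somewhere:
#' per-row flooring (canonical) and per-row nearest-integer rounding. The
#' fractional urgent count is reported both exactly and as the sum of the
#' half-up 2-decimal per-row display values (the convention of the printed
#' aggregated tables, where e.g. 6.86 + 89.43 = 96.29).
#'
#' @param rows A `ubd_profiles` table from [aggregate_profiles()].
#' @param spec A [tier_spec()].
#' @return An object of class `tier_report`: list with `assignments` (the
#'   rows plus `tier`, `count_floor`, `count_nearest`), `cohort_size`,
#'   `urgent_fractional_exact`, `urgent_fractional` (display-rounded
#'   convention), `urgent_count_floor`, `urgent_count_nearest`,
#'   `urgent_count_integer` (canonical = floor), and reduction percentages
#'   under each counting rule.
#' @examples
#' metro <- cohort_state(100000, 19.6 / 100000)
#' fit <- test_characteristics(0.73, 0.94)
#' assign_tiers(aggregate_profiles(metro, fit, 4), tier_spec())
#' @export
assign_tiers <- function(rows, spec = tier_spec()) {
  stopifnot(inherits(rows, "ubd_profiles"), inherits(spec, "tier_spec"))
  if (nrow(rows) == 0L) stop("empty profile table", call. = FALSE)
  root <- attr(rows, "root")
  ref <- spec$reference_prevalence %||% root$prevalence
  post <- rows$posterior
  tier <- ifelse(!is.na(post) & post >= spec$urgent_threshold, "urgent",
          ifelse(!is.na(post) & post >= spec$elevated_multiplier * ref,
                 "elevated", "routine"))
  assignments <- as.data.frame(rows)
  assignments$tier <- tier
  assignments$count_floor <- floor(assignments$concerned)
  assignments$count_nearest <- round_half_up(assignments$concerned, 0)

  urg <- assignments$tier == "urgent"
  cohort_size <- root$size
  urgent_fractional_exact <- sum(assignments$concerned[urg])
  urgent_fractional <- sum(round_half_up(assignments$concerned[urg], 2))
  urgent_count_floor <- sum(assignments$count_floor[urg])
  urgent_count_nearest <- sum(assignments$count_nearest[urg])

  red <- function(n) 100 * (cohort_size - n) / cohort_size
  structure(list(
    assignments = assignments,
    spec = spec,
    cohort_size = cohort_size,
    urgent_fractional_exact = urgent_fractional_exact,
    urgent_fractional = urgent_fractional,
    urgent_count_floor = urgent_count_floor,
    urgent_count_nearest = urgent_count_nearest,
    urgent_count_integer = urgent_count_floor,
    reduction_percent = red(urgent_count_floor),
    reduction_percent_nearest = red(urgent_count_nearest),
    reduction_percent_fractional = red(urgent_fractional_exact)
  ), class = "tier_report")
}

#' @export
print.tier_report <- function(x, ...) {
  cat("Triage tier report\n")
  a <- x$assignments
  cat(sprintf("  %-8s %12s  %-8s\n", "profile", "concerned", "tier"))
  for (i in seq_len(nrow(a)))
    cat(sprintf("  %-8s %12s  %-8s\n", a$label[i],
                format_count(a$concerned[i]), a$tier[i]))
  cat(sprintf("  urgent: %.2f expected (%d floored / %d nearest) of %s\n",
              x$urgent_fractional_exact, x$urgent_count_integer,
              x$urgent_count_nearest, format_count(x$cohort_size)))
  cat(sprintf("  waiting-list reduction: %.1f%% (floor) / %.1f%% (nearest)\n",
              x$reduction_percent, x$reduction_percent_nearest))
  invisible(x)
}

#' Waiting-list reduction achieved by a triage policy
#'
#' Percentage of the cohort that does not need an urgent confirmatory
#' procedure: `100 * (cohort_size - urgent) / cohort_size`.
#'
#' @param report A [assign_tiers()] result.
#' @param cohort_size Cohort headcount; defaults to the report's root size.
#' @param counting Which urgent count to use: `"floor"` (canonical per-row
#'   flooring), `"nearest"` (per-row nearest integer), or `"fractional"`
#'   (exact expected headcount).
#' @return The reduction percentage (0--100).
#' @export
waiting_list_reduction <- function(report, cohort_size = report$cohort_size,
                                   counting = c("floor", "nearest", "fractional")) {
  stopifnot(inherits(report, "tier_report"))
  counting <- match.arg(counting)
  assert_nonneg(cohort_size, "cohort_size")
  if (cohort_size <= 0) stop("`cohort_size` must be positive", call. = FALSE)
  n <- switch(counting,
              floor = report$urgent_count_floor,
              nearest = report$urgent_count_nearest,
              fractional = report$urgent_fractional_exact)
  100 * (cohort_size - n) / cohort_size
}
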