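#' Run configuration for a full screening report
#'
#' Collects and validates everything one report run needs. Prevalence must
#' arrive with an explicit unit tag -- `"prob"` (probability), `"percent"`,
#' or `"per100k"` -- and is converted to a probability once, up front; the
#' unit is never inferred from magnitude.
#'
#' @param cohort_size Cohort headcount, `> 0`.
#' @param prevalence Prevalence in the unit named by `prevalence_unit`.
#' @param prevalence_unit One of `"prob"`, `"percent"`, `"per100k"`.
#' @param sensitivity,specificity Test characteristics, probabilities.
#' @param depth Number of test rounds (default 4, the protocol's working
#'   optimum).
#' @param tiers A [tier_spec()].
#' @param costs A [cost_params()] (its `n_fit_rounds` is synchronised to
#'   `depth`).
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort_size, prevalence,
                       prevalence_unit = c("prob", "percent", "per100k"),
                       sensitivity, specificity, depth = 4,
                       tiers = tier_spec(), costs = cost_params()) {
  prevalence_unit <- match.arg(prevalence_unit)
  assert_nonneg(cohort_size, "cohort_size")
  if (cohort_size <= 0) stop("`cohort_size` must be positive", call. = FALSE)
  assert_nonneg(prevalence, "prevalence")
  p <- switch(prevalence_unit,
              prob = prevalence,
              percent = prevalence / 100,
              per100k = prevalence / 1e5)
  assert_prob(p, "prevalence (after unit conversion)")
  assert_prob(sensitivity, "sensitivity")
  assert_prob(specificity, "specificity")
  depth <- assert_count(depth, "depth")
  stopifnot(inherits(tiers, "tier_spec"), inherits(costs, "cost_params"))
  costs$n_fit_rounds <- depth
  structure(list(cohort_size = cohort_size, prevalence = p,
                 prevalence_unit = prevalence_unit,
                 sensitivity = sensitivity, specificity = specificity,
                 depth = depth, tiers = tiers, costs = costs),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' Accepted keys: `cohort_size`, `prevalence`, `prevalence_unit`,
#' `sensitivity`, `specificity`, `depth`, `urgent_threshold`,
#' `elevated_multiplier`, `reference_prevalence`, `fit_cost`,
#' `colonoscopy_cost`, `currency`.
#'
#' @param path Path to a JSON config file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  required <- c("cohort_size", "prevalence", "prevalence_unit",
                "sensitivity", "specificity")
  missing <- setdiff(required, names(cfg))
  if (length(missing))
    stop("config is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  run_config(
    cohort_size = cfg$cohort_size,
    prevalence = cfg$prevalence,
    prevalence_unit = cfg$prevalence_unit,
    sensitivity = cfg$sensitivity,
    specificity = cfg$specificity,
    depth = cfg$depth %||% 4,
    tiers = tier_spec(
      urgent_threshold = cfg$urgent_threshold %||% 0.04,
      elevated_multiplier = cfg$elevated_multiplier %||% 10,
      reference_prevalence = cfg$reference_prevalence),
    costs = cost_params(
      fit_unit_cost = cfg$fit_cost %||% 5,
      colonoscopy_unit_cost = cfg$colonoscopy_cost %||% 500,
      currency = cfg$currency %||% "USD"))
}

#' Run the full deterministic report bundle
#'
#' Expands the recursion at the configured depth, aggregates by outcome
#' profile, assigns triage tiers, prices the protocol (using the canonical
#' floored urgent count), and traces the posterior trajectories for every
#' fixed number of negatives up to the depth. Depth 0 returns only the root
#' cohort echo.
#'
#' @param config A [run_config()].
#' @return An object of class `ubd_report`: list with `config`, `root`,
#'   `test`, and (for depth `>= 1`) `profiles`, `tiers`, `cost`,
#'   `trajectories`.
#' @export
run_report <- function(config) {
  stopifnot(inherits(config, "run_config"))
  test <- test_characteristics(config$sensitivity, config$specificity)
  root <- cohort_state(config$cohort_size, config$prevalence)
  out <- list(config = config, root = root, test = test)
  if (config$depth >= 1L) {
    profiles <- aggregate_profiles(root, test, config$depth)
    tiers <- assign_tiers(profiles, config$tiers)
    out$profiles <- profiles
    out$tiers <- tiers
    out$cost <- protocol_cost(config$cohort_size, tiers$urgent_count_integer,
                              config$costs)
    out$trajectories <- lapply(0:config$depth, function(j)
      ubd_trajectory(config$prevalence, test, j, config$depth))
    names(out$trajectories) <- paste0("negatives_", 0:config$depth)
  }
  structure(out, class = "ubd_report")
}

#' @export
print.ubd_report <- function(x, ...) {
  cat(sprintf("Screening report: cohort %s, prevalence %s, depth %d\n",
              format_count(x$config$cohort_size, 0),
              format_pct(x$config$prevalence), x$config$depth))
  if (!is.null(x$profiles)) {
    print(render_table(x$profiles), row.names = FALSE)
    cat("\n")
    print(x$tiers)
    cat("\n")
    print(x$cost)
  }
  invisible(x)
}

#' Render an aggregated profile table in a printed-table style
#'
#' Counts are shown at 2 decimals (half-up), posteriors as percentages at 6
#' decimals (9 below 0.001%). Two column conventions exist in the field's
#' tables: `"sick-healthy"` labels the count columns by disease status;
#' `"correct-result"` labels them by whether the (last) test result was
#' correct, so the columns swap on negative-ending profiles. Rendering is a
#' pure presentation layer: nothing rounded here ever feeds back into
#' computation.
#'
#' @param rows A `ubd_profiles` data frame (or any data frame with `label`,
#'   `concerned`, `sick`, `healthy`, `posterior`).
#' @param style `"sick-healthy"` (default) or `"correct-result"`.
#' @return A data frame of formatted character columns `profile`,
#'   `concerned`, `true`, `false`, `sickness_prob`. Empty input yields a
#'   header-only (zero-row) frame.
#' @export
render_table <- function(rows, style = c("sick-healthy", "correct-result")) {
  style <- match.arg(style)
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L)
    return(data.frame(profile = character(), concerned = character(),
                      true = character(), false = character(),
                      sickness_prob = character(), stringsAsFactors = FALSE))
  a <- rows$sick
  b <- rows$healthy
  if (style == "correct-result") {
    neg_end <- !grepl("\\+$", rows$label) # last test negative: correct = healthy
    tmp <- a
    a <- ifelse(neg_end, b, a)
    b <- ifelse(neg_end, tmp, b)
  }
  data.frame(
    profile = paste0("FIT", rows$label),
    concerned = format_count(rows$concerned),
    true = format_count(a),
    false = format_count(b),
    sickness_prob = format_pct(rows$posterior),
    stringsAsFactors = FALSE)
}

#' Write / read an aggregated profile table as full-precision CSV
#'
#' Numeric columns are serialised as 17-significant-digit decimal strings,
#' so a write/read round trip reproduces every double bit-for-bit.
#'
#' @param rows A `ubd_profiles` data frame.
#' @param path Output CSV path.
#' @return `write_profiles_csv` returns `path` invisibly;
#'   `read_profiles_csv` returns the data frame with numeric columns
#'   restored.
#' @export
write_profiles_csv <- function(rows, path) {
  df <- as.data.frame(rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], format_full)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  numcols <- setdiff(names(df), "label")
  df[numcols] <- lapply(df[numcols], as.numeric)
  df
}

#' Serialise a report bundle to JSON
#'
#' Every number is emitted at full precision (no digit truncation); the
#' display-rounded strings of [render_table()] are included alongside under
#' `rendered`.
#'
#' @param report A [run_report()] bundle.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_to_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "ubd_report"))
  payload <- list(
    config = unclass(report$config)[c("cohort_size", "prevalence",
                                      "sensitivity", "specificity", "depth")],
    test = unclass(report$test))
  if (!is.null(report$profiles)) {
    payload$profiles <- as.data.frame(report$profiles)
    payload$rendered <- render_table(report$profiles)
    payload$tiers <- report$tiers[c("cohort_size", "urgent_fractional_exact",
                                    "urgent_fractional", "urgent_count_floor",
                                    "urgent_count_nearest", "urgent_count_integer",
                                    "reduction_percent", "reduction_percent_nearest",
                                    "reduction_percent_fractional")]
    payload$tiers$assignments <- report$tiers$assignments
    payload$cost <- unclass(report$cost)[c("fit_total", "colonoscopy_total",
                                           "protocol_total", "full_screen_total",
                                           "savings")]
    payload$trajectories <- report$trajectories
  }
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows", pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
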