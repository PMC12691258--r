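#' Observed confusion table of a validated test
#'
#' Integer TP/FP/TN/FN counts from a study in which every subject received
#' both the cheap test and the gold-standard confirmation.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts. At least one sick subject
#'   (`tp + fn >= 1`) and one healthy subject (`fp + tn >= 1`) are required
#'   so that sensitivity and specificity are defined.
#' @return An object of class `confusion_table`.
#' @export
confusion_table <- function(tp, fp, tn, fn) {
  tp <- assert_count(tp, "tp"); fp <- assert_count(fp, "fp")
  tn <- assert_count(tn, "tn"); fn <- assert_count(fn, "fn")
  if (tp + fn < 1L) stop("tp + fn must be >= 1 to define sensitivity", call. = FALSE)
  if (fp + tn < 1L) stop("fp + tn must be >= 1 to define specificity", call. = FALSE)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn),
            class = "confusion_table")
}

#' Deduce prevalence and test characteristics from a confusion table
#'
#' The three priors the recursion needs -- prevalence, sensitivity,
#' specificity -- plus the cohort-dependent predictive values, all as exact
#' integer ratios (no display rounding enters the computation):
#' `prevalence = (tp+fn)/n`, `sensitivity = tp/(tp+fn)`,
#' `specificity = tn/(fp+tn)`, `ppv = tp/(tp+fp)`, `npv = tn/(tn+fn)`.
#'
#' @param table A [confusion_table()].
#' @return An object of class `calibration_result`: `n`, `prevalence`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `lr_positive`,
#'   `lr_negative`, and `test` (the [test_characteristics()] ready for
#'   [bayes_split()]). Quantities with a zero denominator (e.g. PPV when no
#'   subject tested positive) are `NA`.
#' @examples
#' cal <- calibrate_confusion(confusion_table(tp = 26, fp = 256, tn = 525, fn = 1))
#' 100 * cal$sensitivity  # 96.2962962963
#' @export
calibrate_confusion <- function(table) {
  stopifnot(inherits(table, "confusion_table"))
  n <- table$tp + table$fp + table$tn + table$fn
  sens <- table$tp / (table$tp + table$fn)
  spec <- table$tn / (table$fp + table$tn)
  test <- test_characteristics(sens, spec)
  structure(list(
    n = n,
    prevalence = (table$tp + table$fn) / n,
    sensitivity = sens, specificity = spec,
    ppv = if (table$tp + table$fp > 0) table$tp / (table$tp + table$fp) else NA_real_,
    npv = if (table$tn + table$fn > 0) table$tn / (table$tn + table$fn) else NA_real_,
    lr_positive = test$lr_positive,
    lr_negative = test$lr_negative,
    test = test, table = table
  ), class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("Calibration from %d validated subjects\n", x$n))
  cat(sprintf("  prevalence:  %.10f (%d/%d)\n", x$prevalence,
              x$table$tp + x$table$fn, x$n))
  cat(sprintf("  sensitivity: %.10f   specificity: %.10f\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  PPV: %s   NPV: %s\n", format_pct(x$ppv), format_pct(x$npv)))
  cat(sprintf("  LR+: %s   LR-: %s\n",
              if (is.na(x$lr_positive)) "undefined" else sprintf("%.4f", x$lr_positive),
              if (is.na(x$lr_negative)) "undefined" else sprintf("%.4f", x$lr_negative)))
  invisible(x)
}

#' Stratified-prevalence indicator observation
#'
#' Counts describing a binary risk indicator (e.g. "aged 65--75") observed
#' on a fully diagnosed cohort: total cohort size and sick count, and the
#' size and sick count of the indicator-positive stratum.
#'
#' @param cohort_size,cohort_sick,stratum_size,stratum_sick Nonnegative
#'   integer counts with `stratum_sick <= min(stratum_size, cohort_sick)`
#'   and `stratum_size <= cohort_size`.
#' @return An object of class `stratum_spec`.
#' @export
stratum_spec <- function(cohort_size, cohort_sick, stratum_size, stratum_sick) {
  cohort_size <- assert_count(cohort_size, "cohort_size", 1L)
  cohort_sick <- assert_count(cohort_sick, "cohort_sick")
  stratum_size <- assert_count(stratum_size, "stratum_size")
  stratum_sick <- assert_count(stratum_sick, "stratum_sick")
  if (cohort_sick > cohort_size) stop("cohort_sick exceeds cohort_size", call. = FALSE)
  if (stratum_size > cohort_size) stop("stratum_size exceeds cohort_size", call. = FALSE)
  if (stratum_sick > stratum_size) stop("stratum_sick exceeds stratum_size", call. = FALSE)
  if (stratum_sick > cohort_sick) stop("stratum_sick exceeds cohort_sick", call. = FALSE)
  structure(list(cohort_size = cohort_size, cohort_sick = cohort_sick,
                 stratum_size = stratum_size, stratum_sick = stratum_sick),
            class = "stratum_spec")
}

#' Rates deducible from a stratified indicator, in both conventions
#'
#' A risk indicator can be read as a "test", but two distinct rate
#' conventions then coexist and are easy to confuse:
#' * the *complement-predictive-value* convention -- the healthy fraction
#'   among indicator-positives (`complement_ppv = 1 - PPV`) and the sick
#'   fraction among indicator-negatives (`complement_npv = 1 - NPV`); these
#'   are sometimes loosely called "false positive / false negative
#'   percentages";
#' * the *test-characteristic* convention -- `one_minus_specificity =
#'   P(indicator+ | healthy)` and `one_minus_sensitivity =
#'   P(indicator- | sick)`, the quantities the recursion consumes as
#'   pFP/pFN.
#'
#' Both are returned, explicitly named; this function never feeds
#' complement-predictive values into the recursion silently -- callers must
#' pick the convention by field name.
#'
#' @param stratum A [stratum_spec()].
#' @return A list with `stratum_prevalence`, `complement_ppv`,
#'   `complement_npv`, `one_minus_specificity`, `one_minus_sensitivity`,
#'   `sensitivity`, `specificity`, `ppv`, `npv`. Zero denominators give
#'   `NA`.
#' @examples
#' # 1000 diagnosed patients, 100 sick; 400 are aged 65-75, of whom 60 sick:
#' indicator_rates(stratum_spec(1000, 100, 400, 60))
#' @export
indicator_rates <- function(stratum) {
  stopifnot(inherits(stratum, "stratum_spec"))
  s <- stratum
  comp_size <- s$cohort_size - s$stratum_size     # indicator-negatives
  comp_sick <- s$cohort_sick - s$stratum_sick
  healthy <- s$cohort_size - s$cohort_sick
  rat <- function(num, den) if (den > 0) num / den else NA_real_
  list(
    stratum_prevalence = rat(s$stratum_sick, s$stratum_size),
    complement_ppv = rat(s$stratum_size - s$stratum_sick, s$stratum_size),
    complement_npv = rat(comp_sick, comp_size),
    one_minus_specificity = rat(s$stratum_size - s$stratum_sick, healthy),
    one_minus_sensitivity = rat(comp_sick, s$cohort_sick),
    sensitivity = rat(s$stratum_sick, s$cohort_sick),
    specificity = rat(healthy - (s$stratum_size - s$stratum_sick), healthy),
    ppv = rat(s$stratum_sick, s$stratum_size),
    npv = rat(comp_size - comp_sick, comp_size)
  )
}
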