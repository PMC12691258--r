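#' Derive the full error-rate profile of a diagnostic test
#'
#' Builds a `test_characteristics` object from a test's sensitivity
#' (P(positive | sick)) and specificity (P(negative | healthy)), deriving the
#' false-positive rate `1 - specificity`, the false-negative rate
#' `1 - sensitivity`, and the likelihood ratios
#' `LR+ = sensitivity / (1 - specificity)` and
#' `LR- = (1 - sensitivity) / specificity`. Likelihood ratios with a zero
#' denominator (perfect specificity, or specificity zero) are reported as
#' `NA`, never fabricated.
#'
#' @param sensitivity Probability that a sick subject tests positive, in
#'   `[0, 1]`.
#' @param specificity Probability that a healthy subject tests negative, in
#'   `[0, 1]`.
#' @return An object of class `test_characteristics`: a list with fields
#'   `sensitivity`, `specificity`, `p_false_positive`, `p_false_negative`,
#'   `lr_positive`, `lr_negative`.
#' @examples
#' fit <- test_characteristics(0.73, 0.94)
#' fit$lr_positive   # ~12.2: a positive FIT multiplies the odds of disease
#' @export
test_characteristics <- function(sensitivity, specificity) {
  assert_prob(sensitivity, "sensitivity")
  assert_prob(specificity, "specificity")
  structure(list(
    sensitivity      = sensitivity,
    specificity      = specificity,
    p_false_positive = 1 - specificity,
    p_false_negative = 1 - sensitivity,
    lr_positive      = if (specificity < 1) sensitivity / (1 - specificity) else NA_real_,
    lr_negative      = if (specificity > 0) (1 - sensitivity) / specificity else NA_real_
  ), class = "test_characteristics")
}

#' @export
print.test_characteristics <- function(x, ...) {
  cat("Diagnostic test characteristics\n")
  cat(sprintf("  sensitivity: %.6g   specificity: %.6g\n",
              x$sensitivity, x$specificity))
  cat(sprintf("  P(FP): %.6g   P(FN): %.6g\n",
              x$p_false_positive, x$p_false_negative))
  cat(sprintf("  LR+: %s   LR-: %s\n",
              if (is.na(x$lr_positive)) "undefined" else sprintf("%.6g", x$lr_positive),
              if (is.na(x$lr_negative)) "undefined" else sprintf("%.6g", x$lr_negative)))
  invisible(x)
}

#' Cohort state acted on by the recursion
#'
#' A cohort is an expected headcount (fractional values are legitimate
#' deductive expectations, not observed patients), a disease prevalence, and
#' a profile label recording the test history that produced it (`""` for the
#' root cohort, e.g. `"+-"` after a positive then a negative test).
#'
#' @param size Expected headcount, nonnegative real.
#' @param prevalence Probability that a member is sick, in `[0, 1]`.
#' @param profile Test-history label over the alphabet `+`/`-`.
#' @return An object of class `cohort_state`.
#' @export
cohort_state <- function(size, prevalence, profile = "") {
  assert_nonneg(size, "size")
  assert_prob(prevalence, "prevalence")
  if (!is.character(profile) || length(profile) != 1L ||
      grepl("[^+-]", profile))
    stop("`profile` must be a single string over the alphabet {+, -}",
         call. = FALSE)
  structure(list(size = size, prevalence = prevalence, profile = profile),
            class = "cohort_state")
}

#' @export
print.cohort_state <- function(x, ...) {
  cat(sprintf("Cohort [%s]: expected size %.4f, prevalence %s\n",
              if (nzchar(x$profile)) x$profile else "root",
              x$size, format_pct(x$prevalence)))
  invisible(x)
}

#' Split a cohort by the outcome of one Bayesian test round
#'
#' Performs the single-round computation block of the recursion: expected
#' sick/healthy headcounts, the four confusion cells, the positive and
#' negative subcohort sizes, and the Bayes-updated prevalence of each
#' subcohort (`P(sick | positive) = nTP / nPos`,
#' `P(sick | negative) = nFN / nNeg`). All quantities are real-valued
#' expectations; no rounding happens inside the computation.
#'
#' @param cohort A [cohort_state()].
#' @param test A [test_characteristics()].
#' @return An object of class `split_result` with fields `n_sick`,
#'   `n_healthy`, `n_tp`, `n_fp`, `n_tn`, `n_fn`, `n_pos`, `n_neg`,
#'   `prevalence_pos`, `prevalence_neg`. An empty branch (zero expected
#'   size) has an `NA` prevalence: an explicit "undefined" marker, not a
#'   NaN artefact.
#' @examples
#' metro <- cohort_state(100000, 19.6 / 100000)
#' fit <- test_characteristics(0.73, 0.94)
#' s <- bayes_split(metro, fit)
#' 100 * s$prevalence_pos  # 0.238%: one positive FIT is far from diagnostic
#' @export
bayes_split <- function(cohort, test) {
  stopifnot(inherits(cohort, "cohort_state"), inherits(test, "test_characteristics"))
  n_sick    <- cohort$size * cohort$prevalence
  n_healthy <- cohort$size - n_sick
  n_fn <- n_sick * test$p_false_negative
  n_tp <- n_sick - n_fn
  n_fp <- n_healthy * test$p_false_positive
  n_tn <- n_healthy - n_fp
  n_pos <- n_tp + n_fp
  n_neg <- n_tn + n_fn
  structure(list(
    n_sick = n_sick, n_healthy = n_healthy,
    n_tp = n_tp, n_fp = n_fp, n_tn = n_tn, n_fn = n_fn,
    n_pos = n_pos, n_neg = n_neg,
    prevalence_pos = if (n_pos > 0) n_tp / n_pos else NA_real_,
    prevalence_neg = if (n_neg > 0) n_fn / n_neg else NA_real_
  ), class = "split_result")
}

#' @export
print.split_result <- function(x, ...) {
  cat("One-round Bayesian split (expected headcounts)\n")
  cat(sprintf("  sick %.4f / healthy %.4f\n", x$n_sick, x$n_healthy))
  cat(sprintf("  TP %.4f  FP %.4f  TN %.4f  FN %.4f\n",
              x$n_tp, x$n_fp, x$n_tn, x$n_fn))
  cat(sprintf("  positive branch: n = %.4f, prevalence = %s\n",
              x$n_pos, format_pct(x$prevalence_pos)))
  cat(sprintf("  negative branch: n = %.4f, prevalence = %s\n",
              x$n_neg, format_pct(x$prevalence_neg)))
  invisible(x)
}

#' Closed-form posterior after an outcome profile
#'
#' Posterior probability of disease after observing `k_pos` positive and
#' `k_neg` negative results of the same test, starting from `prior`.
#' Computed in the joint-likelihood form
#' \deqn{P(s \mid k_+, k_-) = \frac{p\,se^{k_+}(1-se)^{k_-}}
#'   {p\,se^{k_+}(1-se)^{k_-} + (1-p)(1-sp)^{k_+}sp^{k_-}}}
#' which is the compounded likelihood-ratio update of the prior odds and is
#' therefore invariant to the order in which the results arrived: it equals
#' applying [bayes_split()] sequentially along any ordering of the profile.
#' The form stays well defined at the boundaries (perfect tests) where the
#' likelihood ratios themselves are undefined.
#'
#' @param prior Prior probability of disease, in `[0, 1]`.
#' @param test A [test_characteristics()].
#' @param k_pos,k_neg Nonnegative integer counts of positive and negative
#'   results.
#' @return The posterior probability. A profile with probability zero under
#'   both hypotheses (an empty branch, e.g. a positive result from a perfect
#'   test applied to a disease-free cohort) raises an error.
#' @examples
#' fit <- test_characteristics(0.73, 0.94)
#' posterior_after_profile(0.000196, fit, 4, 0)  # four straight positives
#' @export
posterior_after_profile <- function(prior, test, k_pos, k_neg) {
  assert_prob(prior, "prior")
  stopifnot(inherits(test, "test_characteristics"))
  k_pos <- assert_count(k_pos, "k_pos")
  k_neg <- assert_count(k_neg, "k_neg")
  w_sick    <- prior * test$sensitivity^k_pos * test$p_false_negative^k_neg
  w_healthy <- (1 - prior) * test$p_false_positive^k_pos * test$specificity^k_neg
  total <- w_sick + w_healthy
  if (total == 0)
    stop("profile (", k_pos, "+, ", k_neg,
         "-) has zero probability under this prior and test: ",
         "posterior undefined (empty branch)", call. = FALSE)
  w_sick / total
}
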