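#' Configuration of a patient-level Monte-Carlo run
#'
#' @param n_patients Number of simulated patients, `>= 1`.
#' @param prevalence Bernoulli disease probability.
#' @param test A [test_characteristics()].
#' @param n_rounds Number of independent test rounds per patient, `>= 1`.
#' @param seed Integer RNG seed (the run is reproducible given the seed).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_patients, prevalence, test, n_rounds, seed) {
  n_patients <- assert_count(n_patients, "n_patients", 1L)
  assert_prob(prevalence, "prevalence")
  stopifnot(inherits(test, "test_characteristics"))
  n_rounds <- assert_count(n_rounds, "n_rounds", 1L)
  seed <- assert_count(seed, "seed")
  structure(list(n_patients = n_patients, prevalence = prevalence,
                 test = test, n_rounds = n_rounds, seed = seed),
            class = "simulation_config")
}

#' Simulate a cohort of patients under conditional independence
#'
#' The stochastic oracle for the deterministic expected-count machinery:
#' each patient's disease status is Bernoulli(prevalence), and conditional
#' on status the `n_rounds` test results are independent
#' Bernoulli(sensitivity) (sick) or Bernoulli(1 - specificity) (healthy) --
#' exactly the independence assumption of the analytic recursion, with no
#' between-round dependence knob. Draw order is fixed and documented for
#' platform stability: first the disease-status vector, then one
#' positive-count draw per patient.
#'
#' @param config A [simulation_config()].
#' @return An object of class `simulation_result`: `profiles`, a data frame
#'   with one row per number of positives (`n_positive`, `sick_observed`,
#'   `healthy_observed`, `observed`, `sick_expected`, `healthy_expected`,
#'   `expected`, `z` -- the observed total against its binomial standard
#'   deviation); plus `n_sick_realised` and the `config`.
#' @examples
#' fit <- test_characteristics(0.96, 0.67)
#' sim <- simulate_cohort(simulation_config(10000, 0.03, fit, 4, seed = 1))
#' sim$profiles
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  n <- config$n_patients
  rounds <- config$n_rounds
  test <- config$test
  sick <- stats::rbinom(n, 1L, config$prevalence) == 1L
  p_pos <- ifelse(sick, test$sensitivity, test$p_false_positive)
  k <- stats::rbinom(n, rounds, p_pos)

  ks <- 0:rounds
  count_by_k <- function(mask) {
    tab <- tabulate(k[mask] + 1L, nbins = rounds + 1L)
    tab
  }
  sick_obs <- count_by_k(sick)
  healthy_obs <- count_by_k(!sick)

  # Analytic expectations under the deductive model (expected sick = n * p).
  sick_exp <- n * config$prevalence * stats::dbinom(ks, rounds, test$sensitivity)
  healthy_exp <- n * (1 - config$prevalence) *
    stats::dbinom(ks, rounds, test$p_false_positive)
  expected <- sick_exp + healthy_exp
  q <- expected / n
  sd <- sqrt(n * q * (1 - q))
  obs <- sick_obs + healthy_obs
  z <- ifelse(sd > 0, (obs - expected) / sd, ifelse(obs == expected, 0, Inf))

  structure(list(
    profiles = data.frame(
      n_positive = ks,
      label = vapply(ks, profile_label, character(1), n_tests = rounds),
      sick_observed = sick_obs, healthy_observed = healthy_obs,
      observed = obs,
      sick_expected = sick_exp, healthy_expected = healthy_exp,
      expected = expected, z = z, stringsAsFactors = FALSE),
    n_sick_realised = sum(sick),
    config = config
  ), class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  cat(sprintf("Monte-Carlo cohort: %d patients, %d rounds, seed %d (%d sick realised)\n",
              x$config$n_patients, x$config$n_rounds, x$config$seed,
              x$n_sick_realised))
  print(x$profiles, row.names = FALSE, digits = 4)
  invisible(x)
}
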