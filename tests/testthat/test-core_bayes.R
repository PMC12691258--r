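test_that("test_characteristics derives error rates and likelihood ratios", {
  # Symptomatic-cohort FIT: values frozen from an independent numeric check
  # of sens/(1-spec) and (1-sens)/spec at these exact ratios.
  t1 <- test_characteristics(26 / 27, 525 / 781)
  expect_equal(t1$lr_positive, 2.9377894, tolerance = 1e-6)
  expect_equal(t1$lr_negative, 0.0550970, tolerance = 1e-6)

  t2 <- test_characteristics(0.73, 0.94)
  expect_identical(t2$p_false_positive, 1 - 0.94)
  expect_identical(t2$p_false_negative, 1 - 0.73)
  expect_equal(t2$p_false_positive + t2$specificity, 1)
  expect_equal(t2$p_false_negative + t2$sensitivity, 1)

  # Perfect test: error rates zero, LR+ undefined (not fabricated).
  t3 <- test_characteristics(1, 1)
  expect_identical(t3$p_false_positive, 0)
  expect_identical(t3$p_false_negative, 0)
  expect_true(is.na(t3$lr_positive))
  expect_false(is.na(t3$lr_negative))

  # Specificity 0: LR- undefined.
  expect_true(is.na(test_characteristics(0.5, 0)$lr_negative))

  expect_error(test_characteristics(1.2, 0.5), "sensitivity")
  expect_error(test_characteristics(0.5, -0.1), "specificity")
})

test_that("bayes_split reproduces the worked single-round splits", {
  # Metropolitan cohort, the fully worked ten-quantity block.
  s <- bayes_split(metro_cohort(), metro_test())
  expect_equal(s$n_sick, 19.6)
  expect_equal(s$n_healthy, 99980.4)
  expect_equal(s$n_fn, 5.292)
  expect_equal(s$n_fp, 5998.824)
  expect_equal(s$n_tp, 14.308)
  expect_equal(s$n_tn, 93981.576)
  expect_equal(s$n_pos, 6013.132)
  expect_equal(s$n_neg, 93986.868)
  expect_equal(s$prevalence_pos, 0.00237946, tolerance = 1e-6)
  expect_equal(s$prevalence_neg, 0.00005631, tolerance = 1e-4)

  # Symptomatic L/MR cohort: integer-exact branch sizes.
  s2 <- bayes_split(lmr_cohort(), lmr_test())
  expect_equal(s2$n_pos, 282)
  expect_equal(s2$n_neg, 526)
  expect_equal(s2$prevalence_pos, 26 / 282)

  # Hand-derived oracle: (1000, 0.5) with sens 0.8 / spec 0.9.
  s3 <- bayes_split(cohort_state(1000, 0.5), test_characteristics(0.8, 0.9))
  expect_equal(s3$n_tp, 400)
  expect_equal(s3$n_fp, 50)
  expect_equal(s3$prevalence_pos, 400 / 450)

  # Uninformative test (LR+ = LR- = 1) leaves the prevalence unchanged.
  for (p in c(0.001, 0.3, 0.9)) {
    s4 <- bayes_split(cohort_state(500, p), test_characteristics(0.6, 0.4))
    expect_equal(s4$prevalence_pos, p)
    expect_equal(s4$prevalence_neg, p)
  }

  # Zero-size cohort: all-zero result, undefined branch prevalences.
  s5 <- bayes_split(cohort_state(0, 0.1), metro_test())
  expect_equal(s5$n_pos + s5$n_neg, 0)
  expect_true(is.na(s5$prevalence_pos))
  expect_true(is.na(s5$prevalence_neg))
})

test_that("bayes_split conserves headcounts for randomized parameters", {
  set.seed(42)
  for (i in 1:200) {
    size <- runif(1, 0, 1e6)
    coh <- cohort_state(size, runif(1))
    tst <- test_characteristics(runif(1), runif(1))
    s <- bayes_split(coh, tst)
    expect_equal(s$n_sick + s$n_healthy, size, tolerance = 1e-12)
    expect_equal(s$n_tp + s$n_fn, s$n_sick, tolerance = 1e-12)
    expect_equal(s$n_fp + s$n_tn, s$n_healthy, tolerance = 1e-12)
    expect_equal(s$n_pos + s$n_neg, size, tolerance = 1e-12)
    expect_equal(s$n_tp + s$n_fn + s$n_fp + s$n_tn, size, tolerance = 1e-12)
    if (s$n_pos > 0) expect_equal(s$prevalence_pos * s$n_pos, s$n_tp)
    if (s$n_neg > 0) expect_equal(s$prevalence_neg * s$n_neg, s$n_fn)
  }
})

test_that("posterior_after_profile matches the worked compound posteriors", {
  expect_equal(round(posterior_after_profile(0.000196, metro_test(), 4, 0), 8),
               0.81116533)
  expect_equal(round(posterior_after_profile(27 / 808, lmr_test(), 4, 0), 8),
               0.72028812)
  # No tests: posterior equals prior.
  for (p in c(0, 0.001, 0.5, 1))
    expect_identical(posterior_after_profile(p, metro_test(), 0, 0), p)
})

test_that("posterior is order-invariant and equals sequential splitting", {
  priors <- c(1e-5, 1e-3, 0.03, 0.3)
  tst <- metro_test()
  for (prior in priors) {
    for (n in 0:6) {
      for (seqv in all_sequences(n)) {
        k_pos <- sum(seqv)
        expected <- posterior_after_profile(prior, tst, k_pos, n - k_pos)
        # Oracle: elementary per-step Bayes updates along this ordering.
        expect_equal(
          oracle_sequential_posterior(prior, tst$sensitivity,
                                      tst$specificity, seqv),
          expected, tolerance = 1e-10)
      }
    }
  }
  # Sequential bayes_split chain agrees too (expected-count route).
  p <- 0.03
  for (seqv in all_sequences(4)) {
    prev <- p
    for (pos in seqv) {
      s <- bayes_split(cohort_state(1000, prev), tst)
      prev <- if (pos) s$prevalence_pos else s$prevalence_neg
    }
    expect_equal(prev,
                 posterior_after_profile(p, tst, sum(seqv), 4 - sum(seqv)),
                 tolerance = 1e-10)
  }
})

test_that("posterior is monotone in the evidence and saturates in the limits", {
  tst <- test_characteristics(0.8, 0.9) # LR+ > 1, LR- < 1
  for (k_neg in 0:2) {
    post <- vapply(0:5, function(k)
      posterior_after_profile(0.01, tst, k, k_neg), numeric(1))
    expect_true(all(diff(post) > 0))
  }
  for (k_pos in 0:2) {
    post <- vapply(0:5, function(j)
      posterior_after_profile(0.01, tst, k_pos, j), numeric(1))
    expect_true(all(diff(post) < 0))
  }
  # Near-perfect test drives all-positive to 1 and all-negative to 0.
  sharp <- test_characteristics(1 - 1e-9, 1 - 1e-9)
  expect_equal(posterior_after_profile(0.5, sharp, 6, 0), 1, tolerance = 1e-6)
  expect_equal(posterior_after_profile(0.5, sharp, 0, 6), 0, tolerance = 1e-6)
})

test_that("zero-probability profiles raise an explicit domain error", {
  perfect <- test_characteristics(1, 1)
  # Disease-free cohort cannot produce a positive from a perfect test.
  expect_error(posterior_after_profile(0, perfect, 1, 0), "zero probability")
  # All-sick cohort cannot produce a negative.
  expect_error(posterior_after_profile(1, perfect, 0, 1), "zero probability")
  # But the well-defined boundary cases pass through the direct form.
  expect_equal(posterior_after_profile(0.3, perfect, 2, 0), 1)
  expect_equal(posterior_after_profile(0.3, perfect, 0, 2), 0)
})
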