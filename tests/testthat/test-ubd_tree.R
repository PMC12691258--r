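test_that("ubd_expand builds the recursion tree with inherited subcohorts", {
  # Depth 0: a bare root.
  n0 <- ubd_expand(metro_cohort(), metro_test(), 0)
  expect_null(n0$split)
  expect_null(n0$children)

  n2 <- ubd_expand(metro_cohort(), metro_test(), 2)
  # Children inherit exactly the parent's split outputs.
  expect_equal(n2$children$positive$state$size, n2$split$n_pos)
  expect_equal(n2$children$positive$state$prevalence, n2$split$prevalence_pos)
  expect_equal(n2$children$negative$state$size, n2$split$n_neg)
  expect_equal(n2$children$negative$state$prevalence, n2$split$prevalence_neg)
  expect_equal(n2$children$positive$state$profile, "+")

  # The ++ leaf of the two-round metro tree (printed worked table).
  pp <- n2$children$positive$children$positive$state
  expect_equal(round(pp$size, 2), 370.37)
  expect_equal(round(pp$prevalence, 8), 0.02820077)

  # Conservation oracle: the four depth-2 leaves sum back to 808.
  lv <- ubd_leaves(ubd_expand(lmr_cohort(), lmr_test(), 2))
  expect_equal(nrow(lv), 4L)
  expect_equal(sum(lv$size), 808, tolerance = 1e-12)
  expect_equal(nchar(lv$profile), rep(2L, 4))

  expect_error(ubd_expand(metro_cohort(), metro_test(), 13), "maximum")
  # Disease-free cohort with a perfect test: positive branch is pruned.
  n1 <- ubd_expand(cohort_state(100, 0), test_characteristics(1, 1), 1)
  expect_null(n1$children$positive)
  expect_equal(n1$children$negative$state$size, 100)
})

test_that("aggregate_profiles reproduces the printed depth-4 tables", {
  p <- aggregate_profiles(metro_cohort(), metro_test(), 4)
  expect_equal(p$n_positive, 4:0)
  expect_equal(p$label, c("++++", "+++-", "++--", "+---", "----"))
  expect_equal(p$multiplicity, choose(4, 4:0))
  expect_equal(round(p$concerned[1], 2), 6.86)
  expect_equal(round(p$sick[1], 2), 5.57)
  expect_equal(round(p$healthy[1], 2), 1.30)
  expect_equal(round(p$concerned[4], 2), 19931.24)

  # High-risk symptomatic cohort, all-positive row.
  ph <- aggregate_profiles(hr_cohort(), lmr_test(), 4)
  expect_equal(round(ph$concerned[1], 2), 17.56)
  expect_equal(round(ph$sick[1], 2), 13.76)
  expect_equal(round(ph$healthy[1], 2), 3.80)

  # Depth-2 one-positive row: twice the printed single-ordering value.
  p2 <- aggregate_profiles(metro_cohort(), metro_test(), 2)
  expect_equal(round(p2$concerned[p2$n_positive == 1], 2), 2 * 5642.76)
  expect_equal(round(p2$posterior[p2$n_positive == 1], 8), 0.00068462)
})

test_that("aggregation satisfies its conservation and consistency invariants", {
  set.seed(7)
  for (i in 1:20) {
    root <- cohort_state(runif(1, 10, 1e5), runif(1, 1e-5, 0.5))
    tst <- test_characteristics(runif(1, 0.05, 0.99), runif(1, 0.05, 0.99))
    depth <- sample(1:8, 1)
    p <- aggregate_profiles(root, tst, depth)
    expect_equal(sum(p$multiplicity), 2^depth)
    expect_equal(sum(p$concerned), root$size, tolerance = 1e-9)
    expect_equal(sum(p$sick), root$size * root$prevalence, tolerance = 1e-9)
    expect_equal(p$concerned, p$sick + p$healthy, tolerance = 1e-12)
    # Posterior column equals the closed-form single-profile posterior.
    expect_equal(p$posterior,
                 vapply(p$n_positive, function(k)
                   posterior_after_profile(root$prevalence, tst, k, depth - k),
                   numeric(1)),
                 tolerance = 1e-12)
  }
})

test_that("aggregation agrees with brute-force sequence enumeration", {
  set.seed(11)
  for (i in 1:10) {
    size <- runif(1, 1, 1e4)
    prev <- runif(1, 1e-4, 0.6)
    sens <- runif(1, 0.1, 0.99)
    spec <- runif(1, 0.1, 0.99)
    depth <- sample(1:6, 1)
    p <- aggregate_profiles(cohort_state(size, prev),
                            test_characteristics(sens, spec), depth)
    oracle <- oracle_enumerate_profiles(size, prev, sens, spec, depth)
    oracle <- oracle[order(-oracle$n_positive), ]
    expect_equal(p$concerned, oracle$concerned, tolerance = 1e-9)
    expect_equal(p$sick, oracle$sick, tolerance = 1e-9)
    expect_equal(p$healthy, oracle$healthy, tolerance = 1e-9)
  }
})

test_that("ubd_trajectory traces the compounding posterior", {
  tst <- lmr_test()
  t0 <- ubd_trajectory(27 / 808, tst, 0, 4)
  expect_equal(round(t0$posterior[t0$n_tests == 4], 8), 0.72028812)
  t1 <- ubd_trajectory(27 / 808, tst, 1, 4)
  expect_equal(round(t1$posterior[t1$n_tests == 4], 8), 0.04607010)
  # Zero tests: the trajectory starts at the prior.
  expect_equal(ubd_trajectory(0.2, tst, 0, 0)$posterior, 0.2)
  # Monotone nondecreasing in total tests when LR+ > 1.
  tr <- ubd_trajectory(1e-4, tst, 2, 10)
  expect_true(all(diff(tr$posterior) >= 0))
  expect_error(ubd_trajectory(0.1, tst, 5, 4), "max_tests")
})

test_that("level_counts gives the depth-wise profile expectations", {
  lc <- level_counts(lmr_cohort(), lmr_test(), 5)
  tst <- lmr_test()
  allpos <- lc[lc$n_positive == lc$depth, ]
  # Closed-form invariant for the persistently positive pool.
  expect_equal(allpos$concerned,
               27 * tst$sensitivity^(1:5) + 781 * tst$p_false_positive^(1:5),
               tolerance = 1e-12)
  # The printed depth-wise counts (nearest-integer rendering).
  expect_equal(allpos$count_nearest, c(282, 109, 52, 32, 25))
  d5 <- lc[lc$depth == 5 & lc$n_positive == 4, ]
  expect_equal(d5$count_nearest, 35)
  expect_equal(d5$count_floor, 34)

  # Disease-free cohort: all-positive count is size * (1-spec)^d.
  lc0 <- level_counts(cohort_state(1000, 0), test_characteristics(0.8, 0.9), 3)
  ap0 <- lc0[lc0$n_positive == lc0$depth, ]
  expect_equal(ap0$concerned, 1000 * 0.1^(1:3))
  expect_equal(ap0$sick, rep(0, 3))
})
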