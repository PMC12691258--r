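#' Expand the full recursive cohort tree
#'
#' Recursively applies [bayes_split()] to a root cohort: each node's positive
#' child inherits `(n_pos, prevalence_pos)` and its negative child
#' `(n_neg, prevalence_neg)`, down to the requested depth. Branches whose
#' expected size falls below `prune_below` are pruned (an empty branch has no
#' defined prevalence and nothing below it).
#'
#' @param root A [cohort_state()] (typically with an empty profile label).
#' @param test A [test_characteristics()].
#' @param depth Number of test rounds (tree depth), `>= 0`.
#' @param max_depth Refusal threshold: the tree has `2^depth` leaves, so
#'   depths beyond this are rejected rather than silently attempted.
#' @param prune_below Expected-headcount threshold under which a branch is
#'   treated as empty.
#' @return An object of class `ubd_node`: a list with `state`
#'   ([cohort_state()]), `split` ([bayes_split()] result, `NULL` at leaves)
#'   and `children` (list with `positive` / `negative` nodes, `NULL` at
#'   leaves).
#' @seealso [ubd_leaves()] to flatten the tree, [aggregate_profiles()] for
#'   the order-invariant profile table.
#' @export
ubd_expand <- function(root, test, depth, max_depth = 12, prune_below = 1e-12) {
  stopifnot(inherits(root, "cohort_state"), inherits(test, "test_characteristics"))
  depth <- assert_count(depth, "depth")
  if (depth > max_depth)
    stop(sprintf("depth %d exceeds the configured maximum %d (tree grows as 2^depth)",
                 depth, max_depth), call. = FALSE)
  expand_node(root, test, depth, prune_below)
}

expand_node <- function(state, test, depth, prune_below) {
  node <- structure(list(state = state, split = NULL, children = NULL),
                    class = "ubd_node")
  if (depth == 0L || state$size < prune_below) return(node)
  node$split <- bayes_split(state, test)
  mk_child <- function(size, prev, tag) {
    if (size < prune_below) return(NULL)
    expand_node(cohort_state(size, prev, paste0(state$profile, tag)),
                test, depth - 1L, prune_below)
  }
  node$children <- list(
    positive = mk_child(node$split$n_pos, node$split$prevalence_pos %||% 0, "+"),
    negative = mk_child(node$split$n_neg, node$split$prevalence_neg %||% 0, "-")
  )
  node
}

#' @export
print.ubd_node <- function(x, ...) {
  n_leaves <- nrow(ubd_leaves(x))
  cat(sprintf("Recursive cohort tree: root size %.4f, prevalence %s, %d leaves\n",
              x$state$size, format_pct(x$state$prevalence), n_leaves))
  invisible(x)
}

#' Flatten a cohort tree to its leaves
#'
#' @param node A `ubd_node` from [ubd_expand()].
#' @return A data frame with one row per (non-pruned) leaf: `profile`,
#'   `size`, `prevalence`, `sick` (= size x prevalence).
#' @export
ubd_leaves <- function(node) {
  stopifnot(inherits(node, "ubd_node"))
  acc <- list()
  walk <- function(n) {
    kids <- Filter(Negate(is.null), n$children %||% list())
    if (length(kids) == 0L) {
      acc[[length(acc) + 1L]] <<- data.frame(
        profile = n$state$profile, size = n$state$size,
        prevalence = n$state$prevalence,
        sick = n$state$size * n$state$prevalence,
        stringsAsFactors = FALSE)
    } else {
      for (k in kids) walk(k)
    }
  }
  walk(node)
  do.call(rbind, acc)
}

profile_label <- function(n_positive, n_tests) {
  paste0(strrep("+", n_positive), strrep("-", n_tests - n_positive))
}

#' Aggregate the tree by outcome profile
#'
#' Because the posterior update is order-invariant, all `choose(n, k)`
#' orderings with `k` positives out of `n` tests share one posterior, and
#' their expected headcounts can be pooled. This function computes the
#' aggregated table both ways -- by summing the tree leaves over orderings
#' and by the closed form
#' `sick(k) = n_sick_root * C(n,k) * se^k * (1-se)^(n-k)`,
#' `healthy(k) = n_healthy_root * C(n,k) * (1-sp)^k * sp^(n-k)` --
#' and verifies that the two agree to `check_tol` before returning.
#'
#' @inheritParams ubd_expand
#' @param depth Number of test rounds, `>= 1`.
#' @param check_tol Relative tolerance for the tree vs closed-form
#'   cross-check.
#' @return A data frame of class `ubd_profiles` with one row per number of
#'   positives (most positives first): `n_tests`, `n_positive`, `label`,
#'   `multiplicity` (binomial coefficient), `concerned` (expected headcount
#'   over all orderings), `sick`, `healthy`, `posterior`. The root state and
#'   test are attached as attributes `root` and `test`.
#' @examples
#' metro <- cohort_state(100000, 19.6 / 100000)
#' fit <- test_characteristics(0.73, 0.94)
#' aggregate_profiles(metro, fit, depth = 4)
#' @export
aggregate_profiles <- function(root, test, depth, max_depth = 12,
                               check_tol = 1e-9) {
  depth <- assert_count(depth, "depth", min = 1L)
  stopifnot(inherits(root, "cohort_state"), inherits(test, "test_characteristics"))
  if (depth > max_depth)
    stop(sprintf("depth %d exceeds the configured maximum %d (tree grows as 2^depth)",
                 depth, max_depth), call. = FALSE)

  k <- depth:0
  n_sick_root    <- root$size * root$prevalence
  n_healthy_root <- root$size - n_sick_root
  sick    <- n_sick_root * choose(depth, k) *
    test$sensitivity^k * test$p_false_negative^(depth - k)
  healthy <- n_healthy_root * choose(depth, k) *
    test$p_false_positive^k * test$specificity^(depth - k)
  concerned <- sick + healthy
  posterior <- ifelse(concerned > 0, sick / concerned, NA_real_)

  # Independent route: sum the actual recursion's leaves over orderings.
  leaves <- ubd_leaves(ubd_expand(root, test, depth, max_depth = max_depth))
  kl <- nchar(gsub("-", "", leaves$profile))
  tree_concerned <- vapply(k, function(i) sum(leaves$size[kl == i]), numeric(1))
  tree_sick      <- vapply(k, function(i) sum(leaves$sick[kl == i]), numeric(1))
  rel <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)
  bad <- (concerned > 0 & rel(concerned, tree_concerned) > check_tol) |
         (sick > 0 & rel(sick, tree_sick) > check_tol)
  if (any(bad))
    stop("internal inconsistency: tree aggregation and closed form disagree",
         call. = FALSE)

  out <- data.frame(
    n_tests = depth, n_positive = k,
    label = vapply(k, profile_label, character(1), n_tests = depth),
    multiplicity = choose(depth, k),
    concerned = concerned, sick = sick, healthy = healthy,
    posterior = posterior, stringsAsFactors = FALSE)
  attr(out, "root") <- root
  attr(out, "test") <- test
  class(out) <- c("ubd_profiles", "data.frame")
  out
}

#' Posterior trajectory over an increasing number of tests
#'
#' For a fixed number of negative results, traces the posterior as the total
#' number of tests grows (each additional test being positive): the family
#' of sigmoid curves showing how evidence compounds.
#'
#' @param root_prevalence Prior probability of disease.
#' @param test A [test_characteristics()].
#' @param n_negatives Fixed number of negative results in each profile.
#' @param max_tests Largest total test count; `>= n_negatives`.
#' @return A data frame with columns `n_tests`, `n_positive`, `n_negative`,
#'   `posterior`, one row per total test count from `n_negatives` to
#'   `max_tests`.
#' @export
ubd_trajectory <- function(root_prevalence, test, n_negatives, max_tests) {
  assert_prob(root_prevalence, "root_prevalence")
  n_negatives <- assert_count(n_negatives, "n_negatives")
  max_tests <- assert_count(max_tests, "max_tests")
  if (n_negatives > max_tests)
    stop("`n_negatives` must not exceed `max_tests`", call. = FALSE)
  t <- n_negatives:max_tests
  data.frame(
    n_tests = t, n_positive = t - n_negatives, n_negative = n_negatives,
    posterior = vapply(t - n_negatives, function(kp)
      posterior_after_profile(root_prevalence, test, kp, n_negatives),
      numeric(1)))
}

#' Depth-wise expected counts per outcome profile
#'
#' For every depth `d` from 1 to `max_depth`, the expected headcount of each
#' outcome profile (k positives of d tests), with floored and
#' nearest-integer renderings of the expectation. The all-positive count at
#' depth `d` is `n_sick_root * se^d + n_healthy_root * (1-sp)^d`: the curve
#' showing how the persistently-positive pool shrinks with more rounds.
#'
#' @inheritParams aggregate_profiles
#' @param max_depth Largest depth tabulated, `>= 1`.
#' @return A data frame with columns `depth`, `n_positive`, `label`,
#'   `multiplicity`, `concerned`, `sick`, `healthy`, `posterior`,
#'   `count_floor`, `count_nearest`.
#' @export
level_counts <- function(root, test, max_depth) {
  max_depth <- assert_count(max_depth, "max_depth", min = 1L)
  out <- do.call(rbind, lapply(seq_len(max_depth), function(d) {
    p <- aggregate_profiles(root, test, d, max_depth = max(12, max_depth))
    data.frame(depth = d, as.data.frame(p)[setdiff(names(p), "n_tests")],
               stringsAsFactors = FALSE)
  }))
  out$count_floor <- floor(out$concerned)
  out$count_nearest <- round_half_up(out$concerned, 0)
  out
}
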