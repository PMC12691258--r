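# Shared fixtures: the three worked cohorts and independent oracles.
# The asymptomatic Metropolitan-Region cohort (prevalence 19.6/100k) and the
# symptomatic low/moderate-risk (808, 27 sick) and high-risk (345, 16 sick)
# cohorts, with the FIT characteristics observed on each.

metro_test <- function() test_characteristics(0.73, 0.94)
metro_cohort <- function() cohort_state(100000, 19.6 / 100000)

lmr_test <- function() test_characteristics(26 / 27, 525 / 781)
lmr_cohort <- function() cohort_state(808, 27 / 808)
hr_cohort <- function() cohort_state(345, 16 / 345)

# Independent oracle 1: elementary single-step Bayes update applied
# sequentially along an explicit outcome sequence (logical vector, TRUE =
# positive). Shares no code path with posterior_after_profile (which uses
# the joint-likelihood closed form) nor with bayes_split (which works in
# expected headcounts).
oracle_sequential_posterior <- function(prior, sens, spec, outcomes) {
  p <- prior
  for (pos in outcomes) {
    p <- if (pos) {
      p * sens / (p * sens + (1 - p) * (1 - spec))
    } else {
      p * (1 - sens) / (p * (1 - sens) + (1 - p) * spec)
    }
  }
  p
}

# Independent oracle 2: brute-force enumeration of all 2^n outcome
# sequences. For each sequence, P(seq & sick) and P(seq & healthy) are
# accumulated from per-round products; profiles are grouped by the number
# of positives. Exponential, so only usable at small depth - which is the
# point.
oracle_enumerate_profiles <- function(size, prevalence, sens, spec, depth) {
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), depth))
  k <- 0:depth
  sick <- healthy <- numeric(depth + 1)
  for (i in seq_len(nrow(grid))) {
    seqv <- as.logical(grid[i, ])
    p_seq_sick <- prod(ifelse(seqv, sens, 1 - sens))
    p_seq_healthy <- prod(ifelse(seqv, 1 - spec, spec))
    idx <- sum(seqv) + 1L
    sick[idx] <- sick[idx] + prevalence * p_seq_sick
    healthy[idx] <- healthy[idx] + (1 - prevalence) * p_seq_healthy
  }
  data.frame(n_positive = k, sick = size * sick, healthy = size * healthy,
             concerned = size * (sick + healthy))
}

# All distinct outcome sequences of length n as a list of logical vectors.
all_sequences <- function(n) {
  if (n == 0L) return(list(logical(0)))
  grid <- expand.grid(rep(list(c(TRUE, FALSE)), n))
  lapply(seq_len(nrow(grid)), function(i) as.logical(grid[i, ]))
}
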