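---
title: "Updated Bayesian Deduction: model, conventions and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Updated Bayesian Deduction: model, conventions and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ubd)
```

## The problem and the model

A cheap, imperfect diagnostic test (the motivating case is the faecal
immunochemical test, FIT, for colorectal cancer) cannot by itself decide who
needs a scarce confirmatory procedure (a colonoscopy). Updated Bayesian
Deduction (UBD) turns the weakness of one test into a stratification engine:
apply the test to a cohort, split the cohort by outcome, assign each
subcohort its Bayes-updated disease prevalence, and recurse. After $n$
rounds the cohort is partitioned into expected-count subcohorts whose
posteriors span several orders of magnitude, so the handful of
persistently-positive profiles can be prioritised and almost everyone else
safely deferred.

The machinery is elementary Bayes. Writing $se$ for sensitivity
$P(+\mid s)$, $sp$ for specificity $P(-\mid h)$ and $p$ for prevalence, one
round splits a cohort of expected size $N$ into

$$n_{pos} = N\,[p\,se + (1-p)(1-sp)], \qquad
  P(s \mid +) = \frac{p\,se}{p\,se + (1-p)(1-sp)},$$

and symmetrically for the negative branch. Because every test round
multiplies the prior odds by a likelihood ratio
($LR^+ = se/(1-sp)$, $LR^- = (1-se)/sp$), the posterior after $k$ positives
and $j$ negatives is order-invariant:

$$P(s \mid k_+, j_-) =
  \frac{p\,se^{k}(1-se)^{j}}{p\,se^{k}(1-se)^{j} + (1-p)(1-sp)^{k}sp^{j}}.$$

All $\binom{n}{k}$ orderings with $k$ positives therefore share one
posterior, and the full $2^n$-leaf recursion tree collapses to $n+1$
aggregated outcome profiles with binomial multiplicities. `ubd` computes
the aggregation both ways — by summing the actual recursion's leaves and by
the closed form — and refuses to return if the two disagree beyond a
relative $10^{-9}$.

### Assumptions

* **Conditional independence.** Repeated rounds are independent given
  disease status. For FITs this is argued from intermittent polyp bleeding;
  the package offers no between-round dependence model, deliberately — a
  dependence knob without validated parameters would only imply precision
  that does not exist.
* **Constant test characteristics.** $se$ and $sp$ do not drift across
  rounds. They are cohort-dependent in reality (specificity drops in
  symptomatic cohorts), which is why calibration is a first-class module
  rather than a constant.
* **Deductive expectation semantics.** All headcounts are real-valued
  expectations ("6.86 people"), not sampled patients. Nothing is rounded
  inside the computation; integers appear only at the display/decision
  boundary.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `depth` | 4 | test rounds | the working optimum for FIT-like tests: at depth 3 the persistently-positive pool is still inflated by false positives, at depth 5 false negatives start losing true cases (the worked cohort drops from 27 known cases to an expected 25.3 all-positive) |
| `urgent_threshold` | 0.04 | posterior probability | captures exactly the all-positive and one-negative depth-4 profiles in all three worked cohorts (posteriors 81%/9.2%, 72%/4.6%, 78%/6.4%) while excluding every lower profile |
| `elevated_multiplier` | 10 | fold over reference prevalence | marks the "retest or schedule" tier (e.g. the two-positive metro profile at 12× the population prevalence) |
| `fit_unit_cost`, `colonoscopy_unit_cost` | 5, 500 | currency | the worked price points; pure linear cost model |
| `prune_below` | 1e-12 | expected headcount | branches smaller than this are empty; their prevalence is undefined and nothing is expanded below them |

Prevalence is carried internally as a probability at full double precision.
Percent and per-100,000 are I/O conveniences with explicit unit tags, never
inferred from magnitude: compounding posteriors punishes premature rounding
severely (a 2-decimal prevalence at round 1 is a different cohort by
round 4).

## Display and integerisation conventions

Three conventions are implemented explicitly because the source tables mix
them, and each is reproduced by a named field rather than a silent choice:

* **Per-row display**: counts at 2 decimals, half-up; posteriors as
  percentages at 6 decimals, widening to 9 decimals below 0.001% (where 6
  would show nothing).
* **Fractional urgent count**: the sum of the *displayed* (half-up 2-dp)
  urgent rows — the convention behind the headline "6.86 + 89.43 = 96.29".
  The exact sum (96.2966) is reported alongside.
* **Integer headcounts**: per-row flooring is canonical (it reproduces the
  low/moderate-risk headline 32 + 77 = 109 urgent, 86.5% reduction);
  per-row nearest-integer is also emitted because the depth-wise positive
  counts (282, 109, 52, 32, 25, 35) and the high-risk urgent count
  (18 + 33 = 51, 85.2% reduction) are nearest-integer renderings. The
  source material itself floors 77.53 but rounds 50.83 up; a package has to
  pick, so it ships both and names the canonical one.

Rendering is a pure presentation layer: no displayed value ever feeds back
into computation.

## Numerical choices and degenerate inputs

* The posterior uses the joint-likelihood form rather than odds ×
  likelihood-ratio products. The two are algebraically identical in the
  interior, but the joint form stays defined for perfect tests
  ($sp = 1$ makes $LR^+$ undefined while the posterior is plainly 1) and
  avoids odds overflow near prior 1. An error is raised only when a profile
  has probability zero under both hypotheses — a genuinely empty branch.
* Zero denominators everywhere else (empty branches, undefined PPV) yield
  explicit `NA` markers, never silent `NaN` propagation; subtrees below an
  empty branch are pruned.
* Tree depth is refused above 12 by default ($2^{depth}$ growth); the
  aggregated closed form is linear in depth and is what the reporting path
  uses.
* Currency is plain double arithmetic rounded to cents; inputs are
  integer-valued in practice, so totals are exact at these magnitudes.
* Calibration works on integer-ratio doubles (exact to 1 ulp for counts of
  this size); the round-trip invariant (confusion table → priors → expected
  counts → the same table) is tested to $10^{-9}$ and the split-derived
  predictive values match the ratio-derived ones to $10^{-12}$.

## Rate conventions in indicator calibration

A stratified risk indicator ("aged 65–75") can be read as a test, but two
rate conventions then collide. The healthy fraction *among
indicator-positives* (340/400 = 85% in the worked age example) is
$1 - PPV$, **not** $1 - sp$; the latter is 340/900 ≈ 37.8%. Feeding a
complement-PPV into the recursion as a false-positive *rate* is a subtle
semantic bug the prose of screening studies invites. `indicator_rates()`
therefore returns both conventions under explicit names
(`complement_ppv` vs `one_minus_specificity`) and endorses neither as
recursion input; callers must choose by field name.

## What the Monte-Carlo generator emulates — and what it does not

`simulate_cohort()` draws patient-level data under exactly the analytic
model: Bernoulli disease status, then conditionally independent rounds
(Bernoulli $se$ for the sick, $1-sp$ for the healthy), in a fixed draw
order under one seeded generator. It is the stochastic oracle for the
deterministic expectations: profile counts must sit within binomial
sampling noise of the aggregation table (the suite asserts 4 binomial
standard deviations at $10^5$ patients, and shrinking total-variation
distance at $10^4$–$10^6$).

It does **not** emulate the ways real screening data deviate from the
model: correlated rounds from persistent non-bleeding, drifting test
characteristics across rounds or cohorts, imperfect gold-standard
verification, or compliance loss between rounds. A green Monte-Carlo test
therefore establishes internal consistency of the machinery under the
independence assumption — it is no evidence that four real FITs on real
patients behave this way.

## Design decisions that were genuinely open

* **Per-depth test schedules.** The recursion's error rates are constant by
  default but the recursion point where they *could* change is real
  (different tests per round). No update model ships because none is
  specified anywhere authoritative; `bayes_split()` composes freely with
  per-round `test_characteristics`, which is the extension hook.
* **Reference prevalence for the elevated tier** defaults to the root
  cohort's own prevalence rather than a fixed population figure, so tier
  semantics survive rescaling and transfer across cohorts.
* **JSON-only configuration.** YAML was dropped: no YAML parser is part of
  the supported dependency set, and a hand-rolled one would be worse than
  none.
* **The "98.99%" headline.** The worked material quotes a 98.99% (or
  99.9%) colonoscopy-replacement figure whose 98.99% variant does not
  follow from any clean arithmetic path; only the 99.9% reduction
  (96 urgent of 100,000) is computed and asserted here.

## Known limitations

* Expected-count arithmetic says nothing about variance: with 19.6 expected
  cases per 100,000, realised counts fluctuate ±4 and so do all downstream
  integer headlines. The package deliberately reports no confidence
  intervals (the deductive framing declines them), so treat integer
  headcounts as expectations, not forecasts.
* Tier thresholds are calibrated to reproduce the worked prioritisations,
  not derived from a loss function; they are knobs, and clinical or ethical
  decision policy is explicitly out of scope.
* Sensitivity/specificity enter as point values; their sampling uncertainty
  from the calibration study is not propagated.
* The depth-4 optimum is an empirical argument about FIT-like error rates,
  not a theorem; for other tests, sweep `depth` and look at the posterior
  trajectories (`ubd_trajectory()`) before trusting it.
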