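---
title: "Designing factorial and multi-arm (multi-stage) trials of two treatments and their combination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing factorial and multi-arm (multi-stage) trials of two treatments and their combination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(factmams)
```

## The design problem

When two treatments A and B and their combination AB are candidates against a
common control, a trial can be organised in two fundamentally different ways:

* a **2x2 factorial design**, which assumes the combination effect is the sum
  of the single-treatment effects (no interaction) and therefore lets the
  combination arm contribute information to the single-treatment comparisons;
* a **multi-arm design** (single-stage, or two-stage with interim stopping),
  which treats the three active arms as unrelated and compares each with
  control on its own data — a Dunnett-type analysis.

`factmams` computes the operating characteristics of both families under a
normally distributed endpoint `Y_j ~ N(mu_j, sigma^2)` with *known* common
standard deviation, one-sided hypotheses `H0j: mu_j <= mu_0` for
`j = A, B, AB`, and familywise error control: a single critical value `k`
(or boundary pair) chosen so that the probability of rejecting any true null
is `alpha`.

Group sizes are parameterised by the control size `n0` and two allocation
ratios: `r` for each single-treatment arm and `q` for the combination arm
(`nA = nB = r*n0`, `nAB = q*n0`).

## The joint law of the test statistics

The factorial single-treatment statistic pools the direct contrast
(`ybar_A - ybar_0`) with the indirect one through the combination arm
(`ybar_AB - ybar_B`), which is only valid under additivity; the combination
statistic uses the combination and control groups alone.  All three are
marginally N(0,1) under their nulls and jointly trivariate normal.
`factorial_covariance()` evaluates the closed-form correlation matrix `V`;
`factorial_mean()` the mean under an alternative.  Two structural facts drive
the design trade-offs, and are verified by the test suite:

* `corr(Z_A, Z_B) = 0` exactly when `q = r^2`, and along that curve
  `corr(Z_A, Z_AB) = sqrt(r/(1+r^2))`, maximised at `r = 1` with value
  `1/sqrt(2)`;
* `V` is positive semidefinite everywhere but **exactly singular on the line
  `q = 1`** (balanced design included), where `Z_AB` is a linear combination
  of `Z_A` and `Z_B`.

The singularity has a practical numerical consequence discussed below.  The
multi-arm analogue `ma_covariance()` is the familiar Dunnett structure
(`r/(1+r)` between single arms, `sqrt(rq)/sqrt((1+r)(1+q))` to the
combination arm) and is positive definite for all ratios.

```{r joint-law}
factorial_covariance(allocation_ratios(1, 1))
ma_covariance(allocation_ratios(1, 1))
```

## Critical values, power, sample size

`critical_value()` solves `P(Z_A <= k, Z_B <= k, Z_AB <= k) = 1 - alpha`
under the null law by bracketed root finding between the single-test bound
`qnorm(1-alpha)` and the Bonferroni bound `qnorm(1-alpha/3)`.  Power is
always **disjunctive**: the probability of rejecting at least one
hypothesis under the specified alternative.  Per-hypothesis rejection
probabilities are available through the simulator, which uses the same
familywise-calibrated `k` for every comparison (not per-test alpha levels).

```{r critical-values}
factorial_critical_value(allocation_ratios(1, 1), alpha = 0.05)
ma_critical_value(allocation_ratios(1, 1), alpha = 0.05)  # Dunnett, known sigma
```

`factorial_sample_size()` / `ma_sample_size()` solve `power(n0) = target` on
continuous `n0` by root finding and then take the smallest integer `n0` whose
power reaches the target; the reported trial size is
`round(n0 * (1 + 2r + q))`.  This convention reproduces every balanced
tabulated total as `4 * n0`, and the tabulated non-balanced minima to within
a patient or two — the sources do not state whether group sizes or totals
were rounded, which is why the package commits to one explicit rule.

```{r sample-size}
sc <- scenario_suite("iii", delta = 0.5, delta0 = 0.1, sigma = 1)
factorial_sample_size(allocation_ratios(1, 1), sc, alpha = 0.05, power = 0.9)
```

Five named alternatives ([scenario_suite()]) cover the standard comparisons:
the global null "0"; the least favourable configurations "i" (one strong
single treatment, antagonistic combination) and "ii" (strong combination
only); and the additivity-consistent "iii" and "iv".

### Numerical choices

The trivariate orthant probabilities are computed by seeded quasi-Monte-Carlo
integration (Genz–Bretz, absolute tolerance `1e-7`, a fixed internal seed
with the caller's RNG state restored).  A deterministic quadrature rule
(Miwa) was rejected because it requires a non-singular correlation matrix,
and the factorial law is singular on `q = 1` — precisely the balanced
designs of most practical interest.  The seeded quasi-random rule makes
critical values reproducible to well past the third decimal; root finding
uses tolerance `1e-6` on `k` and the sample-size search refines the
continuous solution to the exact minimal integer.

The allocation-ratio surface of the critical value is extremely flat near
its minimum (variations below `1e-3` across neighbouring grid points), so
different software at three-decimal precision can disagree about the exact
argmin while agreeing about every critical value; `optimize_allocation()`
therefore returns the full evaluated grid along with the minimiser, with a
deterministic first-in-row-major tie-break.

## Two-stage MAMS design

The two-stage design (three active arms, equal allocation `r = q = 1`,
interim at half the maximum sample size) tests each arm against control at
an interim analysis with efficacy bound `u1` and futility bound `l1 = 0`,
and at a final analysis with bound `u2 = l2`.  Crossing `u1` stops the whole
trial with rejection (efficacy takes precedence over futility if different
arms cross different bounds); arms below `l1` are dropped, and stage-2
statistics are cumulative over all data from the surviving arms and control.

`mams_fwer()` evaluates the familywise error as a double integral obtained
by conditioning on the two standardised control increments, under which the
three arms are conditionally independent (whence a cubed term).  The
bivariate normal kernel carries the between-stage correlation `1/sqrt(2)` of
two equally sized stages; it is computed by a vectorised
Drezner–Wesolowsky reduction (24-point Gauss–Legendre, ~1e-14 accurate at
this correlation, cross-checked against mvtnorm in the tests) because the
80-point tensor Gauss–Hermite outer quadrature needs thousands of kernel
evaluations per error evaluation.  `obf_boundaries()` then solves for the
O'Brien–Fleming constant (`u1 = u2*sqrt(2)`), achieving the target
familywise error to within `1e-4`; the calibration is cross-validated by
simulation in the test suite.

### What "power" means here

`mams_power()` computes the least-favourable-configuration power
`P(recommend AB | mu_AB - mu_0 = Delta, mu_A - mu_0 = mu_B - mu_0 = delta0)`,
where *recommend* means the combination arm crosses its efficacy bound **and
is the best arm at that stage** (at the interim: the largest statistic; at
the final stage: the largest among surviving arms that cross).  This is the
multi-stage Dunnett notion of correctly selecting the interesting treatment.
It is deliberately stricter than "reject `H0AB` somehow": the two
definitions differ by under a percentage point at the design's operating
point, but they can disagree about the minimal group size (here they give 38
versus 37 per arm per stage), and the selection-based definition is the one
consistent with the published two-stage design this package reproduces.  The
simulator reports both events (`AB` and `AB_selected` rows) so the
distinction is visible empirically.

With degenerate boundaries (`u1` huge, `l1` very negative) the two-stage
design collapses to a single-stage Dunnett analysis of the cumulative data,
and `mams_power()` converges to the single-stage selection power — a
reduction the tests check against an independent Monte-Carlo oracle.

`expected_sample_size()` estimates the mean realised trial size under the
stopping rules by seeded simulation: a trial commits `4n` patients at stage
1 and `(1 + m) n` more if it continues with `m` surviving arms.

```{r mams, eval = FALSE}
b <- obf_boundaries(0.05)                     # u1 = 2.932, u2 = 2.073
mams_sample_size(0.05, 0.9, delta = 28, delta0 = 7, sigma = 50,
                 boundaries = b)              # 38 per arm per stage
```

## The patient-level simulator

`simulate_groups()` draws independent normal responses under the full
interaction model `Y = beta0 + beta1*I_A + beta2*I_B + beta3*I_A*I_B + eps`:
`beta3 < 0` is antagonism, `beta3 > 0` synergy, `beta3 = 0` the additivity
the factorial analysis assumes.  `empirical_rejection()` simulates whole
trials (group means are computed from patient-level draws) and reports
per-hypothesis and global rejection frequencies with Monte-Carlo standard
errors; seeds are mandatory and recorded in every output.  Replicates are
drawn from a single seeded Mersenne-Twister stream with vectorised sampling
— replicates are iid, so this is distributionally identical to per-replicate
substreams and considerably faster.

What the generator emulates — and what it does not: independent,
homoscedastic, exactly normal responses with a known sigma and no dropout.
Real trials estimate sigma (t- rather than z-statistics), adjust for
covariates, and lose patients to attrition; passing tests here validate the
design arithmetic, not robustness to those departures.

The simulator is the package's own adversarial check: the test suite uses
it to confirm that the factorial design's single-arm type-I error inflates
monotonically with synergistic interaction (information borrowed from the
combination arm is spurious when `beta3 > 0`), while the multi-arm
statistics — which never touch the combination arm for the single-arm
tests — hold their level for any `beta3`.

## Head-to-head comparison

`compare_designs()` sizes all three designs once for a common
`(Delta, delta0, sigma, alpha, power)` — the factorial under the additive
scenario "iii", the multi-arm under the combination LFC "ii", the MAMS
design by its LFC power — and evaluates every preset alternative under all
three, analytically where a closed law exists and by seeded simulation for
the MAMS design.  `beta3_sweep()` traces global power and (for MAMS)
expected sample size across an interaction grid.  The sizing conventions are
a package choice: the sources compare designs of nominally equal power but
do not fully specify how each one was sized under which alternative, so the
conventions are fixed here and recorded in every output's configuration.

Problem sizes used throughout the shipped tests are deliberately desk-scale:
`1e4` simulated trials for operating characteristics (binomial standard
error about 0.002 at the 5% level), `2e4` replicates for unbiasedness
checks, and grids of a few dozen allocation points; each tolerance in the
tests is stated in Monte-Carlo standard errors, not tuned numbers.

## Known limitations

* Known sigma only; no t-distributed analogues.
* Two stages, equal stage sizes, O'Brien–Fleming shape and `l1 = 0` only;
  no Pocock or triangular boundaries, no >2-stage designs.
* No covariate adjustment, non-normal endpoints, or attrition modelling.
* The factorial analysis is only as good as the additivity assumption; the
  whole point of the simulator is to quantify how quickly it degrades.
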