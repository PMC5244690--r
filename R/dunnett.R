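# Single-stage multi-arm design: three active arms against a shared
# control, analysed with a Dunnett test (known sigma, one-sided).

#' Critical value of the single-stage multi-arm design
#'
#' The familywise-error-controlling common critical value for the three
#' many-to-one comparisons, i.e. the one-sided Dunnett critical value with
#' known variance, solved from the trivariate normal law with correlation
#' [ma_covariance()].
#'
#' @inheritParams factorial_critical_value
#' @return The critical value `k`; always between `qnorm(1-alpha)` and the
#'   Bonferroni value `qnorm(1-alpha/3)`.
#' @examples
#' \donttest{
#' ma_critical_value(allocation_ratios(1, 1), 0.05)  # ~2.062
#' }
#' @export
ma_critical_value <- function(alloc, alpha = 0.05) {
  critical_value(ma_covariance(alloc), alpha)
}

#' Disjunctive power of the multi-arm design
#'
#' Probability of rejecting at least one of the three null hypotheses under
#' the alternative law `MVN(ma_mean, ma_covariance)`.  Because each
#' statistic uses only its own arm and the control, the power at fixed
#' group means is unaffected by how the combination mean decomposes into
#' main effects and interaction.
#'
#' @inheritParams factorial_power
#' @return The disjunctive power.
#' @export
ma_power <- function(alloc, n0, scen, alpha = 0.05, crit = NULL) {
  alloc <- as_alloc(alloc)
  if (is.null(crit)) crit <- ma_critical_value(alloc, alpha)
  law <- joint_law(ma_mean(alloc, n0, scen), ma_covariance(alloc))
  rejection_prob(law, crit)
}

#' Sample size of the multi-arm design
#'
#' Same search as [factorial_sample_size()] with the multi-arm law.
#'
#' @inheritParams factorial_sample_size
#' @return A `"sample_size_result"`.
#' @export
ma_sample_size <- function(alloc, scen, alpha = 0.05, power = 0.9) {
  alloc <- as_alloc(alloc)
  stopifnot(inherits(scen, "effect_scenario"))
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  mu <- scenario_means(scen)
  if (max(mu[c("muA", "muB", "muAB")]) <= mu[["mu0"]])
    stop("no treatment mean exceeds the control mean: the target power ",
         "cannot be reached at any sample size", call. = FALSE)
  crit <- ma_critical_value(alloc, alpha)
  pf <- function(n0) ma_power(alloc, n0, scen, alpha, crit = crit)
  sol <- solve_n0(pf, power)
  make_sample_size_result("multi-arm", alloc, scen, alpha, power, crit, sol, pf)
}
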