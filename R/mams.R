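# Two-stage multi-arm multi-stage (MAMS) design with three active arms,
# equal allocation across all arms and control, interim at half the
# maximum sample size.  The familywise error and least-favourable-
# configuration power are evaluated as two-dimensional integrals obtained
# by conditioning on the shared control observations; the bivariate normal
# kernel carries the between-stage correlation 1/sqrt(2) of two equally
# sized stages.

STAGE_RHO <- 1 / sqrt(2)

#' Stage boundaries of a two-stage design
#'
#' Upper (efficacy) and lower (futility) bounds per stage.  At the final
#' stage the two bounds coincide (`l2 = u2`); the default futility bound at
#' the interim is 0, and the O'Brien-Fleming shape ties the stages by
#' `u1 = u2 * sqrt(2)`.
#'
#' @param u1,u2 Efficacy bounds of stages 1 and 2.
#' @param l1 Futility bound of stage 1 (default 0); must not exceed `u1`.
#' @param l2 Futility bound of stage 2 (defaults to `u2`, and must equal it).
#' @return An object of class `"stage_boundaries"`.
#' @export
stage_boundaries <- function(u1, u2, l1 = 0, l2 = u2) {
  v <- c(u1, u2, l1, l2)
  if (any(!is.finite(v))) stop("boundaries must be finite", call. = FALSE)
  if (l1 > u1) stop("'l1' must not exceed 'u1'", call. = FALSE)
  if (abs(l2 - u2) > 1e-12)
    stop("the final-stage bounds must coincide (l2 = u2)", call. = FALSE)
  structure(list(u1 = u1, u2 = u2, l1 = l1, l2 = l2),
            class = "stage_boundaries")
}

#' @export
print.stage_boundaries <- function(x, ...) {
  cat(sprintf("Two-stage boundaries: u1 = %.3f, u2 = %.3f, l1 = %.3f, l2 = %.3f\n",
              x$u1, x$u2, x$l1, x$l2))
  if (!is.null(attr(x, "alpha")))
    cat(sprintf("  calibrated for one-sided FWER alpha = %g (achieved %.6f)\n",
                attr(x, "alpha"), attr(x, "fwer")))
  invisible(x)
}

#' Familywise error rate of a two-stage three-arm design
#'
#' Evaluates, under the global null, the probability that any of the three
#' arm-versus-control statistics crosses its efficacy bound at either
#' stage:
#' \deqn{\alpha = 1 - \int\!\!\int \Big[\Phi(\sqrt2\,l_1+t_1)
#'   + \Phi_2(\sqrt2\,u_1+t_1,\ \sqrt2\,u_2+(t_1+t_2)/\sqrt2;\ 1/\sqrt2)
#'   - \Phi_2(\sqrt2\,l_1+t_1,\ \cdot\ ;\ 1/\sqrt2)\Big]^3
#'   d\Phi(t_1)\,d\Phi(t_2),}
#' where the two integration variables are the standardised control
#' increments of the two stages (given the control, the three arms are
#' independent, whence the cube).  The outer integrals use 80-point
#' Gauss-Hermite quadrature (absolute error well below 1e-6 for these
#' smooth integrands).
#'
#' @param boundaries A [stage_boundaries()] object.
#' @return The familywise error rate.
#' @export
mams_fwer <- function(boundaries) {
  stopifnot(inherits(boundaries, "stage_boundaries"))
  u1 <- boundaries$u1; u2 <- boundaries$u2; l1 <- boundaries$l1
  gh <- gauss_hermite_prob(80L)
  idx <- expand.grid(i = seq_along(gh$x), j = seq_along(gh$x))
  t1 <- gh$x[idx$i]; t2 <- gh$x[idx$j]
  w <- gh$w[idx$i] * gh$w[idx$j]
  v <- sqrt(2) * u2 + (t1 + t2) / sqrt(2)
  p1 <- stats::pnorm(sqrt(2) * l1 + t1) +
    pbvn(sqrt(2) * u1 + t1, v, STAGE_RHO) -
    pbvn(sqrt(2) * l1 + t1, v, STAGE_RHO)
  1 - sum(w * p1^3)
}

#' O'Brien-Fleming boundaries of the two-stage design
#'
#' Solves the two-stage familywise-error equation for the O'Brien-Fleming
#' constant with `l1 = 0`, `l2 = u2` and `u1 = u2 * sqrt(2)` (stringent
#' early, relaxing toward the final analysis), so that the familywise
#' error under the global null equals `alpha`.
#'
#' @param alpha One-sided familywise error rate in (0, 1).
#' @param l1 Interim futility bound (default 0).
#' @return A calibrated [stage_boundaries()] object with attributes
#'   `alpha` and `fwer` (the achieved error, within 1e-4 of `alpha`).
#' @examples
#' \donttest{
#' obf_boundaries(0.05)  # u1 = 2.932, u2 = 2.073
#' }
#' @export
obf_boundaries <- function(alpha = 0.05, l1 = 0) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  f <- function(u2) mams_fwer(stage_boundaries(sqrt(2) * u2, u2, l1)) - alpha
  lo <- stats::qnorm(1 - alpha)
  hi <- stats::qnorm(1 - alpha / 6) + 1
  u2 <- tryCatch(stats::uniroot(f, c(lo, hi), tol = 1e-7)$root,
                 error = function(e)
                   stop("boundary calibration failed to converge: ",
                        conditionMessage(e), call. = FALSE))
  b <- stage_boundaries(sqrt(2) * u2, u2, l1)
  achieved <- mams_fwer(b)
  if (abs(achieved - alpha) > 1e-4)
    stop(sprintf("calibrated FWER %.6f differs from alpha %.6f by more than 1e-4",
                 achieved, alpha), call. = FALSE)
  attr(b, "alpha") <- alpha
  attr(b, "fwer") <- achieved
  b
}

#' Least-favourable-configuration power of the two-stage design
#'
#' Probability, under the least favourable configuration
#' `muAB - mu0 = Delta`, `muA - mu0 = muB - mu0 = delta0`, that the
#' combination arm crosses its efficacy bound *and is the best arm at that
#' stage* (the multi-stage Dunnett notion of recommending the combination
#' treatment).  With stage-1 statistic `Z1` and cumulative stage-2
#' statistic `Z2` for each arm:
#' stage 1 contributes `P(Z1_AB > u1, Z1_A < Z1_AB, Z1_B < Z1_AB)`;
#' stage 2 contributes the probability that no arm crossed `u1`, the
#' combination survived the futility bound, `Z2_AB > u2`, and each other
#' arm was either dropped at the interim or finished below `Z2_AB`.
#' Both terms reduce to one- and two-dimensional integrals by conditioning
#' on the combination arm's statistics and the control increments; the
#' bivariate kernels carry correlation `1/sqrt(2)`.
#'
#' @param n Patients per arm per stage (control included; equal allocation).
#' @param delta Interesting effect size (response units).
#' @param delta0 Uninteresting effect size (response units).
#' @param sigma Common standard deviation (> 0).
#' @param boundaries Calibrated [stage_boundaries()].
#' @return The power.
#' @examples
#' \donttest{
#' b <- obf_boundaries(0.05)
#' mams_power(38, delta = 28, delta0 = 7, sigma = 50, boundaries = b)  # >= 0.9
#' }
#' @export
mams_power <- function(n, delta, delta0, sigma, boundaries) {
  stopifnot(inherits(boundaries, "stage_boundaries"))
  if (!is.numeric(n) || length(n) != 1L || n <= 0)
    stop("'n' must be a single positive number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  u1 <- boundaries$u1; u2 <- boundaries$u2; l1 <- boundaries$l1
  aD <- sqrt(n) * delta / sigma    # cumulative-scale effect of AB
  ad <- sqrt(n) * delta0 / sigma   # cumulative-scale effect of A, B
  gh <- gauss_hermite_prob(80L)

  # stage 1: condition on the combination arm's standardised stage-1 mean
  p1 <- sum(gh$w * stats::pnorm(gh$x - sqrt(2) * u1 + aD) *
              stats::pnorm(gh$x + aD - ad)^2)

  # stage 2: t1 = combination arm's standardised cumulative statistic
  # (xi_AB1 + xi_AB2)/sqrt(2); t2 = control's standardised stage-1 mean.
  idx <- expand.grid(i = seq_along(gh$x), j = seq_along(gh$x))
  t1 <- gh$x[idx$i]; t2 <- gh$x[idx$j]
  w <- gh$w[idx$i] * gh$w[idx$j]
  cmp <- t1 + sqrt(2) * (aD - ad)  # "finish below the combination" bound
  other <- stats::pnorm(sqrt(2) * l1 + t2 - ad) +
    pbvn(sqrt(2) * u1 + t2 - ad, cmp, STAGE_RHO) -
    pbvn(sqrt(2) * l1 + t2 - ad, cmp, STAGE_RHO)
  inrange <- stats::pnorm(2 * u1 + sqrt(2) * t2 - sqrt(2) * aD - t1) -
    stats::pnorm(2 * l1 + sqrt(2) * t2 - sqrt(2) * aD - t1)
  cross2 <- stats::pnorm(sqrt(2) * t1 - t2 - 2 * u2 + 2 * aD)
  p2 <- sum(w * other^2 * inrange * cross2)

  p1 + p2
}

#' Fully specified two-stage MAMS design
#'
#' @param boundaries Calibrated [stage_boundaries()].
#' @param n_per_stage Patients per arm per stage (integer >= 1).
#' @param alpha,power_target Design criteria the boundaries and size were
#'   calibrated for.
#' @param delta,delta0,sigma Effect sizes and standard deviation.
#' @return An object of class `"mams_design"`.  Three active arms plus
#'   control, so the maximum trial size is `8 * n_per_stage` and the
#'   stage-1 commitment `4 * n_per_stage`.
#' @export
mams_design <- function(boundaries, n_per_stage, alpha, power_target,
                        delta, delta0, sigma) {
  stopifnot(inherits(boundaries, "stage_boundaries"))
  if (n_per_stage < 1 || n_per_stage != round(n_per_stage))
    stop("'n_per_stage' must be a positive integer", call. = FALSE)
  structure(list(
    boundaries = boundaries,
    n_per_stage = as.integer(n_per_stage),
    n_cumulative = 2L * as.integer(n_per_stage),
    arms = 3L,
    max_total = 8L * as.integer(n_per_stage),
    alpha = alpha, power_target = power_target,
    delta = delta, delta0 = delta0, sigma = sigma,
    power = mams_power(n_per_stage, delta, delta0, sigma, boundaries)
  ), class = "mams_design")
}

#' @export
print.mams_design <- function(x, ...) {
  cat("Two-stage MAMS design, 3 active arms + control, equal allocation\n")
  print(x$boundaries)
  cat(sprintf("  n per arm per stage = %d (cumulative %d); maximum total = %d\n",
              x$n_per_stage, x$n_cumulative, x$max_total))
  cat(sprintf("  LFC power at Delta = %g, delta0 = %g, sigma = %g: %.4f (target %g)\n",
              x$delta, x$delta0, x$sigma, x$power, x$power_target))
  invisible(x)
}

#' Sample size of the two-stage MAMS design
#'
#' Smallest integer per-arm per-stage group size whose
#' least-favourable-configuration power reaches the target, with
#' O'Brien-Fleming boundaries calibrated at `alpha`.
#'
#' @param alpha One-sided familywise error rate.
#' @param power Target power in (0, 1).
#' @param delta,delta0,sigma Effect sizes and standard deviation.
#' @param boundaries Optional pre-calibrated boundaries.
#' @return A [mams_design()] object.
#' @examples
#' \donttest{
#' mams_sample_size(0.05, 0.9, delta = 28, delta0 = 7, sigma = 50)  # n = 38
#' }
#' @export
mams_sample_size <- function(alpha = 0.05, power = 0.9, delta, delta0, sigma,
                             boundaries = NULL) {
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  if (delta <= 0)
    stop("'delta' must be positive for the power target to be reachable",
         call. = FALSE)
  if (is.null(boundaries)) boundaries <- obf_boundaries(alpha)
  sol <- solve_n0(function(n) mams_power(n, delta, delta0, sigma, boundaries),
                  power)
  mams_design(boundaries, sol$n0, alpha, power, delta, delta0, sigma)
}

#' Expected sample size of a MAMS design by simulation
#'
#' Monte-Carlo mean of the realised trial size under the stopping rules:
#' stop everything at stage 1 if any statistic exceeds `u1` (efficacy takes
#' precedence); otherwise drop every arm below `l1`, stop if all are
#' dropped, and continue the survivors plus control to stage 2.  Each
#' continuing arm and the control enrol another `n_per_stage` patients.
#'
#' @param design A [mams_design()] object.
#' @param scen An [effect_scenario()] or [linear_model_effects()]: the true
#'   state of nature the expectation is taken under.
#' @param nsim Number of simulated trials (>= 1).
#' @param seed Integer seed (recorded in the output).
#' @return A list with `expected_n`, its Monte-Carlo standard error `se`,
#'   `max_total`, `nsim` and `seed`, of class `"expected_sample_size"`.
#' @export
expected_sample_size <- function(design, scen, nsim = 10000L, seed = 1L) {
  stopifnot(inherits(design, "mams_design"))
  scen <- as_effect_scenario(scen)
  if (nsim < 1) stop("'nsim' must be at least 1", call. = FALSE)
  n <- design$n_per_stage
  b <- design$boundaries
  mu <- scenario_means(scen); sigma <- scen$sigma
  with_preserved_seed({
    set.seed(as.integer(seed))
    m1 <- sim_stage_means(mu, n, sigma, nsim)
    z1 <- sweep(m1[, -1L, drop = FALSE], 1L, m1[, 1L]) * sqrt(n / 2) / sigma
    stop_eff <- z1[, 1L] > b$u1 | z1[, 2L] > b$u1 | z1[, 3L] > b$u1
    surv <- z1 >= b$l1
    n_surv <- rowSums(surv)
    continue <- !stop_eff & n_surv > 0L
    realised <- 4 * n + ifelse(continue, (1 + n_surv) * n, 0)
  })
  structure(list(expected_n = mean(realised),
                 se = stats::sd(realised) / sqrt(nsim),
                 max_total = design$max_total,
                 nsim = as.integer(nsim), seed = as.integer(seed)),
            class = "expected_sample_size")
}

#' @export
print.expected_sample_size <- function(x, ...) {
  cat(sprintf("Expected sample size: %.1f patients (MC se %.2f, %d simulations, seed %d); maximum %d\n",
              x$expected_n, x$se, x$nsim, x$seed, x$max_total))
  invisible(x)
}

# patient-level stage means: column j is the mean of n fresh responses of
# group j (order 0, A, B, AB) in each of nsim replicate trials
sim_stage_means <- function(mu, n, sigma, nsim) {
  res <- vapply(mu, function(m) {
    if (sigma == 0) return(rep(m, nsim))
    rowMeans(matrix(stats::rnorm(nsim * n, m, sigma), nrow = nsim))
  }, numeric(nsim))
  if (nsim == 1L) res <- matrix(res, nrow = 1L, dimnames = list(NULL, names(mu)))
  res
}
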