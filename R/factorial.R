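# 2x2 factorial design: statistics from data, power, sample size,
# allocation optimisation.

#' Factorial test statistics from group summaries
#'
#' Computes `(Z_A, Z_B, Z_AB)` from the per-group sample means.  The
#' single-treatment statistics pool the direct comparison with the indirect
#' one through the combination arm (valid under additivity); the combination
#' statistic uses only the combination and control groups:
#' \deqn{Z_A = \frac{\sqrt{n_0}\,[r(r+q)(\bar Y_A-\bar Y_0) +
#'   qr(1+r)(\bar Y_{AB}-\bar Y_B)]}
#'   {\sigma\sqrt{(1+r)(r+q)(r^2+2rq+r^2q)}}, \quad
#'   Z_{AB} = \frac{\bar Y_{AB}-\bar Y_0}
#'   {\sigma\sqrt{(n_0+n_{AB})/(n_0 n_{AB})}}.}
#' The ratios `r = n_A/n_0`, `q = n_AB/n_0` are taken from the realised
#' group sizes, so each statistic has variance exactly one; if `alloc` is
#' supplied the realised sizes must match the declared ratios to within
#' rounding to one patient.
#'
#' @param summary A [group_summary()] object with `n_A = n_B`.
#' @param alloc Optional declared [allocation_ratios()] to validate against.
#' @return Named numeric 3-vector `(A, B, AB)`.
#' @examples
#' gs <- group_summary(c(0, 0.5, 0.1, 0.6), c(40, 40, 40, 40), sigma = 1)
#' z_statistics(gs)  # (3.1623, 0.6325, 2.6833)
#' @export
z_statistics <- function(summary, alloc = NULL) {
  stopifnot(inherits(summary, "group_summary"))
  n <- summary$sizes
  if (n[["A"]] != n[["B"]])
    stop("the factorial statistics require n_A = n_B", call. = FALSE)
  r <- n[["A"]] / n[["0"]]
  q <- n[["AB"]] / n[["0"]]
  if (!is.null(alloc)) {
    alloc <- as_alloc(alloc)
    if (abs(n[["A"]] - alloc$r * n[["0"]]) > 1 ||
        abs(n[["AB"]] - alloc$q * n[["0"]]) > 1)
      stop("group sizes are inconsistent with the declared allocation ",
           "ratios beyond rounding", call. = FALSE)
  }
  y <- summary$means
  n0 <- n[["0"]]
  sigma <- summary$sigma
  den <- sigma * sqrt((1 + r) * (r + q) * (r^2 + 2 * r * q + r^2 * q))
  zA <- sqrt(n0) * (r * (r + q) * (y[["A"]] - y[["0"]]) +
                      q * r * (1 + r) * (y[["AB"]] - y[["B"]])) / den
  zB <- sqrt(n0) * (r * (r + q) * (y[["B"]] - y[["0"]]) +
                      q * r * (1 + r) * (y[["AB"]] - y[["A"]])) / den
  zAB <- sqrt(n0) * (y[["AB"]] - y[["0"]]) / (sigma * sqrt((1 + q) / q))
  stats::setNames(c(zA, zB, zAB), arm_names)
}

#' Critical value of the factorial design
#'
#' Convenience wrapper: [critical_value()] applied to
#' [factorial_covariance()].
#'
#' @inheritParams factorial_covariance
#' @param alpha One-sided familywise error rate.
#' @return The common critical value `k`.
#' @export
factorial_critical_value <- function(alloc, alpha = 0.05) {
  critical_value(factorial_covariance(alloc), alpha)
}

#' Disjunctive power of the factorial design
#'
#' Probability of rejecting at least one of the three null hypotheses,
#' `1 - P(Z_A <= k, Z_B <= k, Z_AB <= k)` under the alternative-law
#' trivariate normal with mean [factorial_mean()] and covariance
#' [factorial_covariance()].
#'
#' @inheritParams factorial_mean
#' @param alpha One-sided familywise error rate used to calibrate `k`.
#' @param crit Optional pre-computed critical value (skips the root find).
#' @return The disjunctive power.
#' @examples
#' \donttest{
#' sc <- effect_scenario(0, 0.5, 0.1, 0.6, sigma = 1)
#' factorial_power(allocation_ratios(1, 1), n0 = 40, sc)  # >= 0.9
#' }
#' @export
factorial_power <- function(alloc, n0, scen, alpha = 0.05, crit = NULL) {
  alloc <- as_alloc(alloc)
  if (is.null(crit)) crit <- factorial_critical_value(alloc, alpha)
  law <- joint_law(factorial_mean(alloc, n0, scen), factorial_covariance(alloc))
  rejection_prob(law, crit)
}

# shared integer sample-size search: solve power(n0) = target on continuous
# n0, then take the smallest integer n0 whose power reaches the target
solve_n0 <- function(power_fn, target) {
  f <- function(n0) power_fn(n0) - target
  hi <- 2
  while (f(hi) < 0) {
    hi <- hi * 2
    if (hi > 1e7) stop("sample-size search did not converge; is any ",
                       "treatment effect positive?", call. = FALSE)
  }
  n_cont <- stats::uniroot(f, c(1e-3, hi), tol = 1e-6)$root
  n0 <- max(1L, as.integer(ceiling(n_cont - 1e-9)))
  while (f(n0) < 0) n0 <- n0 + 1L
  while (n0 > 1L && f(n0 - 1L) >= 0) n0 <- n0 - 1L
  list(n_cont = n_cont, n0 = n0)
}

make_sample_size_result <- function(design, alloc, scen, alpha, power_target,
                                    crit, sol, power_fn) {
  r <- alloc$r; q <- alloc$q
  n0 <- sol$n0
  structure(list(
    design = design,
    allocation = alloc,
    scenario = scen,
    alpha = alpha,
    power_target = power_target,
    critical_value = crit,
    n0_continuous = sol$n_cont,
    n0 = n0,
    n_per_group = stats::setNames(
      c(n0, round(r * n0), round(r * n0), round(q * n0)),
      c("0", "A", "B", "AB")),
    total = as.integer(round(n0 * (1 + 2 * r + q))),
    achieved_power = power_fn(n0)
  ), class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf("%s design sample size (alpha = %g, target power = %g)\n",
              x$design, x$alpha, x$power_target))
  cat(sprintf("  allocation r = %g, q = %g; critical value k = %.3f\n",
              x$allocation$r, x$allocation$q, x$critical_value))
  cat(sprintf("  n0 = %d (continuous solution %.2f); per group (0,A,B,AB): %s\n",
              x$n0, x$n0_continuous, paste(x$n_per_group, collapse = ", ")))
  cat(sprintf("  total = %d patients; achieved power = %.4f\n",
              x$total, x$achieved_power))
  invisible(x)
}

#' Sample size of the factorial design
#'
#' Smallest integer control-group size `n0` whose disjunctive power reaches
#' `power` at familywise error `alpha`, found by root finding on continuous
#' `n0` followed by an integer refinement.  The reported trial size is
#' `total = round(n0 * (1 + 2r + q))`.
#'
#' @inheritParams factorial_power
#' @param power Target power in (0, 1), probability of rejecting at least
#'   one null hypothesis under `scen`.
#' @return A `"sample_size_result"` with the continuous solution, `n0`,
#'   per-group sizes and the total.
#' @examples
#' \donttest{
#' sc <- scenario_suite("iii", delta = 0.5, delta0 = 0.1, sigma = 1)
#' factorial_sample_size(allocation_ratios(1, 1), sc)  # total 160
#' }
#' @export
factorial_sample_size <- function(alloc, scen, alpha = 0.05, power = 0.9) {
  alloc <- as_alloc(alloc)
  stopifnot(inherits(scen, "effect_scenario"))
  if (!is.numeric(power) || power <= 0 || power >= 1)
    stop("'power' must be in (0, 1)", call. = FALSE)
  mu <- scenario_means(scen)
  if (max(mu[c("muA", "muB", "muAB")]) <= mu[["mu0"]])
    stop("no treatment mean exceeds the control mean: the target power ",
         "cannot be reached at any sample size", call. = FALSE)
  crit <- factorial_critical_value(alloc, alpha)
  pf <- function(n0) factorial_power(alloc, n0, scen, alpha, crit = crit)
  sol <- solve_n0(pf, power)
  make_sample_size_result("factorial", alloc, scen, alpha, power, crit, sol, pf)
}

#' Allocation-ratio optimisation over a grid
#'
#' Evaluates either the familywise critical value or the total sample size
#' on the full `r x q` grid and returns the grid with its minimiser (ties
#' broken by the first point in row-major r-then-q order).
#'
#' @param r_grid,q_grid Numeric vectors of allocation ratios (> 0).
#' @param objective `"critical_value"` or `"total_sample_size"`.
#' @param scen Effect scenario, required for the sample-size objective.
#' @param alpha One-sided familywise error rate.
#' @param power Target power for the sample-size objective.
#' @param design `"factorial"` (default) or `"ma"`.
#' @return A data frame of class `"allocation_grid"` with columns `r`, `q`,
#'   `objective`, `is_optimum`; the minimiser is also in
#'   `attr(x, "optimum")`.
#' @examples
#' \donttest{
#' # constrained search r = q: optimum at r = q = 1.7 (k = 2.017)
#' g <- seq(0.5, 2.5, by = 0.1)
#' opt <- optimize_allocation(g, g, "critical_value", constrain_equal = TRUE)
#' attr(opt, "optimum")
#' }
#' @param constrain_equal If `TRUE`, restrict the search to the diagonal
#'   `r = q` (the grids must then be equal).
#' @export
optimize_allocation <- function(r_grid, q_grid,
                                objective = c("critical_value",
                                              "total_sample_size"),
                                scen = NULL, alpha = 0.05, power = 0.9,
                                design = c("factorial", "ma"),
                                constrain_equal = FALSE) {
  objective <- match.arg(objective)
  design <- match.arg(design)
  if (length(r_grid) == 0L || length(q_grid) == 0L)
    stop("allocation grids must be non-empty", call. = FALSE)
  if (any(r_grid <= 0) || any(q_grid <= 0))
    stop("allocation ratios must be positive", call. = FALSE)
  if (constrain_equal) {
    grid <- data.frame(r = r_grid, q = r_grid)
  } else {
    grid <- expand.grid(q = q_grid, r = r_grid,
                        KEEP.OUT.ATTRS = FALSE)[, c("r", "q")]
  }
  cov_fn <- if (design == "factorial") factorial_covariance else ma_covariance
  val <- vapply(seq_len(nrow(grid)), function(i) {
    alloc <- allocation_ratios(grid$r[i], grid$q[i])
    if (objective == "critical_value") {
      critical_value(cov_fn(alloc), alpha)
    } else {
      if (is.null(scen))
        stop("'scen' is required for the sample-size objective", call. = FALSE)
      ss <- if (design == "factorial")
        factorial_sample_size(alloc, scen, alpha, power)
      else ma_sample_size(alloc, scen, alpha, power)
      as.numeric(ss$total)
    }
  }, numeric(1))
  grid$objective <- val
  best <- which.min(val)            # first match in row-major order
  grid$is_optimum <- seq_along(val) == best
  structure(grid,
            optimum = grid[best, , drop = FALSE],
            objective_name = objective, design = design, alpha = alpha,
            class = c("allocation_grid", "data.frame"))
}

#' Write an allocation grid as CSV
#'
#' Emits the columns `r`, `q`, `objective`, `is_optimum`.
#'
#' @param grid An `"allocation_grid"` from [optimize_allocation()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  stopifnot(inherits(grid, "allocation_grid"))
  utils::write.csv(as.data.frame(grid)[, c("r", "q", "objective", "is_optimum")],
                   path, row.names = FALSE)
  invisible(path)
}
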