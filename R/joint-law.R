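# Joint trivariate normal law of the three treatment-versus-control
# z-statistics, for the factorial and the single-stage multi-arm design.

arm_names <- c("A", "B", "AB")

#' Correlation matrix of the factorial z-statistics
#'
#' The three factorial test statistics (the two single-treatment statistics,
#' which borrow information from the combination arm under additivity, and
#' the plain combination-versus-control statistic) are marginally standard
#' normal and jointly trivariate normal.  This returns their correlation
#' matrix as a function of the allocation ratios only:
#' \deqn{V_{A,B} = \frac{r(r+q)^2 + qr(1+r)^2 - 2q(1+r)(r+q)}
#'                      {(1+r)(r+q)(r+2q+rq)}, \quad
#'       V_{A,AB} = V_{B,AB} = \frac{\sqrt{rq}\,(1+2r+q)}
#'                      {\sqrt{(1+r)(1+q)(r+q)(r+2q+rq)}}.}
#'
#' `V[A,B]` vanishes exactly when `q = r^2`; the matrix is positive
#' semidefinite everywhere and singular precisely on the line `q = 1`,
#' where `Z_AB` is a linear combination of `Z_A` and `Z_B` (the balanced
#' design `r = q = 1` included).
#'
#' @param alloc An [allocation_ratios()] object (or numeric pair `c(r, q)`).
#' @return A 3x3 correlation matrix with dimnames `A`, `B`, `AB`.
#' @examples
#' factorial_covariance(allocation_ratios(1, 1))["A", "AB"]  # 1/sqrt(2)
#' factorial_covariance(c(0.5, 0.25))["A", "B"]              # 0 since q = r^2
#' @export
factorial_covariance <- function(alloc) {
  alloc <- as_alloc(alloc)
  r <- alloc$r; q <- alloc$q
  den <- (1 + r) * (r + q) * (r + 2 * q + r * q)
  v_ab <- (r * (r + q)^2 + q * r * (1 + r)^2 - 2 * q * (1 + r) * (r + q)) / den
  v_ax <- sqrt(r * q) * (1 + 2 * r + q) /
    sqrt((1 + r) * (1 + q) * (r + q) * (r + 2 * q + r * q))
  V <- diag(3)
  V[1L, 2L] <- V[2L, 1L] <- v_ab
  V[1L, 3L] <- V[3L, 1L] <- V[2L, 3L] <- V[3L, 2L] <- v_ax
  dimnames(V) <- list(arm_names, arm_names)
  V
}

#' Mean of the factorial z-statistics under an alternative
#'
#' Expectation of `(Z_A, Z_B, Z_AB)` when the true group means are those of
#' `scen` and the control group has `n0` patients (continuous `n0` allowed,
#' as used by the sample-size search):
#' \deqn{E Z_A = \frac{\sqrt{r n_0}\,[(r+q)(\mu_A-\mu_0) +
#'   q(1+r)(\mu_{AB}-\mu_B)]}{\sigma\sqrt{(1+r)(r+q)(r+2q+qr)}}, \quad
#'   E Z_{AB} = \frac{\sqrt{q n_0}\,(\mu_{AB}-\mu_0)}{\sigma\sqrt{1+q}},}
#' and `E Z_B` with the roles of A and B exchanged.  The covariance is
#' unchanged under the alternative.
#'
#' @inheritParams factorial_covariance
#' @param n0 Control-group size (> 0, not necessarily integer).
#' @param scen An [effect_scenario()] object.
#' @return Named numeric 3-vector `(A, B, AB)`.
#' @examples
#' sc <- effect_scenario(0, 0.5, 0.1, 0.6, sigma = 1)
#' factorial_mean(allocation_ratios(1, 1), 40, sc)  # (3.1623, 0.6325, 2.6833)
#' @export
factorial_mean <- function(alloc, n0, scen) {
  alloc <- as_alloc(alloc)
  stopifnot(inherits(scen, "effect_scenario"))
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 <= 0)
    stop("'n0' must be a single positive number", call. = FALSE)
  r <- alloc$r; q <- alloc$q
  mu <- scenario_means(scen); sigma <- scen$sigma
  den <- sigma * sqrt((1 + r) * (r + q) * (r + 2 * q + q * r))
  zA <- sqrt(r * n0) * ((r + q) * (mu[["muA"]] - mu[["mu0"]]) +
                          q * (1 + r) * (mu[["muAB"]] - mu[["muB"]])) / den
  zB <- sqrt(r * n0) * ((r + q) * (mu[["muB"]] - mu[["mu0"]]) +
                          q * (1 + r) * (mu[["muAB"]] - mu[["muA"]])) / den
  zAB <- sqrt(q * n0) * (mu[["muAB"]] - mu[["mu0"]]) / (sigma * sqrt(1 + q))
  stats::setNames(c(zA, zB, zAB), arm_names)
}

#' Correlation matrix of the multi-arm (Dunnett) z-statistics
#'
#' In the multi-arm design each active arm is compared with control using
#' only its own and the control data, so the statistics share only the
#' control sample: correlation `r/(1+r)` between the two single-arm
#' statistics and `sqrt(rq)/sqrt((1+r)(1+q))` between a single-arm and the
#' combination statistic.  Positive definite for all `r, q > 0`.
#'
#' @inheritParams factorial_covariance
#' @return A 3x3 correlation matrix with dimnames `A`, `B`, `AB`.
#' @examples
#' ma_covariance(allocation_ratios(1, 1))  # all off-diagonals 1/2
#' @export
ma_covariance <- function(alloc) {
  alloc <- as_alloc(alloc)
  r <- alloc$r; q <- alloc$q
  W <- diag(3)
  W[1L, 2L] <- W[2L, 1L] <- r / (1 + r)
  W[1L, 3L] <- W[3L, 1L] <- W[2L, 3L] <- W[3L, 2L] <-
    sqrt(r * q / ((1 + r) * (1 + q)))
  dimnames(W) <- list(arm_names, arm_names)
  W
}

#' Mean of the multi-arm z-statistics under an alternative
#'
#' `E Z'_j = sqrt(n0 n_j / (n0 + n_j)) (mu_j - mu_0) / sigma` with
#' `n_A = n_B = r n0` and `n_AB = q n0`.  The combination statistic is the
#' same in the factorial and the multi-arm design, so the third component
#' equals the third component of [factorial_mean()].
#'
#' @inheritParams factorial_mean
#' @return Named numeric 3-vector `(A, B, AB)`.
#' @export
ma_mean <- function(alloc, n0, scen) {
  alloc <- as_alloc(alloc)
  stopifnot(inherits(scen, "effect_scenario"))
  if (!is.numeric(n0) || length(n0) != 1L || !is.finite(n0) || n0 <= 0)
    stop("'n0' must be a single positive number", call. = FALSE)
  r <- alloc$r; q <- alloc$q
  mu <- scenario_means(scen); sigma <- scen$sigma
  ratio <- c(r, r, q)
  eff <- c(mu[["muA"]], mu[["muB"]], mu[["muAB"]]) - mu[["mu0"]]
  stats::setNames(sqrt(n0 * ratio / (1 + ratio)) * eff / sigma, arm_names)
}

#' Joint law of the three test statistics
#'
#' Bundles a mean vector and correlation matrix, validating that the matrix
#' is a symmetric positive-semidefinite correlation matrix (unit diagonal).
#'
#' @param mean Numeric 3-vector of expectations.
#' @param cov 3x3 correlation matrix.
#' @return An object of class `"joint_law"`.
#' @export
joint_law <- function(mean, cov) {
  if (length(mean) != 3L || any(!is.finite(mean)))
    stop("'mean' must be three finite numbers", call. = FALSE)
  if (!is.matrix(cov) || any(dim(cov) != 3L) || any(!is.finite(cov)))
    stop("'cov' must be a finite 3x3 matrix", call. = FALSE)
  if (max(abs(cov - t(cov))) > 1e-10)
    stop("'cov' must be symmetric", call. = FALSE)
  if (max(abs(diag(cov) - 1)) > 1e-10)
    stop("'cov' must have unit diagonal (correlation matrix)", call. = FALSE)
  ev <- eigen(cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("'cov' is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")", call. = FALSE)
  structure(list(mean = stats::setNames(as.numeric(mean), arm_names), cov = cov),
            class = "joint_law")
}

#' Probability of rejecting at least one hypothesis at critical value k
#'
#' `1 - P(Z_A <= k, Z_B <= k, Z_AB <= k)` under the given trivariate normal
#' law.  Under the null law this is the familywise error rate of the common
#' critical value `k`; under an alternative it is the disjunctive power.
#'
#' @param law A [joint_law()] object.
#' @param k Common one-sided critical value.
#' @return A probability (absolute integration tolerance about 1e-7).
#' @examples
#' null_law <- joint_law(rep(0, 3), diag(3))
#' rejection_prob(null_law, 2) - (1 - pnorm(2)^3)  # ~0: independence case
#' @export
rejection_prob <- function(law, k) {
  stopifnot(inherits(law, "joint_law"))
  if (!is.numeric(k) || length(k) != 1L || is.na(k))
    stop("'k' must be a single number", call. = FALSE)
  if (k == Inf) return(0)
  1 - tvn_lower(rep(k, 3L), law$mean, law$cov)
}

#' Familywise-error-controlling critical value
#'
#' Solves `P(Z_A <= k, Z_B <= k, Z_AB <= k) = 1 - alpha` under the zero-mean
#' trivariate normal null law with correlation matrix `cov`, by bracketed
#' root finding on `[qnorm(1-alpha) - 0.01, qnorm(1-alpha/3) + 0.01]`
#' (single-test and Bonferroni bounds).
#'
#' @param cov 3x3 correlation matrix of the test statistics under the null.
#' @param alpha One-sided familywise error rate, in (0, 1).
#' @param tol Root-finding tolerance on k (default 1e-6; the design tables
#'   quote three decimals).
#' @return The critical value `k`.
#' @examples
#' \donttest{
#' critical_value(factorial_covariance(c(1, 1)), 0.05)  # 2.028
#' }
#' @export
critical_value <- function(cov, alpha, tol = 1e-6) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  law <- joint_law(rep(0, 3L), cov)
  lo <- stats::qnorm(1 - alpha) - 0.01
  hi <- stats::qnorm(1 - alpha / 3) + 0.01
  f <- function(k) tvn_lower(rep(k, 3L), law$mean, law$cov) - (1 - alpha)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}
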