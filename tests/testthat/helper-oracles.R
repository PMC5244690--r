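# Shared fixtures and independent Monte-Carlo oracles.

case_study <- list(delta = 28, delta0 = 7, sigma = 50)

# Monte-Carlo estimate of 1 - P(all three statistics <= k) by direct
# sampling of the trivariate normal (eigendecomposition handles the
# singular correlation matrices on the q = 1 line).
mc_rejection <- function(mean, cov, k, n = 1e6, seed = 404) {
  withr::with_seed(seed, {
    ee <- eigen(cov, symmetric = TRUE)
    ev <- pmax(ee$values, 0)
    z <- matrix(rnorm(3 * n), ncol = 3) %*% (t(ee$vectors) * sqrt(ev))
    z <- sweep(z, 2L, mean, "+")
    p <- mean(apply(z > k, 1L, any))
    list(p = p, se = sqrt(p * (1 - p) / n))
  })
}

# Monte-Carlo oracle for the single-stage "combination best and
# significant" probability under the LFC, used by the MAMS degenerate-
# boundary reduction check.  Equal allocation, n patients per arm.
mc_selection_power <- function(n, delta, delta0, sigma, k, nsim = 4e5,
                               seed = 505) {
  withr::with_seed(seed, {
    mu <- c(0, delta0, delta0, delta)
    m <- vapply(mu, function(m0) rnorm(nsim, m0, sigma / sqrt(n)), numeric(nsim))
    z <- sweep(m[, -1L], 1L, m[, 1L]) * sqrt(n / 2) / sigma
    p <- mean(z[, 3L] > k & z[, 3L] >= z[, 1L] & z[, 3L] >= z[, 2L])
    list(p = p, se = sqrt(p * (1 - p) / nsim))
  })
}

expect_within_3se <- function(estimate, se, truth) {
  expect_lt(abs(estimate - truth), 3 * se + 1e-12)
}
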