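test_that("allocation and scenario constructors reject degenerate inputs", {
  expect_error(allocation_ratios(0, 1), "positive")
  expect_error(allocation_ratios(1, -2), "positive")
  expect_error(allocation_ratios(Inf, 1), "finite")
  expect_error(allocation_ratios(NA, 1), "finite")
  expect_error(effect_scenario(0, 1, 1, 1, sigma = 0), "positive")
  expect_error(scenario_suite("v", 1, 0.1, 1), "unknown scenario")
})

test_that("factorial covariance matches the closed form and its special cases", {
  V <- factorial_covariance(allocation_ratios(1, 1))
  expect_equal(V["A", "AB"], 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(V["A", "B"], 0, tolerance = 1e-12)  # balanced lies on q = r^2
  expect_equal(diag(V), c(A = 1, B = 1, AB = 1))

  # Z_A and Z_B are uncorrelated exactly when q = r^2
  for (r in c(0.3, 0.5, 1.4, 2)) {
    expect_equal(factorial_covariance(c(r, r^2))["A", "B"], 0,
                 tolerance = 1e-12)
    expect_gt(abs(factorial_covariance(c(r, r^2 + 0.2))["A", "B"]), 1e-4)
  }
})

test_that("factorial covariance is a PSD correlation matrix, singular on q = 1", {
  for (r in c(0.2, 0.7, 1, 1.7, 2.5)) {
    for (q in c(0.3, 1, 1.9)) {
      V <- factorial_covariance(c(r, q))
      expect_equal(V, t(V))
      expect_equal(V["A", "AB"], V["B", "AB"])
      ev <- eigen(V, symmetric = TRUE, only.values = TRUE)$values
      expect_gt(min(ev), -1e-10)
      if (abs(q - 1) > 1e-9) expect_gt(min(ev), 1e-4)  # PD off the q = 1 line
      else expect_lt(min(ev), 1e-10)                   # exactly singular on it
    }
  }
})

test_that("corr(Z_A, Z_AB) along q = r^2 is sqrt(r/(1+r^2)), maximal 1/sqrt(2) at r = 1", {
  rs <- seq(0.2, 3, by = 0.2)
  corr <- vapply(rs, function(r) factorial_covariance(c(r, r^2))["A", "AB"],
                 numeric(1))
  expect_equal(corr, sqrt(rs / (1 + rs^2)), tolerance = 1e-12)
  expect_equal(max(corr), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(rs[which.max(corr)], 1)
})

test_that("factorial mean reproduces the closed-form examples", {
  sc <- effect_scenario(0, 0.5, 0.1, 0.6, sigma = 1)
  m <- factorial_mean(allocation_ratios(1, 1), 40, sc)
  expect_equal(unname(m), c(sqrt(40) / 2, 0.4 * sqrt(40) / 4, sqrt(20) * 0.6),
               tolerance = 1e-12)
  expect_equal(round(unname(m), 4), c(3.1623, 0.6325, 2.6833))

  # antagonistic LFC: strong A effect pulls Z_B negative through the
  # combination-arm correction
  m2 <- factorial_mean(allocation_ratios(1, 1), 176,
                       effect_scenario(0, 0.5, 0.1, 0.1, sigma = 1))
  expect_equal(round(m2[["A"]], 4), 3.3166)
  expect_lt(m2[["B"]], 0)

  null <- factorial_mean(allocation_ratios(1.3, 0.6), 55,
                         effect_scenario(2, 2, 2, 2, sigma = 3))
  expect_equal(unname(null), c(0, 0, 0))
  expect_error(factorial_mean(allocation_ratios(1, 1), -5, sc), "positive")
})

test_that("multi-arm covariance and mean follow the Dunnett structure", {
  W <- ma_covariance(allocation_ratios(1, 1))
  expect_equal(unname(W[upper.tri(W)]), rep(0.5, 3))
  expect_equal(ma_covariance(c(1, 3))["A", "AB"], sqrt(3) / sqrt(8),
               tolerance = 1e-12)
  for (rq in list(c(0.4, 2), c(2, 0.3), c(1.7, 1.7))) {
    W <- ma_covariance(rq)
    expect_equal(W, t(W))
    expect_gt(min(eigen(W, symmetric = TRUE, only.values = TRUE)$values), 0)
  }

  sc <- effect_scenario(0, 0.2, 0.1, 0.6, sigma = 1)
  m <- ma_mean(allocation_ratios(1, 1), 40, sc)
  expect_equal(m[["AB"]], sqrt(20) * 0.6, tolerance = 1e-12)
  # same statistic as in the factorial design
  expect_equal(m[["AB"]],
               factorial_mean(allocation_ratios(1, 1), 40, sc)[["AB"]])
  # linear in the effects
  sc2 <- effect_scenario(0, 0.4, 0.2, 1.2, sigma = 1)
  expect_equal(unname(ma_mean(allocation_ratios(1, 1), 40, sc2)),
               2 * unname(m), tolerance = 1e-12)
  expect_equal(unname(ma_mean(allocation_ratios(1, 1), 40,
                              effect_scenario(1, 1, 1, 1, 2))), c(0, 0, 0))
})

test_that("rejection_prob matches independence closed form and MC oracle", {
  null_ind <- joint_law(rep(0, 3), diag(3))
  for (k in c(1, 2, 2.5))
    expect_equal(rejection_prob(null_ind, k), 1 - pnorm(k)^3,
                 tolerance = 1e-6)
  expect_equal(rejection_prob(null_ind, Inf), 0)

  # quasi-MC integration against a plain MC oracle, incl. a singular law
  for (cfg in list(list(a = c(1, 1), mu = c(0, 0, 0)),
                   list(a = c(1.7, 0.8), mu = c(1.2, -0.3, 0.9)))) {
    V <- factorial_covariance(cfg$a)
    p <- rejection_prob(joint_law(cfg$mu, V), 2)
    mc <- mc_rejection(cfg$mu, V, 2)
    expect_within_3se(mc$p, mc$se, p)
  }
})

test_that("critical_value solves the FWER equation within its bounds", {
  V <- factorial_covariance(allocation_ratios(1, 1))
  k <- critical_value(V, 0.05)
  expect_equal(round(k, 3), 2.028)
  expect_equal(rejection_prob(joint_law(rep(0, 3), V), k), 0.05,
               tolerance = 1e-4)
  expect_equal(round(critical_value(factorial_covariance(c(1.7, 1.7)), 0.05), 3),
               2.017)
  expect_equal(critical_value(diag(3), 0.05), qnorm(0.95^(1 / 3)),
               tolerance = 1e-4)

  # monotone in alpha, inside single-test and Bonferroni bounds
  ks <- vapply(c(0.01, 0.05, 0.2), function(a) critical_value(V, a), numeric(1))
  expect_true(all(diff(ks) < 0))
  for (i in seq_along(ks)) {
    a <- c(0.01, 0.05, 0.2)[i]
    expect_gte(ks[i], qnorm(1 - a) - 1e-6)
    expect_lte(ks[i], qnorm(1 - a / 3) + 1e-6)
  }
  expect_error(critical_value(V, 1.2), "alpha")
  expect_error(critical_value(matrix(2, 3, 3), 0.05), "diagonal")
})
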