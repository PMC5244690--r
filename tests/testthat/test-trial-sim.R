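test_that("the generator maps linear-model coefficients to Table-style cell means", {
  eff <- linear_model_effects(beta0 = 1, beta1 = 2, beta2 = 3, beta3 = -4,
                              sigma = 1)
  expect_equal(cell_means(eff), c(mu0 = 1, muA = 3, muB = 4, muAB = 2))
  sc <- as_effect_scenario(eff)
  expect_equal(sc$muAB, 2)

  # sigma = 0: the sample means are the cell means exactly
  gs <- simulate_groups(linear_model_effects(1, 2, 3, -4, sigma = 0),
                        c(5, 5, 5, 5), seed = 1)
  expect_equal(unname(gs$means), c(1, 3, 4, 2))
})

test_that("the generator is reproducible and leaves the caller's RNG alone", {
  eff <- linear_model_effects(beta1 = 0.5, sigma = 1)
  g1 <- simulate_groups(eff, c(10, 10, 10, 10), seed = 42)
  g2 <- simulate_groups(eff, c(10, 10, 10, 10), seed = 42)
  expect_identical(g1$means, g2$means)
  g3 <- simulate_groups(eff, c(10, 10, 10, 10), seed = 43)
  expect_false(identical(g1$means, g3$means))

  set.seed(5)
  x1 <- runif(1)
  invisible(simulate_groups(eff, c(10, 10, 10, 10), seed = 1))
  x2 <- runif(1)
  set.seed(5)
  expect_identical(c(x1, x2), runif(2))  # generator did not disturb the stream
  expect_error(simulate_groups(eff, c(10, 10, 10, 10)), "seed")
  expect_error(simulate_groups(eff, c(0, 10, 10, 10), seed = 1), "positive")
})

test_that("group means are unbiased for the cell means (law of large numbers)", {
  eff <- linear_model_effects(beta0 = 0.2, beta1 = 0.5, beta2 = 0.1,
                              beta3 = -0.3, sigma = 1)
  nsim <- 20000L
  n_ab <- 12L
  yab <- withr::with_seed(77, vapply(seq_len(nsim), function(i)
    simulate_groups(eff, c(4, 4, 4, n_ab),
                    seed = sample.int(2^30, 1))$means[["AB"]],
    numeric(1)))
  truth <- cell_means(eff)[["muAB"]]
  se <- 1 / sqrt(n_ab) / sqrt(nsim)
  expect_within_3se(mean(yab), se, truth)
})

test_that("scenario presets reproduce the printed configurations", {
  d <- 28; d0 <- 7; s <- 50
  expect_equal(unname(scenario_means(scenario_suite("0", d, d0, s))),
               rep(0, 4))
  expect_equal(unname(scenario_means(scenario_suite("i", d, d0, s))),
               c(0, 28, 7, 7))
  expect_equal(unname(scenario_means(scenario_suite("ii", d, d0, s))),
               c(0, 7, 7, 28))
  expect_equal(unname(scenario_means(scenario_suite("iii", d, d0, s))),
               c(0, 28, 7, 35))
  expect_equal(unname(scenario_means(scenario_suite("iv", d, d0, s))),
               c(0, 7, 7, 14))
  # (ii) and (iv) coincide only when delta = 2 * delta0
  expect_equal(scenario_means(scenario_suite("ii", 14, 7, s)),
               scenario_means(scenario_suite("iv", 14, 7, s)))
  expect_false(isTRUE(all.equal(
    scenario_means(scenario_suite("ii", d, d0, s)),
    scenario_means(scenario_suite("iv", d, d0, s)))))
})

test_that("every design holds its familywise error under its own null", {
  null_eff <- linear_model_effects(sigma = 1)
  for (design in c("factorial", "ma", "mams2")) {
    oc <- empirical_rejection(design, null_eff, n0 = 50, nsim = 1e4,
                              seed = 314)
    g <- oc[oc$hypothesis == "global", ]
    expect_within_3se(g$rate, g$se, 0.05)
  }
})

test_that("analytic power equals empirical power across scenarios (both designs)", {
  alloc <- allocation_ratios(1, 1)
  kf <- factorial_critical_value(alloc, 0.05)
  km <- ma_critical_value(alloc, 0.05)
  n0 <- 45
  for (preset in c("0", "i", "ii", "iii", "iv")) {
    sc <- scenario_suite(preset, case_study$delta, case_study$delta0,
                         case_study$sigma)
    for (design in c("factorial", "ma")) {
      oc <- empirical_rejection(design, sc, n0 = n0, alloc = alloc,
                                nsim = 1e4, seed = 1000 + as.integer(charmatch(preset, c("0","i","ii","iii","iv"))),
                                crit = if (design == "factorial") kf else km)
      g <- oc[oc$hypothesis == "global", ]
      truth <- if (design == "factorial")
        factorial_power(alloc, n0, sc, crit = kf)
      else ma_power(alloc, n0, sc, crit = km)
      expect_within_3se(g$rate, g$se, truth)
    }
  }
})

test_that("synergy inflates the factorial single-arm type-I error, monotonically, but not the Dunnett test", {
  alloc <- allocation_ratios(1, 1)
  kf <- factorial_critical_value(alloc, 0.05)
  km <- ma_critical_value(alloc, 0.05)
  b3_grid <- c(-1, -0.5, 0, 0.5, 1)
  rateA <- vapply(seq_along(b3_grid), function(i) {
    eff <- linear_model_effects(beta3 = b3_grid[i], sigma = 1)
    oc <- empirical_rejection("factorial", eff, n0 = 50, alloc = alloc,
                              nsim = 1e4, seed = 200 + i, crit = kf)
    oc$rate[oc$hypothesis == "A"]
  }, numeric(1))
  expect_true(all(diff(rateA) > 0))            # monotone in beta3
  se <- sqrt(0.05 * 0.95 / 1e4)
  expect_gt(rateA[4], 0.05 + 3 * se)           # inflated under synergy
  expect_gt(rateA[5], rateA[4])

  # the multi-arm statistics ignore the combination arm entirely: the
  # single-arm error stays at its analytic value whatever beta3 does
  for (b3 in c(-1, 1)) {
    eff <- linear_model_effects(beta3 = b3, sigma = 1)
    oc <- empirical_rejection("ma", eff, n0 = 50, alloc = alloc, nsim = 1e4,
                              seed = 300, crit = km)
    rA <- oc[oc$hypothesis == "A", ]
    expect_within_3se(rA$rate, rA$se, 1 - pnorm(km))
  }
})

test_that("operating characteristics carry their resolved configuration and write CSV", {
  oc <- empirical_rejection("factorial", linear_model_effects(sigma = 1),
                            n0 = 20, nsim = 200, seed = 9)
  cfg <- attr(oc, "config")
  expect_identical(cfg$design, "factorial")
  expect_identical(cfg$seed, 9L)
  expect_true(all(oc$rate >= 0 & oc$rate <= 1))
  # global rejection = any rejection >= each marginal
  expect_true(all(oc$rate[oc$hypothesis == "global"] >=
                    oc$rate[oc$hypothesis != "global"]))

  path <- withr::local_tempfile(fileext = ".csv")
  write_oc_csv(oc, path)
  back <- read.csv(path)
  expect_identical(names(back),
                   c("design", "hypothesis", "rate", "se", "nsim", "seed"))
  expect_equal(back$rate, oc$rate, tolerance = 1e-12)
  expect_error(empirical_rejection("factorial",
                                   linear_model_effects(sigma = 1),
                                   n0 = 20, nsim = 0, seed = 1), "nsim")
})
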