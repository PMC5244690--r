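# Head-to-head design comparison and reporting glue.

balanced <- function() allocation_ratios(1, 1)

#' Head-to-head comparison of factorial, multi-arm and MAMS designs
#'
#' Sizes each design once for the given design criteria — the factorial
#' under the additive alternative (scenario `"iii"`), the multi-arm under
#' the least favourable configuration on the combination (scenario `"ii"`),
#' the MAMS design by its least-favourable-configuration power — and then
#' evaluates, for each requested alternative scenario, the global and
#' per-hypothesis rejection probabilities of all three designs (analytic
#' trivariate-normal probabilities for factorial and multi-arm, seeded
#' simulation for MAMS).  All designs are balanced (`r = q = 1`).
#'
#' @param delta,delta0 Interesting / uninteresting effect sizes.
#' @param sigma Common standard deviation.
#' @param alpha One-sided familywise error rate.
#' @param power Target power used to size each design.
#' @param scenarios Character vector of preset names (see
#'   [scenario_suite()]); must be non-empty.
#' @param nsim,seed Simulation size and seed for the MAMS rows.
#' @return A data frame of class `"design_comparison"` with columns
#'   `scenario`, `design`, `hypothesis`, `probability`, `method`, `n0`,
#'   `total`; the resolved configuration is in `attr(x, "config")`.
#' @examples
#' \donttest{
#' cmp <- compare_designs(delta = 28, delta0 = 7, sigma = 50,
#'                        scenarios = c("0", "i"), nsim = 2000)
#' subset(cmp, hypothesis == "global")
#' }
#' @export
compare_designs <- function(delta, delta0, sigma, alpha = 0.05, power = 0.9,
                            scenarios = c("0", "i", "ii", "iii", "iv"),
                            nsim = 10000L, seed = 1L) {
  scenarios <- as.character(scenarios)
  if (length(scenarios) == 0L)
    stop("'scenarios' must name at least one alternative", call. = FALSE)
  config <- list(command = "compare", delta = delta, delta0 = delta0,
                 sigma = sigma, alpha = alpha, power = power,
                 scenarios = scenarios, nsim = as.integer(nsim),
                 seed = as.integer(seed))

  fac <- factorial_sample_size(balanced(),
                               scenario_suite("iii", delta, delta0, sigma),
                               alpha, power)
  ma <- ma_sample_size(balanced(),
                       scenario_suite("ii", delta, delta0, sigma),
                       alpha, power)
  mams <- mams_sample_size(alpha, power, delta, delta0, sigma)

  rows <- lapply(scenarios, function(sc_name) {
    scen <- scenario_suite(sc_name, delta, delta0, sigma)
    an <- function(design, mean_fn, cov_fn, ss) {
      m <- mean_fn(ss$allocation, ss$n0, scen)
      k <- ss$critical_value
      law <- joint_law(m, cov_fn(ss$allocation))
      data.frame(scenario = sc_name, design = design,
                 hypothesis = c(arm_names, "global"),
                 probability = c(1 - stats::pnorm(k - m), rejection_prob(law, k)),
                 method = "analytic", n0 = ss$n0, total = ss$total)
    }
    oc <- empirical_rejection("mams2",
                              effect_scenario(scen$mu0, scen$muA, scen$muB,
                                              scen$muAB, sigma),
                              n0 = mams$n_per_stage, alpha = alpha,
                              nsim = nsim, seed = seed,
                              boundaries = mams$boundaries)
    mams_rows <- data.frame(scenario = sc_name, design = "mams2",
                            hypothesis = oc$hypothesis[oc$hypothesis != "AB_selected"],
                            probability = oc$rate[oc$hypothesis != "AB_selected"],
                            method = "simulated", n0 = mams$n_per_stage,
                            total = mams$max_total)
    rbind(an("factorial", factorial_mean, factorial_covariance, fac),
          an("ma", ma_mean, ma_covariance, ma),
          mams_rows)
  })
  structure(do.call(rbind, rows),
            config = config,
            sizes = list(factorial = fac, ma = ma, mams = mams),
            class = c("design_comparison", "data.frame"))
}

#' @export
print.design_comparison <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Design comparison (Delta = %g, delta0 = %g, sigma = %g, alpha = %g, power = %g)\n",
              cfg$delta, cfg$delta0, cfg$sigma, cfg$alpha, cfg$power))
  df <- as.data.frame(x)
  df$probability <- sprintf("%.4f", df$probability)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Interaction sweep: power and expected sample size against beta3
#'
#' For a grid of interaction strengths `beta3`, fixes the single-treatment
#' effects `muA - mu0` and `muB - mu0` and sets
#' `muAB - mu0 = (muA - mu0) + (muB - mu0) + beta3`, then reports the
#' global rejection probability of each design (analytic for factorial and
#' multi-arm, simulated for MAMS) and the trial sizes: fixed totals for the
#' single-stage designs, expected and maximum size for the MAMS design.
#' Designs are sized exactly as in [compare_designs()].
#'
#' @inheritParams compare_designs
#' @param beta3_grid Numeric grid of interaction strengths (response units).
#' @param mu_a,mu_b Single-treatment effects above control.
#' @return A data frame of class `"beta3_sweep"` with columns `beta3`,
#'   `design`, `global_power`, `n_total` (expected size for MAMS, with
#'   `n_max` alongside).
#' @export
beta3_sweep <- function(beta3_grid, mu_a = 0, mu_b = 0, delta, delta0, sigma,
                        alpha = 0.05, power = 0.9, nsim = 10000L, seed = 1L) {
  if (length(beta3_grid) == 0L)
    stop("'beta3_grid' must be non-empty", call. = FALSE)
  config <- list(command = "beta3-sweep", beta3_grid = beta3_grid,
                 mu_a = mu_a, mu_b = mu_b, delta = delta, delta0 = delta0,
                 sigma = sigma, alpha = alpha, power = power,
                 nsim = as.integer(nsim), seed = as.integer(seed))
  fac <- factorial_sample_size(balanced(),
                               scenario_suite("iii", delta, delta0, sigma),
                               alpha, power)
  ma <- ma_sample_size(balanced(),
                       scenario_suite("ii", delta, delta0, sigma),
                       alpha, power)
  mams <- mams_sample_size(alpha, power, delta, delta0, sigma)
  rows <- lapply(seq_along(beta3_grid), function(i) {
    b3 <- beta3_grid[i]
    scen <- effect_scenario(0, mu_a, mu_b, mu_a + mu_b + b3, sigma)
    pf <- factorial_power(fac$allocation, fac$n0, scen, alpha,
                          crit = fac$critical_value)
    pm <- ma_power(ma$allocation, ma$n0, scen, alpha, crit = ma$critical_value)
    oc <- empirical_rejection("mams2", scen, n0 = mams$n_per_stage,
                              alpha = alpha, nsim = nsim, seed = seed + i,
                              boundaries = mams$boundaries)
    en <- expected_sample_size(mams, scen, nsim = nsim, seed = seed + i)
    data.frame(beta3 = b3,
               design = c("factorial", "ma", "mams2"),
               global_power = c(pf, pm, oc$rate[oc$hypothesis == "global"]),
               n_total = c(fac$total, ma$total, en$expected_n),
               n_max = c(fac$total, ma$total, mams$max_total))
  })
  structure(do.call(rbind, rows), config = config,
            class = c("beta3_sweep", "data.frame"))
}

#' Re-run a reported computation from its resolved configuration
#'
#' Every result object carries the resolved configuration in
#' `attr(x, "config")`; feeding it back reproduces the result exactly
#' (same seed, same numbers).
#'
#' @param config A named list with a `command` element (`"compare"` or
#'   `"beta3-sweep"`) and that command's parameters.
#' @return The recomputed result object.
#' @export
run_config <- function(config) {
  if (!is.list(config) || is.null(config$command))
    stop("'config' must be a list with a 'command' element", call. = FALSE)
  args <- config[setdiff(names(config), "command")]
  switch(config$command,
         "compare" = do.call(compare_designs, args),
         "beta3-sweep" = {
           names(args)[names(args) == "beta3_grid"] <- "beta3_grid"
           do.call(beta3_sweep, args)
         },
         stop(sprintf("unknown command '%s'", config$command), call. = FALSE))
}

#' Write a result and its resolved configuration as JSON
#'
#' @param x A result object carrying a `config` attribute (for example from
#'   [compare_designs()]), or a plain list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_design_json <- function(x, path) {
  payload <- if (is.data.frame(x)) {
    list(config = attr(x, "config"), results = as.data.frame(x))
  } else if (is.list(x)) {
    list(config = attr(x, "config"), results = x)
  } else stop("'x' must be a data frame or list", call. = FALSE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
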