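#' Allocation ratios of a four-group design
#'
#' The two dimensionless ratios that fix the group sizes of a 2x2 factorial
#' or three-active-arm design relative to the control group: each single
#' treatment arm receives `r * n0` patients and the combination arm `q * n0`,
#' where `n0` is the control group size.
#'
#' @param r Ratio of each single-treatment group size to control (> 0).
#' @param q Ratio of the combination group size to control (> 0).
#'
#' @return An object of class `"allocation_ratios"`, a list with elements
#'   `r` and `q`.
#' @examples
#' allocation_ratios(1, 1)     # balanced design
#' allocation_ratios(2.5, 0.8) # allocation minimising the factorial critical value
#' @export
allocation_ratios <- function(r, q) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(q) || length(q) != 1L || !is.finite(q) || q <= 0)
    stop("'q' must be a single finite positive number", call. = FALSE)
  structure(list(r = as.numeric(r), q = as.numeric(q)),
            class = "allocation_ratios")
}

#' @export
print.allocation_ratios <- function(x, ...) {
  cat(sprintf("Allocation ratios: r = %g (single arms), q = %g (combination)\n",
              x$r, x$q))
  invisible(x)
}

# coerce numeric pair or object; internal
as_alloc <- function(alloc) {
  if (inherits(alloc, "allocation_ratios")) return(alloc)
  if (is.numeric(alloc) && length(alloc) == 2L)
    return(allocation_ratios(alloc[1L], alloc[2L]))
  stop("'alloc' must be an allocation_ratios object or a numeric pair (r, q)",
       call. = FALSE)
}

#' Effect scenario: the four group means and common standard deviation
#'
#' Describes one configuration of true group means for control, treatment A,
#' treatment B and the combination AB, with the common (known) standard
#' deviation of the normally distributed response.
#'
#' @param mu0,muA,muB,muAB True group means, in response units.
#' @param sigma Common standard deviation (> 0), in response units.
#' @param delta,delta0 Optional interesting / uninteresting effect sizes the
#'   scenario was built from (recorded for reporting; see [scenario_suite()]).
#'
#' @return An object of class `"effect_scenario"`.
#' @seealso [scenario_suite()] for the named preset configurations,
#'   [linear_model_effects()] for the interaction-model parametrisation.
#' @examples
#' effect_scenario(0, 0.5, 0.1, 0.6, sigma = 1)
#' @export
effect_scenario <- function(mu0, muA, muB, muAB, sigma,
                            delta = NA_real_, delta0 = NA_real_) {
  mus <- c(mu0, muA, muB, muAB)
  if (!is.numeric(mus) || length(mus) != 4L || any(!is.finite(mus)))
    stop("group means must be finite numbers", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  structure(list(mu0 = mu0, muA = muA, muB = muB, muAB = muAB,
                 sigma = sigma, delta = delta, delta0 = delta0),
            class = "effect_scenario")
}

#' @export
print.effect_scenario <- function(x, ...) {
  cat("Effect scenario (response units):\n")
  cat(sprintf("  mu0 = %g, muA = %g, muB = %g, muAB = %g, sigma = %g\n",
              x$mu0, x$muA, x$muB, x$muAB, x$sigma))
  invisible(x)
}

scenario_means <- function(scen) {
  stopifnot(inherits(scen, "effect_scenario"))
  c(mu0 = scen$mu0, muA = scen$muA, muB = scen$muB, muAB = scen$muAB)
}

#' Named alternative-hypothesis presets
#'
#' The five standard alternatives used to compare designs, expressed through
#' an interesting effect `delta` and a positive but uninteresting effect
#' `delta0` (both above the control mean `mu0`):
#'
#' * `"0"`   global null: all group means equal `mu0`;
#' * `"i"`   least favourable configuration on a single arm:
#'   `muA - mu0 = delta`, `muB - mu0 = muAB - mu0 = delta0` (the combination
#'   effect is antagonistic);
#' * `"ii"`  least favourable configuration on the combination:
#'   `muAB - mu0 = delta`, `muA - mu0 = muB - mu0 = delta0` (synergistic);
#' * `"iii"` additive, one strong arm: `muA - mu0 = delta`,
#'   `muB - mu0 = delta0`, `muAB - mu0 = delta + delta0`;
#' * `"iv"`  additive, both arms weak: `muA - mu0 = muB - mu0 = delta0`,
#'   `muAB - mu0 = 2 * delta0`.
#'
#' @param preset One of `"0"`, `"i"`, `"ii"`, `"iii"`, `"iv"`.
#' @param delta Interesting effect size (response units).
#' @param delta0 Uninteresting effect size (response units).
#' @param sigma Common standard deviation (> 0).
#' @param mu0 Control mean (default 0).
#'
#' @return An [effect_scenario()] object.
#' @examples
#' scenario_suite("iii", delta = 0.5, delta0 = 0.1, sigma = 1)
#' scenario_suite("iv", delta = 28, delta0 = 7, sigma = 50)
#' @export
scenario_suite <- function(preset, delta, delta0, sigma, mu0 = 0) {
  preset <- as.character(preset)
  eff <- switch(preset,
    "0"   = c(0, 0, 0),
    "i"   = c(delta, delta0, delta0),
    "ii"  = c(delta0, delta0, delta),
    "iii" = c(delta, delta0, delta + delta0),
    "iv"  = c(delta0, delta0, 2 * delta0),
    stop(sprintf("unknown scenario preset '%s' (use 0, i, ii, iii or iv)", preset),
         call. = FALSE))
  effect_scenario(mu0, mu0 + eff[1L], mu0 + eff[2L], mu0 + eff[3L], sigma,
                  delta = delta, delta0 = delta0)
}

#' Linear-model parametrisation of the treatment effects
#'
#' Coefficients of the full two-factor interaction model
#' `Y = beta0 + beta1 * I_A + beta2 * I_B + beta3 * I_A * I_B + eps`,
#' `eps ~ N(0, sigma^2)`.  The cell means are control `beta0`, A
#' `beta0 + beta1`, B `beta0 + beta2` and AB
#' `beta0 + beta1 + beta2 + beta3`.  `beta3` measures the interaction:
#' negative values are antagonistic, positive synergistic, zero is the
#' additivity assumption of the factorial analysis.
#'
#' @param beta0 Baseline (control) mean.
#' @param beta1,beta2 Main effects of treatments A and B.
#' @param beta3 Interaction between the treatments.
#' @param sigma Residual standard deviation (>= 0; zero gives a
#'   deterministic response, useful for checking the generator).
#'
#' @return An object of class `"linear_model_effects"`.
#' @examples
#' linear_model_effects(beta3 = -0.5, sigma = 1)  # antagonistic interaction
#' @export
linear_model_effects <- function(beta0 = 0, beta1 = 0, beta2 = 0, beta3 = 0,
                                 sigma = 1) {
  b <- c(beta0, beta1, beta2, beta3)
  if (!is.numeric(b) || length(b) != 4L || any(!is.finite(b)))
    stop("beta coefficients must be finite numbers", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma < 0)
    stop("'sigma' must be a single non-negative number", call. = FALSE)
  structure(list(beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 sigma = sigma),
            class = "linear_model_effects")
}

#' Cell means implied by linear-model coefficients
#'
#' @param effects A [linear_model_effects()] object.
#' @return Named numeric vector `c(mu0, muA, muB, muAB)`.
#' @export
cell_means <- function(effects) {
  stopifnot(inherits(effects, "linear_model_effects"))
  with(effects,
       c(mu0 = beta0, muA = beta0 + beta1, muB = beta0 + beta2,
         muAB = beta0 + beta1 + beta2 + beta3))
}

#' Convert linear-model effects to an effect scenario
#'
#' @param effects A [linear_model_effects()] object with `sigma > 0`.
#' @return An [effect_scenario()] object with the implied cell means.
#' @export
as_effect_scenario <- function(effects) {
  if (inherits(effects, "effect_scenario")) return(effects)
  stopifnot(inherits(effects, "linear_model_effects"))
  m <- cell_means(effects)
  effect_scenario(m[["mu0"]], m[["muA"]], m[["muB"]], m[["muAB"]], effects$sigma)
}

#' Per-group summary statistics of one trial
#'
#' Sample means and sizes of the four groups, together with the known
#' standard deviation, i.e. the sufficient statistics on which all test
#' statistics of the designs are based.
#'
#' @param means Named or positional numeric vector of the four sample means
#'   in the order control, A, B, AB.
#' @param sizes Integer vector of the four group sizes (each >= 1), same order.
#' @param sigma Known standard deviation (> 0).
#'
#' @return An object of class `"group_summary"`.
#' @seealso [simulate_groups()], [z_statistics()]
#' @export
group_summary <- function(means, sizes, sigma) {
  if (length(means) != 4L || any(!is.finite(means)))
    stop("'means' must be four finite numbers (control, A, B, AB)", call. = FALSE)
  if (length(sizes) != 4L || any(!is.finite(sizes)) || any(sizes < 1) ||
      any(sizes != round(sizes)))
    stop("'sizes' must be four positive integers (control, A, B, AB)", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  structure(list(means = stats::setNames(as.numeric(means), c("0", "A", "B", "AB")),
                 sizes = stats::setNames(as.integer(sizes), c("0", "A", "B", "AB")),
                 sigma = sigma),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("Group summary (control, A, B, AB):\n")
  cat("  n    :", paste(x$sizes, collapse = ", "), "\n")
  cat("  mean :", paste(signif(x$means, 5), collapse = ", "), "\n")
  cat("  sigma:", x$sigma, "(known)\n")
  invisible(x)
}
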