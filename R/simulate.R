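# Patient-level synthetic-data generator under the full interaction model,
# and empirical operating characteristics for all three designs.

#' Simulate one trial's patient-level responses
#'
#' Draws independent normal responses for the four groups under the full
#' interaction model: cell means control `beta0`, A `beta0+beta1`, B
#' `beta0+beta2`, AB `beta0+beta1+beta2+beta3`, residual standard deviation
#' `sigma` (an [effect_scenario()] is accepted too and used verbatim).
#' Returns the per-group sufficient statistics.
#'
#' @param effects A [linear_model_effects()] or [effect_scenario()] object.
#' @param sizes Integer vector of group sizes `(n0, nA, nB, nAB)`, each >= 1.
#' @param seed Integer seed; the same seed reproduces the same trial.  The
#'   caller's RNG state is left untouched.
#' @return A [group_summary()] with attribute `"seed"`.
#' @examples
#' eff <- linear_model_effects(beta1 = 0.5, beta2 = 0.1, sigma = 1)
#' simulate_groups(eff, sizes = c(40, 40, 40, 40), seed = 7)
#' @export
simulate_groups <- function(effects, sizes, seed) {
  mu <- if (inherits(effects, "effect_scenario")) scenario_means(effects)
        else cell_means(effects)
  sigma <- effects$sigma
  if (length(sizes) != 4L || any(sizes < 1) || any(sizes != round(sizes)))
    stop("'sizes' must be four positive integers (n0, nA, nB, nAB)",
         call. = FALSE)
  if (missing(seed) || !is.finite(seed))
    stop("a seed must be provided", call. = FALSE)
  means <- with_preserved_seed({
    set.seed(as.integer(seed))
    vapply(seq_len(4L), function(j) {
      if (sigma == 0) mu[[j]] else mean(stats::rnorm(sizes[j], mu[[j]], sigma))
    }, numeric(1))
  })
  gs <- group_summary(means, sizes, if (sigma > 0) sigma else 1)
  if (sigma == 0) gs$sigma <- 0  # deterministic check mode
  attr(gs, "seed") <- as.integer(seed)
  gs
}

#' Empirical rejection frequencies of a design
#'
#' Simulates `nsim` complete trials at patient level under the given
#' effects and estimates, for each null hypothesis and globally, the
#' probability of rejection:
#'
#' * `"factorial"` / `"ma"`: `Z_j > k` with the single
#'   familywise-calibrated critical value `k` for all three comparisons;
#' * `"mams2"`: the two-stage rule (cross `u1` at the interim, or survive
#'   the futility bound in a trial that continues and cross `u2` on the
#'   cumulative statistic; surviving arms' stage-2 statistics use all their
#'   data and all control data).  Requires `r = q = 1`; `n0` is the
#'   per-arm per-stage size.  For the combination arm the frequency of
#'   being rejected *and best at its stage* is also reported (row
#'   `AB_selected`), the event whose probability [mams_power()] computes.
#'
#' @param design `"factorial"`, `"ma"` or `"mams2"`.
#' @param effects A [linear_model_effects()] or [effect_scenario()].
#' @param n0 Control group size (per stage, for `"mams2"`).
#' @param alloc [allocation_ratios()]; group sizes are `round(r*n0)` and
#'   `round(q*n0)`.
#' @param alpha One-sided familywise error rate.
#' @param nsim Number of simulated trials.
#' @param seed Integer seed, recorded in the output.
#' @param crit Optional pre-computed critical value (factorial / ma).
#' @param boundaries Optional pre-calibrated [stage_boundaries()] (mams2).
#' @return An object of class `"operating_characteristics"`: a data frame
#'   with columns `hypothesis`, `rate`, `se` plus attributes `nsim`,
#'   `seed` and the resolved `config`.
#' @examples
#' \donttest{
#' eff <- linear_model_effects(beta3 = 0.5, sigma = 1)  # synergy, nulls true
#' empirical_rejection("factorial", eff, n0 = 50, nsim = 2000, seed = 1)
#' }
#' @export
empirical_rejection <- function(design = c("factorial", "ma", "mams2"),
                                effects, n0,
                                alloc = allocation_ratios(1, 1),
                                alpha = 0.05, nsim = 10000L, seed = 1L,
                                crit = NULL, boundaries = NULL) {
  design <- match.arg(design)
  alloc <- as_alloc(alloc)
  if (!is.numeric(nsim) || nsim < 1)
    stop("'nsim' must be a positive integer", call. = FALSE)
  nsim <- as.integer(nsim)
  mu <- if (inherits(effects, "effect_scenario")) scenario_means(effects)
        else cell_means(effects)
  sigma <- effects$sigma
  if (sigma <= 0) stop("'sigma' must be positive for simulation", call. = FALSE)

  if (design == "mams2") {
    if (abs(alloc$r - 1) > 1e-9 || abs(alloc$q - 1) > 1e-9)
      stop("the two-stage design assumes equal allocation r = q = 1",
           call. = FALSE)
    if (is.null(boundaries)) boundaries <- obf_boundaries(alpha)
    rej <- with_preserved_seed({
      set.seed(as.integer(seed))
      n <- as.integer(round(n0))
      m1 <- sim_stage_means(mu, n, sigma, nsim)
      m2 <- sim_stage_means(mu, n, sigma, nsim)
      z1 <- sweep(m1[, -1L, drop = FALSE], 1L, m1[, 1L]) * sqrt(n / 2) / sigma
      mc <- (m1 + m2) / 2
      z2 <- sweep(mc[, -1L, drop = FALSE], 1L, mc[, 1L]) * sqrt(n) / sigma
      stop_eff <- z1 > boundaries$u1
      any_stop <- rowSums(stop_eff) > 0L
      surv <- z1 >= boundaries$l1
      rej <- matrix(FALSE, nsim, 3L, dimnames = list(NULL, arm_names))
      rej[any_stop, ] <- stop_eff[any_stop, , drop = FALSE]
      cont <- !any_stop
      rej[cont, ] <- (surv & z2 > boundaries$u2)[cont, , drop = FALSE]
      # combination rejected while best at its stage (the power event)
      z2s <- z2; z2s[!surv] <- -Inf
      sel <- (any_stop & stop_eff[, 3L] & z1[, 3L] >= pmax(z1[, 1L], z1[, 2L])) |
        (cont & surv[, 3L] & z2[, 3L] > boundaries$u2 &
           z2[, 3L] >= pmax(z2s[, 1L], z2s[, 2L]))
      cbind(rej, AB_selected = sel)
    })
    k_or_b <- boundaries
  } else {
    sizes <- c(n0, round(alloc$r * n0), round(alloc$r * n0),
               round(alloc$q * n0))
    if (any(sizes < 1)) stop("allocation yields an empty group", call. = FALSE)
    if (is.null(crit)) {
      crit <- if (design == "factorial") factorial_critical_value(alloc, alpha)
              else ma_critical_value(alloc, alpha)
    }
    rej <- with_preserved_seed({
      set.seed(as.integer(seed))
      ybar <- vapply(seq_len(4L), function(j)
        rowMeans(matrix(stats::rnorm(nsim * sizes[j], mu[[j]], sigma),
                        nrow = nsim)), numeric(nsim))
      if (nsim == 1L) ybar <- matrix(ybar, nrow = 1L)
      z <- if (design == "factorial")
        z_stat_matrix(ybar, sizes, sigma)
      else sweep(ybar[, -1L, drop = FALSE], 1L, ybar[, 1L]) *
        rep(sqrt(sizes[1] * sizes[-1] / (sizes[1] + sizes[-1])), each = nsim) /
        sigma
      colnames(z) <- arm_names
      z > crit
    })
    k_or_b <- crit
  }

  glob <- rowSums(rej[, arm_names, drop = FALSE]) > 0L
  tab <- rbind(
    data.frame(hypothesis = colnames(rej), rate = colMeans(rej)),
    data.frame(hypothesis = "global", rate = mean(glob)))
  tab$se <- sqrt(tab$rate * (1 - tab$rate) / nsim)
  rownames(tab) <- NULL
  structure(tab,
            nsim = nsim, seed = as.integer(seed),
            config = list(design = design, mu = as.list(mu), sigma = sigma,
                          n0 = n0, r = alloc$r, q = alloc$q, alpha = alpha,
                          nsim = nsim, seed = as.integer(seed)),
            calibration = k_or_b,
            class = c("operating_characteristics", "data.frame"))
}

# vectorised factorial statistics over nsim rows of group means
z_stat_matrix <- function(ybar, sizes, sigma) {
  n0 <- sizes[1]
  r <- sizes[2] / n0; q <- sizes[4] / n0
  den <- sigma * sqrt((1 + r) * (r + q) * (r^2 + 2 * r * q + r^2 * q))
  zA <- sqrt(n0) * (r * (r + q) * (ybar[, 2L] - ybar[, 1L]) +
                      q * r * (1 + r) * (ybar[, 4L] - ybar[, 3L])) / den
  zB <- sqrt(n0) * (r * (r + q) * (ybar[, 3L] - ybar[, 1L]) +
                      q * r * (1 + r) * (ybar[, 4L] - ybar[, 2L])) / den
  zAB <- sqrt(n0) * (ybar[, 4L] - ybar[, 1L]) / (sigma * sqrt((1 + q) / q))
  cbind(zA, zB, zAB)
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("Empirical operating characteristics: %s design, %d simulations, seed %d\n",
              cfg$design, attr(x, "nsim"), attr(x, "seed")))
  df <- as.data.frame(x)
  df$rate <- sprintf("%.4f", df$rate)
  df$se <- sprintf("%.4f", df$se)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write operating characteristics as CSV
#'
#' Columns: design, hypothesis, rate, se, nsim, seed.
#'
#' @param oc An `"operating_characteristics"` object (or a list of them).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_oc_csv <- function(oc, path) {
  if (inherits(oc, "operating_characteristics")) oc <- list(oc)
  rows <- do.call(rbind, lapply(oc, function(x) {
    cfg <- attr(x, "config")
    data.frame(design = cfg$design, hypothesis = x$hypothesis,
               rate = x$rate, se = x$se,
               nsim = attr(x, "nsim"), seed = attr(x, "seed"))
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}
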