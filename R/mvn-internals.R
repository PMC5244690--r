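# Numerical primitives shared by the design calculations.

# Fixed internal seed for the quasi-Monte-Carlo multivariate-normal
# integration: probabilities must be reproducible to ~1e-7 so that critical
# values solved from them are stable to the third decimal.  The caller's RNG
# state is saved and restored around every call.
.QMC_SEED <- 20160712L

with_preserved_seed <- function(code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  force(code)
}

# P(Z1 <= upper[1], Z2 <= upper[2], Z3 <= upper[3]) for MVN(mean, corr).
# Genz-Bretz quasi-random integration with a fixed seed: deterministic,
# absolute tolerance ~1e-7, and (unlike Miwa quadrature) valid for the
# singular correlation matrices that arise along q = 1 (balanced design
# included), where Z_AB is a linear combination of Z_A and Z_B.
tvn_lower <- function(upper, mean, corr) {
  with_preserved_seed({
    set.seed(.QMC_SEED)
    p <- mvtnorm::pmvnorm(lower = rep(-Inf, 3L), upper = upper, mean = mean,
                          corr = corr,
                          algorithm = mvtnorm::GenzBretz(maxpts = 2e6,
                                                         abseps = 1e-7))
    as.numeric(p)
  })
}

# Bivariate standard normal CDF P(X <= h, Y <= k) at correlation rho,
# vectorised over (h, k).  Drezner-Wesolowsky one-dimensional reduction
#   Phi2(h,k;rho) = Phi(h)Phi(k)
#                   + (2*pi)^-1 int_0^asin(rho) exp(-(h^2-2hk sin t+k^2)
#                                                   /(2 cos^2 t)) dt,
# integrated with 24-point Gauss-Legendre (exact to ~1e-14 for |rho|<0.925;
# the package only ever uses rho = 1/sqrt(2), the between-stage correlation
# of equally sized stages).  Vectorisation is what makes the two-stage
# double integrals cheap: mvtnorm evaluates one probability per call.
pbvn <- function(h, k, rho) {
  n <- max(length(h), length(k))
  h <- rep_len(h, n)
  k <- rep_len(k, n)
  if (abs(rho) < .Machine$double.eps)
    return(stats::pnorm(h) * stats::pnorm(k))
  stopifnot(abs(rho) < 0.925)
  gl <- gauss_legendre_rule(24L, 0, asin(rho))
  acc <- 0
  for (i in seq_along(gl$x)) {
    sn <- sin(gl$x[i])
    acc <- acc + gl$w[i] * exp(-(h^2 - 2 * sn * h * k + k^2) / (2 * (1 - sn^2)))
  }
  stats::pnorm(h) * stats::pnorm(k) + acc / (2 * pi)
}

# cached quadrature rules -----------------------------------------------

.quad_cache <- new.env(parent = emptyenv())

# nodes/weights for integrals against the standard normal density:
# int f(t) dPhi(t) ~ sum(w * f(x))
gauss_hermite_prob <- function(n = 80L) {
  key <- paste0("gh", n)
  if (is.null(.quad_cache[[key]])) {
    gh <- pracma::gaussHermite(n)
    .quad_cache[[key]] <- list(x = gh$x * sqrt(2), w = gh$w / sqrt(pi))
  }
  .quad_cache[[key]]
}

gauss_legendre_rule <- function(n, a, b) {
  key <- sprintf("gl%d_%.15g_%.15g", n, a, b)
  if (is.null(.quad_cache[[key]]))
    .quad_cache[[key]] <- pracma::gaussLegendre(n, a, b)
  .quad_cache[[key]]
}
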