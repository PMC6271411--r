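# Independent oracles and fixture builders shared across tests.

R_KCAL <- 1.987e-3
R_CAL <- 1.987
T37 <- 310.15

# bisection root of K*Ct*(1-f)^2 = 2f on [0, 1] -- independent of the
# closed-form quadratic used by the package
bisect_fraction <- function(K, Ct, tol = 1e-14) {
  g <- function(f) K * Ct * (1 - f)^2 - 2 * f
  gp <- function(f) -2 * K * Ct * (1 - f) - 2
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  f <- (lo + hi) / 2
  # Newton polish so the oracle is accurate in RELATIVE terms even for tiny f
  for (i in 1:20) f <- f - g(f) / gp(f)
  f
}

# bisection solve of f(T) = 1/2 -- independent of the closed-form Tm
bisect_tm <- function(dH, dS, Ct, lo = 200, hi = 450, tol = 1e-6) {
  frac <- function(T) {
    K <- exp(-(dH - T * dS / 1000) / (R_KCAL * T))
    x <- K * Ct
    2 * x / ((2 * x + 2) + sqrt((2 * x + 2)^2 - 4 * x^2))
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (frac(mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# default generator configuration used by fitting tests
default_cfg <- function(seed, dH = -92, dS = -258, noise_sd = 0.002, ...) {
  sim_config(dH = dH, dS = dS, noise_sd = noise_sd, seed = seed, ...)
}
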