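test_that("two-state fit recovers truth on noiseless curves", {
  cfg <- default_cfg(seed = 1, dH = -92, dS = -258, noise_sd = 0)
  fit <- fit_two_state(generate_melting_curve(cfg, 1e-5, noise = FALSE))
  expect_true(fit$converged)
  expect_lt(abs(fit$params$dH - (-92)) / 92, 0.001)
  expect_lt(abs(fit$params$dS - (-258)) / 258, 0.001)
  expect_lt(abs(fit$params$dH - (-92)), 0.1)
  # recovered baselines
  expect_equal(unname(fit$baselines["b_ds"]), 0.60, tolerance = 1e-3)
  expect_equal(unname(fit$baselines["b_ss"]), 0.75, tolerance = 1e-3)
  # Tm consistency invariant with the closed form at this Ct
  expect_lt(abs(fit$Tm - melting_temperature(fit$params$dH, fit$params$dS,
                                             fit$Ct)), 0.01)
})

test_that("two-state fit SSE beats a coarse grid search around truth", {
  cfg <- default_cfg(seed = 21, noise_sd = 0.002)
  set.seed(cfg$seed)
  crv <- generate_melting_curve(cfg, 1e-5)
  fit <- fit_two_state(crv)
  expect_true(fit$converged)
  sse_model <- function(dH, Tm) {
    dS <- 1000 * dH / Tm - R_CAL * log(crv$Ct / 4)
    T_K <- crv$temperature_C + 273.15
    K <- exp(-(dH - T_K * dS / 1000) / (R_KCAL * T_K))
    x <- K * crv$Ct
    f <- 2 * x / ((2 * x + 2) + sqrt((2 * x + 2)^2 - 4 * x^2))
    A <- f * (0.60 + 2e-4 * crv$temperature_C) +
      (1 - f) * (0.75 + 3e-4 * crv$temperature_C)
    sum((crv$absorbance - A)^2)
  }
  tm_true <- melting_temperature(-92, -258, 1e-5)
  grid <- expand.grid(dH = seq(-100, -84, by = 2),
                      Tm = tm_true + seq(-1, 1, by = 0.25))
  best <- min(mapply(sse_model, grid$dH, grid$Tm))
  expect_lte(fit$sse, best + 1e-12)
})

test_that("degenerate curves are rejected with a no-transition error", {
  Tc <- seq(0, 95, by = 0.5)
  flat <- melting_curve(Tc, rep(0.7, length(Tc)), Ct = 1e-5)
  expect_error(fit_two_state(flat), "transition")
  # monotone baseline-only ramp has no interior derivative maximum
  ramp <- melting_curve(Tc, 0.6 + 1e-3 * Tc, Ct = 1e-5)
  expect_error(tm_from_derivative(ramp), "interior")
  short <- melting_curve(seq(40, 48, 0.5), rnorm(17, 0.7, 0.001), Ct = 1e-5)
  expect_error(fit_two_state(short), "20 points")
})

test_that("derivative Tm matches the steepest-point oracle and is shift invariant", {
  cfg <- default_cfg(seed = 2, noise_sd = 0,
                     baselines = c(b_ds = 0.60, m_ds = 0, b_ss = 0.75, m_ss = 0))
  crv <- generate_melting_curve(cfg, 1e-5, noise = FALSE)
  tm_d <- tm_from_derivative(crv)
  # independent oracle: steepest point of f(T) on a fine grid
  T_K <- seq(310, 340, by = 1e-3)
  f <- duplex_fraction(
    equilibrium_constant(gibbs_free_energy(-92, -258, T_K), T_K), 1e-5)
  oracle <- T_K[which.min(diff(f) / diff(T_K))]
  expect_lt(abs(tm_d - oracle), 0.5)
  # the steepest point of a bimolecular transition sits ~1 K above Tm
  tm_cf <- melting_temperature(-92, -258, 1e-5)
  expect_lt(abs(tm_d - tm_cf), 1.5)
  expect_gt(tm_d, tm_cf)
  # invariant to adding a constant to all absorbances
  shifted <- melting_curve(crv$temperature_C, crv$absorbance + 0.3, Ct = 1e-5)
  expect_equal(tm_from_derivative(shifted), tm_d)
})

test_that("noisy fits recover the enthalpy within 5% in the median", {
  errs <- sapply(1:15, function(s) {
    cfg <- default_cfg(seed = 100 + s, noise_sd = 0.002)
    set.seed(cfg$seed)
    fit <- fit_two_state(generate_melting_curve(cfg, 1e-5))
    if (!fit$converged) return(NA_real_)
    abs(fit$params$dH - (-92)) / 92
  })
  expect_lt(median(errs, na.rm = TRUE), 0.05)
})

test_that("van't Hoff regression is an exact inverse on perfect points", {
  ct <- c(1e-6, 5e-6, 1e-5, 5e-5, 1e-4)
  tm <- sapply(ct, function(c) melting_temperature(-90, -250, c))
  vh <- vant_hoff_regression(data.frame(Ct = ct, Tm = tm))
  expect_equal(vh$params$dH, -90, tolerance = 1e-9)
  expect_equal(vh$params$dS, -250, tolerance = 1e-9)
  expect_equal(vh$r_squared, 1, tolerance = 1e-12)
  # internal consistency invariants of the result object
  expect_equal(vh$params$dH, log(10) * R_KCAL / vh$slope, tolerance = 1e-9)
  expect_equal(vh$params$dS, 1000 * vh$intercept * vh$params$dH,
               tolerance = 1e-9)
  expect_error(vant_hoff_regression(data.frame(Ct = c(1e-5, 1e-5, 1e-5),
                                               Tm = tm[1:3])), "3 distinct")
  expect_warning(vant_hoff_regression(data.frame(Ct = ct[1:3],
                                                 Tm = rev(tm[1:3]))),
                 "non-negative")
})

test_that("van't Hoff estimate tolerates Tm jitter", {
  ct <- 10^seq(-6, -4, length.out = 5)
  tm0 <- sapply(ct, function(c) melting_temperature(-90, -250, c))
  set.seed(9)
  errs <- replicate(40, {
    vh <- vant_hoff_regression(data.frame(Ct = ct, Tm = tm0 + rnorm(5, 0, 0.2)))
    abs(vh$params$dH - (-90)) / 90
  })
  expect_lt(median(errs), 0.10)
})

test_that("consolidation averages the two estimates and flags disagreement", {
  cfg <- default_cfg(seed = 4, noise_sd = 0)
  curves <- generate_ct_series(cfg, noise = FALSE)
  fits <- lapply(curves, fit_two_state)
  vh <- vant_hoff_regression(data.frame(
    Ct = sapply(fits, `[[`, "Ct"), Tm = sapply(fits, `[[`, "Tm")))
  cons <- consolidate_parameters(fits, vh)
  # identical sources: output equals input, flag true (idempotence)
  expect_true(cons$two_state_flag)
  expect_equal(cons$params$dH, -92, tolerance = 0.01)
  expect_equal(cons$params$dH,
               mean(c(cons$curve_fit_params$dH, cons$vant_hoff_params$dH)))
  # a 33% dH discrepancy trips the flag
  vh_bad <- vh
  vh_bad$params <- thermo_params(-120, vh$params$dS)
  cons_bad <- consolidate_parameters(fits, vh_bad)
  expect_false(cons_bad$two_state_flag)
  # non-converged fits are never averaged in
  dud <- fits[[1]]
  dud$converged <- FALSE
  dud$params <- thermo_params(-500, -1500)
  cons2 <- consolidate_parameters(c(fits, list(dud)), vh)
  expect_equal(cons2$params$dH, cons$params$dH)
  expect_error(consolidate_parameters(list(dud), vh), "converged")
})
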