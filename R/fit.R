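#' Melting temperature from the smoothed absorbance derivative
#'
#' Locates the maximum of dA/dT after smoothing with a centered 5-point
#' moving average.  This model-free estimate serves (i) as the midpoint
#' temperature for long duplexes whose transitions are not analysed
#' thermodynamically, and (ii) as the initial `Tm` for the nonlinear fit.
#' Ties are broken towards the lowest temperature; a maximum on the grid
#' boundary (e.g. a baseline-only, transition-free series) is an error.
#'
#' @param curve A [melting_curve()] with at least 20 points.
#' @return Temperature of maximum dA/dT, Kelvin.
#' @export
tm_from_derivative <- function(curve) {
  stopifnot(inherits(curve, "melting_curve"))
  Tc <- curve$temperature_C
  A <- curve$absorbance
  if (length(Tc) < 20) {
    stop("at least 20 points are required", call. = FALSE)
  }
  dAdT <- diff(A) / diff(Tc)
  Tmid <- (Tc[-1] + Tc[-length(Tc)]) / 2
  sm <- as.numeric(stats::filter(dAdT, rep(1 / 5, 5), sides = 2))
  ok <- which(!is.na(sm))
  imax <- ok[which.max(sm[ok])]  # which.max takes the first (lowest T) tie
  rng <- diff(range(sm[ok]))
  prominence <- sm[imax] - max(sm[ok[1]], sm[ok[length(ok)]])
  if (imax == ok[1] || imax == ok[length(ok)] ||
      rng <= 1e-6 * max(abs(sm[ok])) ||  # constant derivative: baseline only
      prominence < 0.1 * rng) {
    stop("no interior maximum in dA/dT: no melting transition detected",
         call. = FALSE)
  }
  Tmid[imax] + C_TO_K
}

# model absorbance parameterised by (dH, Tm); dS is derived from the closed
# form so that Tm is an actual fit parameter (decorrelates dH and dS)
two_state_model_abs <- function(T_C, dH, Tm, b_ds, m_ds, b_ss, m_ss, Ct) {
  dS <- 1000 * dH / Tm - RGAS_CAL * log(Ct / 4)
  f <- two_state_fraction(T_C + C_TO_K, dH, dS, Ct)
  f * (b_ds + m_ds * T_C) + (1 - f) * (b_ss + m_ss * T_C)
}

# linear fit to the lowest/highest `frac` of the temperature range
edge_baseline <- function(Tc, A, frac = 0.15, upper = FALSE) {
  rng <- range(Tc)
  cut <- if (upper) rng[2] - frac * diff(rng) else rng[1] + frac * diff(rng)
  sel <- if (upper) Tc >= cut else Tc <= cut
  fit <- lm(A[sel] ~ Tc[sel])
  unname(coef(fit))
}

#' Fit a two-state transition to a melting curve
#'
#' Nonlinear least squares (Levenberg-Marquardt) fit of the six-parameter
#' two-state model: thermodynamics `(dH, Tm)` — the entropy is derived from
#' the closed-form melting temperature relation — plus linear duplex and
#' single-strand baselines.  Initial values: `Tm` from
#' [tm_from_derivative()], `dH = -80` kcal/mol, baselines from linear fits
#' to the lowest and highest 15% of the temperature range.
#'
#' Convergence trouble is reported through the `converged` flag rather than
#' an error, so batch pipelines continue; a curve with no detectable
#' transition (absorbance range under 3x a robust noise estimate, or no
#' interior derivative maximum) is an error.
#'
#' @param curve A [melting_curve()] with >= 20 points.
#' @param dH_init Initial enthalpy, kcal/mol.
#' @param max_iter Iteration cap for the optimiser.
#' @param ftol Relative SSE convergence tolerance.
#' @return An object of class `two_state_fit`: list with `params`
#'   ([thermo_params()]), `baselines` (b_ds, m_ds, b_ss, m_ss), `Tm` (K),
#'   `sse`, `converged`, `n_iter` and `Ct`.
#' @export
#' @examples
#' cfg <- sim_config(dH = -92, dS = -258, noise_sd = 0, seed = 1)
#' fit <- fit_two_state(generate_melting_curve(cfg, 1e-5, noise = FALSE))
#' fit$params$dH  # recovers -92
fit_two_state <- function(curve, dH_init = -80, max_iter = 500, ftol = 1e-10) {
  stopifnot(inherits(curve, "melting_curve"))
  Tc <- curve$temperature_C
  A <- curve$absorbance
  Ct <- curve$Ct
  if (length(Tc) < 20) stop("at least 20 points are required", call. = FALSE)

  noise_est <- mad(diff(A)) / sqrt(2)
  if (diff(range(A)) <= 3 * noise_est || diff(range(A)) == 0) {
    stop("no melting transition detected (absorbance range within noise)",
         call. = FALSE)
  }
  Tm0 <- tryCatch(tm_from_derivative(curve), error = function(e) {
    stop("no melting transition detected: ", conditionMessage(e), call. = FALSE)
  })
  lo <- edge_baseline(Tc, A, upper = FALSE)
  hi <- edge_baseline(Tc, A, upper = TRUE)
  start <- list(dH = dH_init, Tm = Tm0, b_ds = lo[1], m_ds = lo[2],
                b_ss = hi[1], m_ss = hi[2])

  fit <- tryCatch(
    nlsLM(A ~ two_state_model_abs(Tc, dH, Tm, b_ds, m_ds, b_ss, m_ss, Ct),
          start = start,
          lower = c(dH = -400, Tm = min(Tc) + C_TO_K - 20,
                    b_ds = -Inf, m_ds = -Inf, b_ss = -Inf, m_ss = -Inf),
          upper = c(dH = -5, Tm = max(Tc) + C_TO_K + 20,
                    b_ds = Inf, m_ds = Inf, b_ss = Inf, m_ss = Inf),
          control = nls.lm.control(maxiter = max_iter, ftol = ftol)),
    error = function(e) NULL
  )

  if (is.null(fit)) {
    res <- list(params = NULL, baselines = NULL, Tm = NA_real_,
                sse = NA_real_, converged = FALSE, n_iter = NA_integer_,
                Ct = Ct, label = curve$label)
    class(res) <- "two_state_fit"
    return(res)
  }

  cf <- coef(fit)
  dH <- unname(cf["dH"]); Tm <- unname(cf["Tm"])
  dS <- 1000 * dH / Tm - RGAS_CAL * log(Ct / 4)
  res <- list(
    params = thermo_params(dH, dS),
    baselines = c(b_ds = unname(cf["b_ds"]), m_ds = unname(cf["m_ds"]),
                  b_ss = unname(cf["b_ss"]), m_ss = unname(cf["m_ss"])),
    Tm = Tm,
    sse = sum(residuals(fit)^2),
    converged = isTRUE(fit$convInfo$isConv),
    n_iter = fit$convInfo$finIter,
    Ct = Ct,
    label = curve$label
  )
  class(res) <- "two_state_fit"
  res
}

#' @export
print.two_state_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) cat("Two-state fit: NOT CONVERGED\n")
  if (!is.null(x$params)) {
    cat(sprintf("Two-state fit (Ct = %.3g M): dH = %.2f kcal/mol, dS = %.1f cal/(mol K), Tm = %.2f K, SSE = %.3g\n",
                x$Ct, x$params$dH, x$params$dS, x$Tm, x$sse))
  }
  invisible(x)
}

#' van't Hoff regression of 1/Tm on log10(Ct/4)
#'
#' For a non-self-complementary duplex, `1/Tm` is linear in `log10(Ct/4)`
#' with slope `2.303 R / dH` (R in kcal units, 2.303 = ln 10 carried at
#' full precision) and intercept `dS / (1000 dH)`; ordinary least squares
#' on melting temperatures measured at several strand concentrations
#' therefore recovers `dH` and `dS`.  For a duplex with `dH < 0` the slope
#' is negative; a non-negative slope implies `dH >= 0` and is flagged with
#' a warning.
#'
#' @param points Data frame with columns `Ct` (total strand concentration,
#'   M) and `Tm` (K); at least 3 distinct concentrations.
#' @return An object of class `vant_hoff_fit`: list with `params`
#'   ([thermo_params()]), `slope` (1/K per log10 unit), `intercept` (1/K),
#'   `r_squared` and `n_points`.
#' @export
#' @examples
#' ct <- c(1e-6, 1e-5, 1e-4)
#' tm <- sapply(ct, function(c) melting_temperature(-90, -250, c))
#' vant_hoff_regression(data.frame(Ct = ct, Tm = tm))$params$dH  # -90
vant_hoff_regression <- function(points) {
  stopifnot(is.data.frame(points), all(c("Ct", "Tm") %in% names(points)))
  pts <- points[!duplicated(points$Ct), , drop = FALSE]
  if (length(unique(pts$Ct)) < 3) {
    stop("at least 3 distinct strand concentrations are required", call. = FALSE)
  }
  x <- log10(pts$Ct / 4)
  y <- 1 / pts$Tm
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  if (slope >= 0) {
    warning("non-negative van't Hoff slope implies dH >= 0; estimates are suspect",
            call. = FALSE)
  }
  dH <- log(10) * RGAS_KCAL / slope
  dS <- 1000 * intercept * dH
  # summary.lm warns on numerically perfect fits (noiseless input); benign
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(params = thermo_params(dH, dS), slope = slope,
         intercept = intercept, r_squared = r2, n_points = nrow(pts)),
    class = "vant_hoff_fit"
  )
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff (1/Tm vs log10(Ct/4), n = %d, r2 = %.4f): dH = %.2f kcal/mol, dS = %.1f cal/(mol K)\n",
              x$n_points, x$r_squared, x$params$dH, x$params$dS))
  invisible(x)
}

#' Consolidate curve-fit and van't Hoff parameter estimates
#'
#' Averages the per-curve fit parameters (converged fits only), then takes
#' the unweighted mean of that average and the van't Hoff estimate — dH and
#' dS are averaged and dG37 recomputed from the averages.  Agreement of the
#' two independent dH estimates (relative difference within
#' `dh_agreement_tol` of their mean) is the operational indicator of
#' two-state melting behaviour.
#'
#' @param fits List of [fit_two_state()] results; non-converged fits are
#'   excluded, and at least one converged fit is required.
#' @param vh A [vant_hoff_regression()] result.
#' @param dh_agreement_tol Relative dH agreement threshold for the
#'   two-state flag (default 0.15).
#' @return An object of class `consolidated_params`: list with `params`
#'   (averaged [thermo_params()]), `curve_fit_params`, `vant_hoff_params`,
#'   `two_state_flag`, `n_curves`.
#' @export
consolidate_parameters <- function(fits, vh, dh_agreement_tol = 0.15) {
  if (inherits(fits, "two_state_fit")) fits <- list(fits)
  stopifnot(inherits(vh, "vant_hoff_fit"))
  conv <- Filter(function(f) isTRUE(f$converged), fits)
  if (length(conv) == 0) {
    stop("no converged curve fits to consolidate", call. = FALSE)
  }
  dH_fit <- mean(vapply(conv, function(f) f$params$dH, numeric(1)))
  dS_fit <- mean(vapply(conv, function(f) f$params$dS, numeric(1)))
  cf <- thermo_params(dH_fit, dS_fit)
  dH_vh <- vh$params$dH
  flag <- abs(dH_fit - dH_vh) / abs(mean(c(dH_fit, dH_vh))) <= dh_agreement_tol
  avg <- thermo_params(mean(c(dH_fit, dH_vh)),
                       mean(c(dS_fit, vh$params$dS)))
  structure(
    list(params = avg, curve_fit_params = cf, vant_hoff_params = vh$params,
         two_state_flag = flag, n_curves = length(conv)),
    class = "consolidated_params"
  )
}

#' @export
print.consolidated_params <- function(x, ...) {
  cat(sprintf("Consolidated over %d curve fits + van't Hoff (two-state: %s):\n",
              x$n_curves, ifelse(x$two_state_flag, "yes", "NO")))
  print(x$params)
  invisible(x)
}
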