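#' Salt-dependence series of duplex stability
#'
#' Points of duplex stability — either `-dG37` (kcal/mol) or `1/Tm` (1/K) —
#' measured at several salt concentrations under one solution condition.
#'
#' @param conc_M Positive, distinct salt concentrations, M.
#' @param value Stability values, same length.
#' @param value_kind `"minus_dG37"` or `"inv_Tm"`.
#' @param species `"Na"` or `"Mg"`.
#' @param solvent_tag Free text, e.g. `"aqueous"` or `"ethanol-3M"`.
#' @return An object of class `salt_series`.
#' @export
salt_series <- function(conc_M, value,
                        value_kind = c("minus_dG37", "inv_Tm"),
                        species = c("Na", "Mg"), solvent_tag = "aqueous") {
  value_kind <- match.arg(value_kind)
  species <- match.arg(species)
  stopifnot(is.numeric(conc_M), is.numeric(value),
            length(conc_M) == length(value))
  if (any(conc_M <= 0)) stop("salt concentrations must be positive", call. = FALSE)
  if (anyDuplicated(conc_M)) stop("salt concentrations must be distinct", call. = FALSE)
  structure(
    list(conc_M = conc_M, value = value, value_kind = value_kind,
         species = species, solvent_tag = solvent_tag),
    class = "salt_series"
  )
}

#' Regress duplex stability on log10 of the salt concentration
#'
#' Unweighted ordinary least squares of the stability value on
#' `log10([M])`.  The intercept is the value extrapolated to 1 M salt
#' (`log10[M] = 0`); for a `-dG37` series the slope (kcal/mol per decade)
#' is the quantity converted to a counterion-uptake number by
#' [ion_uptake_from_dg()].
#'
#' @param series A [salt_series()] with at least 3 points.
#' @return An object of class `salt_slope`: list with `slope`, `stderr`
#'   (standard error of the slope), `intercept` (extrapolated 1 M value),
#'   `r_squared`, `value_kind`, `species`, `solvent_tag`, `n_points`.
#' @export
#' @examples
#' s <- salt_series(c(0.03, 0.1, 0.3, 1), 12.5 + 3.91 * log10(c(0.03, 0.1, 0.3, 1)))
#' fit_salt_slope(s)$slope  # 3.91
fit_salt_slope <- function(series) {
  stopifnot(inherits(series, "salt_series"))
  if (length(series$conc_M) < 3) {
    stop("at least 3 salt concentrations are required", call. = FALSE)
  }
  x <- log10(series$conc_M)
  if (diff(range(x)) == 0) {
    stop("zero variance in log10 concentration", call. = FALSE)
  }
  fit <- lm(series$value ~ x)
  sm <- suppressWarnings(summary(fit))  # warns on numerically perfect fits
  structure(
    list(slope = unname(coef(fit)[2]),
         stderr = sm$coefficients[2, 2],
         intercept = unname(coef(fit)[1]),
         r_squared = sm$r.squared,
         value_kind = series$value_kind,
         species = series$species,
         solvent_tag = series$solvent_tag,
         n_points = length(series$conc_M)),
    class = "salt_slope"
  )
}

#' @export
print.salt_slope <- function(x, ...) {
  cat(sprintf("Salt dependence (%s, %s, %s): slope %.3f +/- %.3f per log10[M], 1 M intercept %.3f, r2 = %.4f\n",
              x$value_kind, x$species, x$solvent_tag, x$slope, x$stderr,
              x$intercept, x$r_squared))
  invisible(x)
}

#' Counterion uptake from the free-energy salt dependence
#'
#' Converts the slope `d(-dG)/d log10[M]` into the net number of ions bound
#' on duplex formation: `dn = slope / (2.303 alpha R T)` (2.303 = ln 10,
#' carried at full precision) with R = 1.987e-3
#' kcal/(mol K).  `alpha` is the empirical nonideality factor of the salt
#' solution (0.9 for NaCl, 0.88 for MgCl2); `T` defaults to 310.15 K
#' because the free energies are extrapolated to 37 degrees C.
#'
#' @param slope Slope of `-dG` versus `log10[M]`, kcal/mol per decade.
#' @param alpha Nonideality factor, in (0, 1].
#' @param T Absolute temperature, K.
#' @return An object of class `ion_uptake`: `delta_n` (full precision),
#'   `delta_n_rounded` (one decimal, the reporting convention), `alpha`,
#'   `method = "from_dG"`.
#' @export
#' @examples
#' ion_uptake_from_dg(3.91, alpha = 0.9)$delta_n_rounded  # 3.1 Na+ per duplex
ion_uptake_from_dg <- function(slope, alpha = 0.9, T = T37K) {
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (!is.finite(T) || T <= 0) stop("T must be positive", call. = FALSE)
  dn <- slope / (log(10) * alpha * RGAS_KCAL * T)
  structure(
    list(delta_n = dn, delta_n_rounded = round(dn, 1), alpha = alpha,
         method = "from_dG"),
    class = "ion_uptake"
  )
}

#' Counterion uptake from the melting-temperature salt dependence
#'
#' Uses `d(1/Tm)/d log10[M] = 2.303 alpha R dn / dH` (R = 1.987e-3
#' kcal/(mol K)), assuming the enthalpy is constant over the salt range:
#' `dn = slope * dH / (2.303 alpha R)`.  A salt-stabilised duplex has a
#' negative `1/Tm` slope and a negative `dH`, giving a positive uptake.
#'
#' @param slope_tm_inv Slope of `1/Tm` versus `log10[M]`, 1/K per decade.
#' @param dH Duplex formation enthalpy, kcal/mol (non-zero).
#' @param alpha Nonideality factor, in (0, 1].
#' @return An `ion_uptake` object with `method = "from_Tm"`.
#' @export
ion_uptake_from_tm <- function(slope_tm_inv, dH, alpha = 0.9) {
  if (!is.finite(dH) || dH == 0) stop("dH must be non-zero", call. = FALSE)
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  dn <- slope_tm_inv * dH / (log(10) * alpha * RGAS_KCAL)
  structure(
    list(delta_n = dn, delta_n_rounded = round(dn, 1), alpha = alpha,
         method = "from_Tm"),
    class = "ion_uptake"
  )
}

#' @export
print.ion_uptake <- function(x, ...) {
  cat(sprintf("Counterion uptake (%s, alpha = %.2f): dn = %.1f ions/duplex (%.4f)\n",
              x$method, x$alpha, x$delta_n_rounded, x$delta_n))
  invisible(x)
}

#' Stability shift relative to the 30 mM reference condition
#'
#' `dG_ref_30mM - dG_obs`: positive when the observed condition stabilises
#' the duplex relative to 30 mM salt.
#'
#' @param dg_obs Observed `dG37`, kcal/mol.
#' @param dg_ref_30mM Reference `dG37` at 30 mM salt, kcal/mol.
#' @return Shift in kcal/mol (vectorised).
#' @export
delta_g_salt_shift <- function(dg_obs, dg_ref_30mM) {
  dg_ref_30mM - dg_obs
}

#' Match/mismatch discrimination energetics
#'
#' Compares a matched and a mismatched duplex measured under the same
#' solution condition and strand concentration: `ddG37 = dG37_mismatch -
#' dG37_match` (positive when the match is more stable) and `dTm =
#' Tm_match - Tm_mismatch`.
#'
#' @param match,mismatch Lists with elements `params` ([thermo_params()])
#'   and `Tm` (K); optionally `condition`, which must agree between the two
#'   when present in both.
#' @return List with `ddG37` (kcal/mol) and `dTm` (K).
#' @export
#' @examples
#' m <- list(params = thermo_params(-98, (-98 + 12.5) * 1000 / 310.15), Tm = 335)
#' x <- list(params = thermo_params(-88, (-88 + 9.15) * 1000 / 310.15), Tm = 325)
#' discrimination(m, x)$ddG37  # 3.35
discrimination <- function(match, mismatch) {
  if (!is.null(match$condition) && !is.null(mismatch$condition) &&
      !identical(match$condition, mismatch$condition)) {
    stop("match and mismatch must share the same solution condition",
         call. = FALSE)
  }
  list(ddG37 = mismatch$params$dG37 - match$params$dG37,
       dTm = match$Tm - mismatch$Tm)
}

#' Correlation between salt-dependence slopes and 1 M intercepts
#'
#' Across a set of duplexes, more stable duplexes tend to show a steeper
#' salt dependence; this reports the Pearson correlation between the fitted
#' slopes and the 1 M-extrapolated stabilities.
#'
#' @param slopes,intercepts Numeric vectors of equal length (>= 3).
#' @return Pearson correlation coefficient.
#' @export
slope_intercept_correlation <- function(slopes, intercepts) {
  stopifnot(length(slopes) == length(intercepts), length(slopes) >= 3)
  cor(slopes, intercepts)
}
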