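#' Thermodynamic parameter triple for duplex formation
#'
#' Bundles the standard enthalpy, entropy and 37 degrees C free energy of
#' duplex formation.  `dG37` is always recomputed from `dH` and `dS`
#' (`dG37 = dH - 310.15 * dS / 1000`) so the triple is internally consistent
#' by construction.  For a duplex that is stable at 37 degrees C both `dH`
#' and `dG37` are negative.
#'
#' @param dH Enthalpy change, kcal/mol (negative for duplex formation).
#' @param dS Entropy change, cal/(mol K).
#' @return An object of class `thermo_params`: a list with elements `dH`,
#'   `dS` and `dG37` (kcal/mol).
#' @export
#' @examples
#' tp <- thermo_params(dH = -90, dS = -250)
#' tp$dG37  # -12.46 kcal/mol
thermo_params <- function(dH, dS) {
  stopifnot(is.numeric(dH), length(dH) == 1L, is.finite(dH),
            is.numeric(dS), length(dS) == 1L, is.finite(dS))
  structure(
    list(dH = dH, dS = dS, dG37 = gibbs_free_energy(dH, dS, T37K)),
    class = "thermo_params"
  )
}

#' @export
print.thermo_params <- function(x, ...) {
  cat(sprintf("Duplex formation thermodynamics:\n"))
  cat(sprintf("  dH   = %8.2f kcal/mol\n", x$dH))
  cat(sprintf("  dS   = %8.1f cal/(mol K)\n", x$dS))
  cat(sprintf("  dG37 = %8.2f kcal/mol\n", x$dG37))
  invisible(x)
}

# arithmetic helpers used by the nearest-neighbor decomposition
tp_add <- function(a, b) thermo_params(a$dH + b$dH, a$dS + b$dS)
tp_sub <- function(a, b) thermo_params(a$dH - b$dH, a$dS - b$dS)

#' Gibbs free energy from enthalpy and entropy
#'
#' `dG(T) = dH - T * dS / 1000`; the factor 1000 converts the entropy from
#' cal to kcal units.
#'
#' @param dH Enthalpy change, kcal/mol.
#' @param dS Entropy change, cal/(mol K).
#' @param T Absolute temperature, K (> 0).  May be a vector.
#' @return Free energy change in kcal/mol, same length as `T`.
#' @export
#' @examples
#' gibbs_free_energy(-90, -250, 310.15)  # -12.46
gibbs_free_energy <- function(dH, dS, T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("temperature must be positive (Kelvin)", call. = FALSE)
  }
  dH - T * dS / 1000
}

#' Association equilibrium constant from free energy
#'
#' `K = exp(-dG / (R T))` with R = 1.987e-3 kcal/(mol K).
#'
#' @param dG Free energy change of association, kcal/mol.
#' @param T Absolute temperature, K (> 0).
#' @return Equilibrium constant, 1/M (strictly positive).
#' @export
equilibrium_constant <- function(dG, T) {
  if (any(!is.finite(T)) || any(T <= 0)) {
    stop("temperature must be positive (Kelvin)", call. = FALSE)
  }
  exp(-dG / (RGAS_KCAL * T))
}

#' Fraction of strands in duplex under two-state mass action
#'
#' For a bimolecular, non-self-complementary duplex with total strand
#' concentration `Ct` (each strand at `Ct/2`), the duplexed fraction `f`
#' satisfies `K * Ct * (1 - f)^2 = 2 f`.  The smaller root of the quadratic
#' is the physical one; it is computed in the rationalised form
#' `f = 2 K Ct / (2 K Ct + 2 + sqrt((2 K Ct + 2)^2 - 4 (K Ct)^2))`
#' which avoids cancellation when `K * Ct` is small.
#'
#' @param K Association constant, 1/M (>= 0).  May be a vector.
#' @param Ct Total single-strand concentration, M (> 0).
#' @return Fraction in duplex, in `[0, 1]`.
#' @export
#' @examples
#' duplex_fraction(4 / 1e-5, 1e-5)  # 0.5, the definition of Tm
duplex_fraction <- function(K, Ct) {
  if (any(!is.finite(K)) || any(K < 0)) {
    stop("equilibrium constant K must be non-negative", call. = FALSE)
  }
  if (!is.numeric(Ct) || length(Ct) != 1L || !is.finite(Ct) || Ct <= 0) {
    stop("total strand concentration Ct must be positive", call. = FALSE)
  }
  x <- K * Ct
  2 * x / ((2 * x + 2) + sqrt((2 * x + 2)^2 - 4 * x^2))
}

#' Melting temperature of a non-self-complementary duplex
#'
#' Closed form `Tm = 1000 * dH / (dS + R * ln(Ct / 4))` with R = 1.987
#' cal/(mol K).  `Ct` is the TOTAL strand concentration (both strands
#' summed, each at `Ct/2`); the `Ct/4` form of the equation holds only
#' under this convention.  At `Tm` the duplexed fraction is exactly 1/2 and
#' `K(Tm) = 4/Ct`.
#'
#' Only the bimolecular heteroduplex case is supported; self-complementary
#' sequences follow a different molecularity and are rejected.
#'
#' @param dH Enthalpy change, kcal/mol (must be negative).
#' @param dS Entropy change, cal/(mol K).
#' @param Ct Total single-strand concentration, M.
#' @param self_complementary Must be `FALSE`; `TRUE` raises an
#'   unsupported-molecularity error.
#' @return Melting temperature in Kelvin.
#' @export
#' @examples
#' melting_temperature(-90, -250, 1e-4)  # 332.04 K
melting_temperature <- function(dH, dS, Ct, self_complementary = FALSE) {
  if (isTRUE(self_complementary)) {
    stop("self-complementary (unimolecular-symmetry) duplexes are not supported",
         call. = FALSE)
  }
  if (!is.finite(dH) || dH >= 0) {
    stop("dH must be negative for a melting duplex", call. = FALSE)
  }
  if (!is.finite(Ct) || Ct <= 0) {
    stop("Ct must be positive", call. = FALSE)
  }
  denom <- dS + RGAS_CAL * log(Ct / 4)
  if (denom >= 0) {
    stop("parameter combination yields a non-positive melting temperature",
         call. = FALSE)
  }
  1000 * dH / denom
}

# duplexed fraction directly from (dH, dS) at temperatures T_K (vectorised)
two_state_fraction <- function(T_K, dH, dS, Ct) {
  K <- equilibrium_constant(gibbs_free_energy(dH, dS, T_K), T_K)
  duplex_fraction(K, Ct)
}
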