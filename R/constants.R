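# Single source of truth for physical constants.  The package works in the
# kcal/cal unit system conventional for nucleic acid thermodynamics, not SI.

RGAS_KCAL <- 1.987e-3   # gas constant, kcal mol-1 K-1
RGAS_CAL  <- 1.987      # gas constant, cal mol-1 K-1
T37K      <- 310.15     # 37 degrees C in Kelvin
C_TO_K    <- 273.15     # Celsius -> Kelvin offset

#' Physical constants used by the package
#'
#' Returns the gas constant and reference temperature used by every module,
#' in the kcal/cal unit system of nucleic acid thermodynamics.
#'
#' @return A list with elements `R_kcal` (1.987e-3 kcal/(mol K)), `R_cal`
#'   (1.987 cal/(mol K)) and `T37` (310.15 K).
#' @export
#' @examples
#' physical_constants()$T37
physical_constants <- function() {
  list(R_kcal = RGAS_KCAL, R_cal = RGAS_CAL, T37 = T37K)
}
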