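# Published reference values for the six 13-mer duplexes
# 5'-TTTGTATCXCAAT-3' / 5'-ATTGYGATACAAA-3' differing only in the internal
# X.Y pair.  These printed values are analysis inputs (e.g. for converting
# salt-dependence slopes into ion-uptake numbers) and generator defaults;
# they are not recomputed by the package.

.XY_PAIRS <- c("G.C", "D.T", "I.C", "A.T", "G.T", "I.T")

#' The study duplex sequences
#'
#' Returns the 13-mer duplex `5'-TTTGTATCXCAAT-3' / 5'-ATTGYGATACAAA-3'`
#' for a given internal X.Y pair (position 9 of the top strand).
#'
#' @param xy One of `"G.C"`, `"D.T"`, `"I.C"`, `"A.T"`, `"G.T"`, `"I.T"`.
#' @return A [validate_duplex()] result.
#' @export
#' @examples
#' study_duplex("G.T")$pairs[9]
study_duplex <- function(xy = .XY_PAIRS) {
  xy <- match.arg(xy)
  x <- substr(xy, 1, 1)
  y <- substr(xy, 3, 3)
  top <- sub("X", x, "TTTGTATCXCAAT")
  bottom <- sub("Y", y, "ATTGYGATACAAA")
  validate_duplex(top, bottom)
}

#' Published duplex stabilities at 1 M Na+
#'
#' The `-dG37` values (kcal/mol) of the six X.Y duplex variants at 1 M
#' Na+, in decreasing stability order G.C > D.T ~ I.C > A.T > G.T > I.T.
#'
#' @return Data frame with columns `pair` and `minus_dG37_1M`.
#' @export
published_duplex_stability <- function() {
  data.frame(
    pair = .XY_PAIRS,
    minus_dG37_1M = c(12.5, 11.2, 11.2, 10.4, 9.15, 8.83)
  )
}

#' Published salt-dependence slopes
#'
#' Slopes of `-dG37` versus `log10[M]` (kcal/mol per decade) with their
#' standard errors for the six X.Y duplex variants, under three solution
#' conditions: aqueous Na+, Na+ with 3 M ethanol, and Mg2+.
#'
#' @return Data frame with columns `pair`, `condition` (`"Na"`,
#'   `"Na_ethanol"`, `"Mg"`), `species` (`"Na"` or `"Mg"`), `slope`,
#'   `stderr`.
#' @export
#' @examples
#' subset(published_salt_slopes(), condition == "Na_ethanol" & pair == "G.C")
published_salt_slopes <- function() {
  data.frame(
    pair = rep(.XY_PAIRS, 3),
    condition = rep(c("Na", "Na_ethanol", "Mg"), each = 6),
    species = rep(c("Na", "Na", "Mg"), each = 6),
    slope = c(3.91, 3.25, 3.21, 2.91, 2.61, 2.55,
              3.32, 3.17, 3.19, 2.74, 2.43, 2.41,
              2.63, 2.00, 2.15, 1.92, 1.59, 1.50),
    stderr = c(0.19, 0.32, 0.16, 0.23, 0.18, 0.13,
               0.09, 0.21, 0.11, 0.09, 0.17, 0.13,
               0.26, 0.22, 0.16, 0.19, 0.26, 0.26)
  )
}

#' Default nonideality factors
#'
#' The empirical nonideality factor alpha of the salt solution used in the
#' counterion-uptake equations: 0.9 for NaCl (with or without ethanol) and
#' 0.88 for MgCl2.
#'
#' @param species `"Na"` or `"Mg"`.
#' @return Numeric alpha.
#' @export
default_alpha <- function(species = c("Na", "Mg")) {
  species <- match.arg(species)
  c(Na = 0.9, Mg = 0.88)[[species]]
}

# generator enthalpies paired with the published -dG37 values: fixture
# choices within the typical 13-mer range, ordered with stability
.DEFAULT_DH <- c("G.C" = -98, "D.T" = -95, "I.C" = -94,
                 "A.T" = -92, "G.T" = -88, "I.T" = -86)

#' Default synthetic study design
#'
#' The six-duplex synthetic study emulating the published design: each X.Y
#' variant gets its published 1 M `-dG37` and salt slope (for the chosen
#' condition), paired with a fixture enthalpy in the -85 to -105 kcal/mol
#' range typical of 13-mers.
#'
#' @param condition `"Na"`, `"Na_ethanol"` or `"Mg"`.
#' @return Data frame with columns `pair`, `minus_dG37_1M`, `dH`, `slope`,
#'   `species`, `alpha`.
#' @export
default_study_design <- function(condition = c("Na", "Na_ethanol", "Mg")) {
  condition <- match.arg(condition)
  stab <- published_duplex_stability()
  sl <- published_salt_slopes()
  sl <- sl[sl$condition == condition, c("pair", "species", "slope")]
  out <- merge(stab, sl, by = "pair", sort = FALSE)
  out$dH <- unname(.DEFAULT_DH[out$pair])
  out$alpha <- default_alpha(out$species[1])
  out[match(.XY_PAIRS, out$pair), c("pair", "minus_dG37_1M", "dH", "slope",
                                    "species", "alpha")]
}
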