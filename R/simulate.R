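#' Melting curve container
#'
#' A temperature/absorbance series at 260 nm together with the solution
#' condition it was recorded under.  Temperatures are stored in degrees
#' Celsius (the I/O convention); analysis functions convert to Kelvin
#' internally.
#'
#' @param temperature_C Strictly increasing numeric vector of temperatures,
#'   degrees C.  At least 20 points are required for downstream fitting.
#' @param absorbance Numeric vector of absorbances (arbitrary units), same
#'   length as `temperature_C`.
#' @param Ct Total single-strand concentration, M (> 0).
#' @param condition List describing the solution: elements `species`
#'   (`"Na"` or `"Mg"`), `salt_M` and `ethanol_M`.
#' @param label Free-text label.
#' @return An object of class `melting_curve`.
#' @export
melting_curve <- function(temperature_C, absorbance, Ct,
                          condition = list(species = "Na", salt_M = 1,
                                           ethanol_M = 0),
                          label = "") {
  stopifnot(is.numeric(temperature_C), is.numeric(absorbance))
  if (length(temperature_C) != length(absorbance)) {
    stop("temperature and absorbance must have the same length", call. = FALSE)
  }
  if (any(diff(temperature_C) <= 0)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(absorbance))) {
    stop("absorbance values must be finite", call. = FALSE)
  }
  if (!is.finite(Ct) || Ct <= 0) stop("Ct must be positive", call. = FALSE)
  structure(
    list(temperature_C = temperature_C, absorbance = absorbance, Ct = Ct,
         condition = condition, label = label),
    class = "melting_curve"
  )
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("Melting curve '%s': %d points, %.1f-%.1f C, Ct = %.3g M (%s %.3g M)\n",
              x$label, length(x$temperature_C), min(x$temperature_C),
              max(x$temperature_C), x$Ct, x$condition$species,
              x$condition$salt_M))
  invisible(x)
}

#' Configuration for the synthetic melting-curve generator
#'
#' Describes the true underlying thermodynamics, baselines, noise and
#' temperature grid from which synthetic UV melting data are produced.  The
#' generator runs the two-state model forward:
#' `A(T) = f(T) (b_ds + m_ds T) + (1 - f(T)) (b_ss + m_ss T) + eps`,
#' with `eps ~ Normal(0, noise_sd)` i.i.d. per point and `T` in degrees C
#' for the baselines.  The single-strand baseline must lie above the duplex
#' baseline over the whole grid (hyperchromicity on melting).
#'
#' Either `dS` or `dG37` must be given; if `dG37` is given, `dS` is derived
#' as `(dH - dG37) * 1000 / 310.15`.
#'
#' @param dH True enthalpy, kcal/mol (negative).
#' @param dS True entropy, cal/(mol K), or `NULL` to derive from `dG37`.
#' @param dG37 True free energy at 37 C, kcal/mol, used when `dS` is `NULL`.
#' @param baselines Named numeric vector `c(b_ds, m_ds, b_ss, m_ss)`:
#'   intercepts (absorbance units) and slopes (per degree C) of the duplex
#'   and single-strand baselines.  Defaults give roughly 20%
#'   hyperchromicity at 260 nm.
#' @param noise_sd Gaussian absorbance noise standard deviation (>= 0).
#' @param T_start,T_stop,T_step Temperature grid, degrees C.
#' @param Ct_list Strand concentrations for the van't Hoff series, M.
#' @param salt_model List for the salt series generator: `minus_dG37_1M`
#'   (the -dG37 extrapolated to 1 M salt, kcal/mol), `slope` (kcal/mol per
#'   log10 unit of [M]), `alpha` (nonideality factor) and `species`.
#' @param seed Mandatory integer seed; identical configurations produce
#'   identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dH, dS = NULL, dG37 = NULL,
                       baselines = c(b_ds = 0.60, m_ds = 2e-4,
                                     b_ss = 0.75, m_ss = 3e-4),
                       noise_sd = 0.002,
                       T_start = 0, T_stop = 95, T_step = 0.5,
                       Ct_list = c(2e-6, 5e-6, 1e-5, 2e-5, 5e-5, 1e-4),
                       salt_model = list(minus_dG37_1M = 12.5, slope = 3.91,
                                         alpha = 0.9, species = "Na"),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for the generator", call. = FALSE)
  if (is.null(dS)) {
    if (is.null(dG37)) stop("supply either dS or dG37", call. = FALSE)
    dS <- (dH - dG37) * 1000 / T37K
  }
  truth <- thermo_params(dH, dS)
  stopifnot(noise_sd >= 0)
  bl <- as.list(baselines)
  T_grid <- seq(T_start, T_stop, by = T_step)
  ss <- bl$b_ss + bl$m_ss * T_grid
  ds <- bl$b_ds + bl$m_ds * T_grid
  if (any(ss <= ds)) {
    stop("single-strand baseline must lie above the duplex baseline over the grid",
         call. = FALSE)
  }
  structure(
    list(truth = truth, baselines = bl, noise_sd = noise_sd,
         T_grid = T_grid, Ct_list = Ct_list, salt_model = salt_model,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# noiseless forward model on the configured grid
sim_noiseless <- function(config, Ct) {
  T_K <- config$T_grid + C_TO_K
  f <- two_state_fraction(T_K, config$truth$dH, config$truth$dS, Ct)
  bl <- config$baselines
  f * (bl$b_ds + bl$m_ds * config$T_grid) +
    (1 - f) * (bl$b_ss + bl$m_ss * config$T_grid)
}

#' Generate one synthetic melting curve
#'
#' Runs the two-state model forward on the configured temperature grid and
#' adds i.i.d. Gaussian absorbance noise.  The noiseless transition
#' midpoint equals `melting_temperature(dH, dS, Ct)` by construction.
#'
#' @param config A [sim_config()].
#' @param Ct Total strand concentration, M.
#' @param noise Set `FALSE` for the noiseless forward model (the noise RNG
#'   is still advanced identically either way, so noiseless and noisy runs
#'   of the same config are comparable point by point).
#' @return A [melting_curve()] whose label records the seed.
#' @export
#' @examples
#' cfg <- sim_config(dH = -92, dS = -258, seed = 1)
#' crv <- generate_melting_curve(cfg, Ct = 1e-5)
generate_melting_curve <- function(config, Ct, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (length(config$T_grid) < 20) {
    stop("temperature grid too sparse: at least 20 points required",
         call. = FALSE)
  }
  A <- sim_noiseless(config, Ct)
  if (noise && config$noise_sd > 0) {
    A <- A + rnorm(length(A), sd = config$noise_sd)
  }
  melting_curve(
    temperature_C = config$T_grid, absorbance = A, Ct = Ct,
    condition = list(species = config$salt_model$species,
                     salt_M = 1, ethanol_M = 0),
    label = sprintf("synthetic seed=%d Ct=%.3g", config$seed, Ct)
  )
}

#' Generate a strand-concentration (van't Hoff) series of melting curves
#'
#' One curve per concentration in `config$Ct_list`, sharing the same truth
#' parameters, so that the noiseless `1/Tm` is exactly linear in
#' `log10(Ct/4)`.  The RNG is seeded once from `config$seed` and curves are
#' drawn sequentially, so the whole series is reproducible.
#'
#' @param config A [sim_config()] with at least 2 (ideally >= 4)
#'   concentrations spanning >= 1.5 decades in `Ct_list`.
#' @param noise Passed to [generate_melting_curve()].
#' @return A list of [melting_curve()] objects.
#' @export
generate_ct_series <- function(config, noise = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  cts <- unique(config$Ct_list)
  if (length(cts) < 2) {
    stop("at least 2 distinct strand concentrations are required", call. = FALSE)
  }
  span <- log10(max(cts) / min(cts))
  if (length(cts) < 4 || span < 1.5) {
    warning(sprintf(paste0("van't Hoff design is weak: %d concentrations over ",
                           "%.2f decades (>= 4 over >= 1.5 recommended)"),
                    length(cts), span), call. = FALSE)
  }
  set.seed(config$seed)
  lapply(cts, function(ct) generate_melting_curve(config, ct, noise = noise))
}

#' Generate a synthetic salt series of duplex thermodynamics
#'
#' Emulates the linear dependence of duplex stability on the logarithm of
#' the salt concentration: `-dG37([M]) = minus_dG37_1M + slope * log10[M]`,
#' with the enthalpy held constant across the series (the entropy absorbs
#' the salt effect).  This is the generative structure assumed by the
#' counterion-uptake analysis, so the fitted slope of `-dG37` on `log10[M]`
#' recovers the configured slope exactly in the noiseless case.
#'
#' @param config A [sim_config()]; its `salt_model` supplies the 1 M
#'   intercept and slope, its `truth$dH` the constant enthalpy.
#' @param concentrations Positive salt concentrations, M (>= 3 of them).
#' @param noise_sd Optional Gaussian noise on `-dG37`, kcal/mol.
#' @return A data frame with columns `conc_M`, `dH`, `dS`, `dG37` and
#'   attribute `species`; one row per concentration.
#' @export
generate_salt_series <- function(config,
                                 concentrations = c(0.03, 0.07, 0.12, 0.3, 1.0),
                                 noise_sd = 0) {
  stopifnot(inherits(config, "sim_config"))
  if (any(concentrations <= 0)) {
    stop("salt concentrations must be positive", call. = FALSE)
  }
  if (length(concentrations) < 3) {
    stop("at least 3 salt concentrations are required", call. = FALSE)
  }
  sm <- config$salt_model
  minus_dG <- sm$minus_dG37_1M + sm$slope * log10(concentrations)
  if (noise_sd > 0) {
    set.seed(config$seed)
    minus_dG <- minus_dG + rnorm(length(minus_dG), sd = noise_sd)
  }
  dH <- config$truth$dH
  dG37 <- -minus_dG
  dS <- (dH - dG37) * 1000 / T37K
  out <- data.frame(conc_M = concentrations, dH = dH, dS = dS, dG37 = dG37)
  attr(out, "species") <- sm$species
  attr(out, "alpha") <- sm$alpha
  out
}
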