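#' Configuration for the end-to-end analysis pipeline
#'
#' Bundles everything [run_pipeline()] needs: the per-duplex study design
#' (truth stabilities, enthalpies and salt slopes for the synthetic data),
#' the strand-concentration and salt grids, noise level, nonideality
#' factor, the two-state agreement threshold and the seed.
#'
#' @param design Data frame as returned by [default_study_design()]:
#'   columns `pair`, `minus_dG37_1M`, `dH`, `slope`, `species`, `alpha`.
#' @param Ct_list Strand concentrations for the van't Hoff series, M.
#' @param salt_concs Salt concentrations for the salt series, M.
#' @param noise_sd Absorbance noise for the synthetic curves.
#' @param dh_agreement_tol Two-state flag threshold (see
#'   [consolidate_parameters()]).
#' @param reference_pair The matched duplex against which discrimination is
#'   computed (default `"G.C"`).
#' @param seed Integer seed recorded in every output artifact.
#' @param out_dir Optional directory for TSV/JSON outputs.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = default_study_design("Na"),
                       Ct_list = c(2e-6, 5e-6, 1e-5, 2e-5, 5e-5, 1e-4),
                       salt_concs = c(0.03, 0.07, 0.12, 0.3, 1.0),
                       noise_sd = 0.002,
                       dh_agreement_tol = 0.15,
                       reference_pair = "G.C",
                       seed,
                       out_dir = NULL) {
  if (missing(seed)) stop("a seed is mandatory", call. = FALSE)
  stopifnot(dh_agreement_tol > 0, noise_sd >= 0)
  needed <- c("pair", "minus_dG37_1M", "dH", "slope", "species", "alpha")
  if (!all(needed %in% names(design))) {
    stop("design is missing columns: ",
         paste(setdiff(needed, names(design)), collapse = ", "), call. = FALSE)
  }
  structure(
    list(design = design, Ct_list = Ct_list, salt_concs = salt_concs,
         noise_sd = noise_sd, dh_agreement_tol = dh_agreement_tol,
         reference_pair = reference_pair, seed = as.integer(seed),
         out_dir = out_dir),
    class = "run_config"
  )
}

pipeline_log <- function(stage, ..., verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full synthetic study pipeline
#'
#' For every duplex in the design: simulate a strand-concentration series
#' of melting curves, fit each curve to the two-state model, run the van't
#' Hoff regression on the fitted melting temperatures, and consolidate the
#' two estimates.  Then build the salt series from the design slope, fit
#' the stability-vs-log[M] regression and convert the slope into a
#' counterion-uptake number.  Finally tabulate discrimination (ddG37, dTm)
#' of every duplex against the reference pair.  Deterministic for a given
#' configuration.
#'
#' @param config A [run_config()].
#' @param verbose Log stage progress to standard error.
#' @return An object of class `analysis_report`: list with data frames
#'   `consolidated`, `salt` and `discrimination`, plus `n_nonconverged`
#'   and a `provenance` block (seed, package version, units note).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  stopifnot(inherits(config, "run_config"))
  design <- config$design
  if (nrow(design) == 0) stop("empty study design", call. = FALSE)

  consolidated <- list()
  salt_rows <- list()
  n_nonconv <- 0L
  per_duplex <- list()

  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    pipeline_log("simulate", "duplex %s: Ct series (%d curves, noise %.4g)",
                 row$pair, length(config$Ct_list), config$noise_sd,
                 verbose = verbose)
    cfg <- sim_config(
      dH = row$dH, dG37 = -row$minus_dG37_1M,
      noise_sd = config$noise_sd, Ct_list = config$Ct_list,
      salt_model = list(minus_dG37_1M = row$minus_dG37_1M,
                        slope = row$slope, alpha = row$alpha,
                        species = row$species),
      seed = config$seed + i
    )
    curves <- generate_ct_series(cfg)

    pipeline_log("fit", "duplex %s: two-state fits", row$pair,
                 verbose = verbose)
    fits <- lapply(curves, fit_two_state)
    conv <- vapply(fits, function(f) isTRUE(f$converged), logical(1))
    n_nonconv <- n_nonconv + sum(!conv)

    pipeline_log("vanthoff", "duplex %s: 1/Tm vs log10(Ct/4)", row$pair,
                 verbose = verbose)
    pts <- data.frame(
      Ct = vapply(fits[conv], function(f) f$Ct, numeric(1)),
      Tm = vapply(fits[conv], function(f) f$Tm, numeric(1))
    )
    vh <- vant_hoff_regression(pts)
    cons <- consolidate_parameters(fits, vh,
                                   dh_agreement_tol = config$dh_agreement_tol)

    pipeline_log("salt", "duplex %s: salt series and ion uptake", row$pair,
                 verbose = verbose)
    ss <- generate_salt_series(cfg, concentrations = config$salt_concs)
    series <- salt_series(ss$conc_M, -ss$dG37, value_kind = "minus_dG37",
                          species = row$species)
    slope_fit <- fit_salt_slope(series)
    uptake <- ion_uptake_from_dg(slope_fit$slope, alpha = row$alpha)

    consolidated[[i]] <- data.frame(
      pair = row$pair,
      dH = cons$params$dH, dS = cons$params$dS, dG37 = cons$params$dG37,
      dH_curve_fit = cons$curve_fit_params$dH,
      dH_vant_hoff = cons$vant_hoff_params$dH,
      two_state = cons$two_state_flag,
      n_curves = cons$n_curves,
      Tm_at_ref_Ct = melting_temperature(cons$params$dH, cons$params$dS,
                                         config$Ct_list[1])
    )
    salt_rows[[i]] <- data.frame(
      pair = row$pair, species = row$species,
      slope = slope_fit$slope, stderr = slope_fit$stderr,
      intercept_1M = slope_fit$intercept, r_squared = slope_fit$r_squared,
      alpha = row$alpha, delta_n = uptake$delta_n,
      delta_n_rounded = uptake$delta_n_rounded
    )
    per_duplex[[row$pair]] <- cons
  }

  cons_df <- do.call(rbind, consolidated)
  salt_df <- do.call(rbind, salt_rows)

  pipeline_log("discrimination", "ddG37/dTm vs %s", config$reference_pair,
               verbose = verbose)
  ref <- cons_df[cons_df$pair == config$reference_pair, ]
  if (nrow(ref) != 1) stop("reference pair not in design", call. = FALSE)
  disc <- do.call(rbind, lapply(
    setdiff(cons_df$pair, config$reference_pair),
    function(p) {
      r <- cons_df[cons_df$pair == p, ]
      d <- discrimination(
        list(params = thermo_params(ref$dH, ref$dS), Tm = ref$Tm_at_ref_Ct),
        list(params = thermo_params(r$dH, r$dS), Tm = r$Tm_at_ref_Ct)
      )
      data.frame(match = config$reference_pair, mismatch = p,
                 ddG37 = d$ddG37, dTm = d$dTm)
    }
  ))

  report <- structure(
    list(consolidated = cons_df, salt = salt_df, discrimination = disc,
         n_nonconverged = n_nonconv,
         provenance = list(
           seed = config$seed,
           package = "duplexmelt",
           version = as.character(packageVersion("duplexmelt")),
           units = paste("temperatures degC at I/O (K internal);",
                         "dH, dG37 kcal/mol; dS cal/(mol K); Ct, [M] mol/L"),
           config = config[c("Ct_list", "salt_concs", "noise_sd",
                             "dh_agreement_tol", "reference_pair")]
         )),
    class = "analysis_report"
  )
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("Analysis report (seed %d, %d duplexes, %d non-converged fits)\n",
              x$provenance$seed, nrow(x$consolidated), x$n_nonconverged))
  cat("\nConsolidated thermodynamics:\n")
  print(x$consolidated, row.names = FALSE, digits = 4)
  cat("\nSalt dependence and counterion uptake:\n")
  print(x$salt, row.names = FALSE, digits = 4)
  cat("\nDiscrimination vs reference:\n")
  print(x$discrimination, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write an analysis report to disk
#'
#' TSV tables (`consolidated.tsv`, `salt.tsv`, `discrimination.tsv`), each
#' headed by a units note and the seed, plus a nested `report.json` with
#' the full provenance block.  No timestamps are written, so identical runs
#' produce byte-identical output.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- c(sprintf("# seed=%d", report$provenance$seed),
           sprintf("# units=%s", report$provenance$units))
  for (nm in c("consolidated", "salt", "discrimination")) {
    path <- file.path(dir, paste0(nm, ".tsv"))
    con <- file(path, "w", encoding = "UTF-8")
    writeLines(hdr, con)
    close(con)
    suppressWarnings(
      write.table(report[[nm]], path, sep = "\t", quote = FALSE,
                  row.names = FALSE, append = TRUE)
    )
  }
  jsonlite::write_json(
    list(consolidated = report$consolidated, salt = report$salt,
         discrimination = report$discrimination,
         n_nonconverged = report$n_nonconverged,
         provenance = report$provenance),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
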