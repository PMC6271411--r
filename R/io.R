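# File formats: tab-delimited tables ('.' decimal, UTF-8) with '#'-prefixed
# key=value metadata headers, JSON for nested reports, two-record FASTA for
# duplex sequences.  All temperature I/O is in degrees C, energies in
# kcal/mol, entropies in cal/(mol K).

fmt_num <- function(x) formatC(x, format = "g", digits = 17)

#' Write a melting curve to TSV
#'
#' Metadata lines `# key=value` (`ct_M`, `salt_species`, `salt_conc_M`,
#' `ethanol_M`, `label`) followed by a `temperature_C<TAB>absorbance`
#' table at full precision.
#'
#' @param curve A [melting_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_melting_curve <- function(curve, path) {
  stopifnot(inherits(curve, "melting_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  meta <- c(
    sprintf("# ct_M=%s", fmt_num(curve$Ct)),
    sprintf("# salt_species=%s", curve$condition$species),
    sprintf("# salt_conc_M=%s", fmt_num(curve$condition$salt_M)),
    sprintf("# ethanol_M=%s", fmt_num(curve$condition$ethanol_M)),
    sprintf("# label=%s", curve$label)
  )
  writeLines(meta, con)
  writeLines("temperature_C\tabsorbance", con)
  writeLines(paste(fmt_num(curve$temperature_C),
                   fmt_num(curve$absorbance), sep = "\t"), con)
  invisible(path)
}

#' Read a melting curve from TSV
#'
#' Parses the format written by [write_melting_curve()].  The `ct_M`
#' metadata key is mandatory; temperatures must be strictly increasing;
#' malformed data rows are reported with their line number.
#'
#' @param path Input path.
#' @return A [melting_curve()].
#' @export
read_melting_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) {
      meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
    }
  }
  if (is.null(meta$ct_M)) {
    stop("metadata key 'ct_M' is missing from ", path, call. = FALSE)
  }
  body <- setdiff(seq_along(lines), meta_idx)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) < 2) stop("no data rows in ", path, call. = FALSE)
  header <- lines[body[1]]
  if (!identical(strsplit(header, "\t")[[1]][1:2],
                 c("temperature_C", "absorbance"))) {
    stop("expected header 'temperature_C\\tabsorbance' in ", path, call. = FALSE)
  }
  rows <- body[-1]
  parsed <- lapply(rows, function(i) {
    fields <- strsplit(lines[i], "\t")[[1]]
    vals <- suppressWarnings(as.numeric(fields))
    if (length(vals) != 2 || any(is.na(vals))) {
      stop(sprintf("malformed data row at line %d of %s", i, path),
           call. = FALSE)
    }
    vals
  })
  m <- do.call(rbind, parsed)
  if (any(diff(m[, 1]) <= 0)) {
    stop("temperatures are not strictly increasing in ", path, call. = FALSE)
  }
  melting_curve(
    temperature_C = m[, 1], absorbance = m[, 2],
    Ct = as.numeric(meta$ct_M),
    condition = list(
      species = if (is.null(meta$salt_species)) "Na" else meta$salt_species,
      salt_M = if (is.null(meta$salt_conc_M)) NA_real_ else as.numeric(meta$salt_conc_M),
      ethanol_M = if (is.null(meta$ethanol_M)) 0 else as.numeric(meta$ethanol_M)
    ),
    label = if (is.null(meta$label)) "" else meta$label
  )
}

#' Write a salt series to TSV
#'
#' @param series A [salt_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_salt_series <- function(series, path) {
  stopifnot(inherits(series, "salt_series"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(sprintf("# species=%s", series$species),
               sprintf("# solvent_tag=%s", series$solvent_tag),
               "concentration_M\tvalue\tvalue_kind"), con)
  writeLines(paste(fmt_num(series$conc_M), fmt_num(series$value),
                   series$value_kind, sep = "\t"), con)
  invisible(path)
}

#' Read a salt series from TSV
#'
#' @param path Input path (format of [write_salt_series()]).
#' @return A [salt_series()].
#' @export
read_salt_series <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8")
  meta_idx <- grep("^#", lines)
  meta <- list()
  for (ln in lines[meta_idx]) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq > 0) meta[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  tab <- read.table(text = lines[setdiff(seq_along(lines), meta_idx)],
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  kinds <- unique(tab$value_kind)
  if (length(kinds) != 1) {
    stop("salt series must have a single value_kind", call. = FALSE)
  }
  salt_series(tab$concentration_M, tab$value, value_kind = kinds,
              species = if (is.null(meta$species)) "Na" else meta$species,
              solvent_tag = if (is.null(meta$solvent_tag)) "aqueous" else meta$solvent_tag)
}

#' Read a duplex from a two-record FASTA file
#'
#' The first record is the top strand, the second the bottom strand, both
#' written 5' to 3'.  The I and D letters are permitted.
#'
#' @param path FASTA path.
#' @return A [validate_duplex()] result.
#' @export
read_duplex_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) != 2) {
    stop("expected exactly 2 FASTA records (top then bottom strand), got ",
         length(seqs), call. = FALSE)
  }
  validate_duplex(as.character(seqs[[1]]), as.character(seqs[[2]]))
}
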