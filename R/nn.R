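# Nearest-neighbor thermodynamics: unified Watson-Crick parameters plus the
# internal G.T wobble set, with step keys written "XY/WZ" meaning top strand
# 5'-XY-3' over bottom strand 3'-WZ-5' (X pairs W, Y pairs Z).

# canonical entries: dH kcal/mol, dS cal/(mol K)
.NN_WC <- list(
  "AA/TT" = c(-7.9, -22.2),
  "AT/TA" = c(-7.2, -20.4),
  "TA/AT" = c(-7.2, -21.3),
  "CA/GT" = c(-8.5, -22.7),
  "GT/CA" = c(-8.4, -22.4),
  "CT/GA" = c(-7.8, -21.0),
  "GA/CT" = c(-8.2, -22.2),
  "CG/GC" = c(-10.6, -27.2),
  "GC/CG" = c(-9.8, -24.4),
  "GG/CC" = c(-8.0, -19.9)
)

# internal G.T wobble steps (single and tandem)
.NN_GT <- list(
  "AG/TT" = c(1.0, 0.9),
  "AT/TG" = c(-2.5, -8.3),
  "CG/GT" = c(-4.1, -11.7),
  "CT/GG" = c(-2.8, -8.0),
  "GG/CT" = c(3.3, 10.4),
  "GG/TT" = c(5.8, 16.3),
  "GT/CG" = c(-4.4, -12.3),
  "GT/TG" = c(4.1, 9.5),
  "TG/AT" = c(-0.1, -1.7),
  "TG/GT" = c(-1.4, -6.2),
  "TT/AG" = c(-1.3, -5.3)
)

# duplex initiation contributions per terminal pair type
.NN_INIT <- list(
  GC = c(0.1, -2.8),   # terminal G.C
  AT = c(2.3, 4.1)     # terminal A.T
)

.NN_PROVENANCE <- paste(
  "Unified Watson-Crick DNA nearest-neighbor set (SantaLucia 1998,",
  "PNAS 95:1460; Allawi & SantaLucia 1997, Biochemistry 36:10581) and",
  "internal G.T wobble set (Allawi & SantaLucia 1997, Biochemistry 36:10581);",
  "1 M NaCl reference condition."
)

# the same step written from the other strand: "XY/WZ" -> "ZW/YX"
nn_alt_key <- function(key) {
  ch <- strsplit(key, "")[[1]]  # X Y / W Z
  paste0(ch[5], ch[4], "/", ch[2], ch[1])
}

# lookup environment with both written forms registered
.nn_env <- local({
  e <- new.env(parent = emptyenv())
  for (tab in list(.NN_WC, .NN_GT)) {
    for (key in names(tab)) {
      assign(key, tab[[key]], envir = e)
      assign(nn_alt_key(key), tab[[key]], envir = e)
    }
  }
  e
})

#' Nearest-neighbor parameter table
#'
#' The embedded published nearest-neighbor parameters: the 10 unique
#' Watson-Crick dinucleotide steps, the 11 internal G.T wobble steps, and
#' the per-terminal-pair initiation terms, all at the 1 M NaCl reference
#' condition.  Each step is stored as (dH, dS) with dG37 recomputed;
#' looking up a step under either of its two written forms returns the same
#' values.
#'
#' @return List with `steps` (data frame: `key`, `set`, `dH`, `dS`,
#'   `dG37`), `initiation` (list of [thermo_params()] for terminal `GC` and
#'   `AT` pairs) and `provenance` (citation string).
#' @export
#' @examples
#' tab <- nn_table()
#' subset(tab$steps, key == "CG/GT")  # a G.T wobble step
nn_table <- function() {
  mk <- function(tab, set) {
    data.frame(
      key = names(tab), set = set,
      dH = vapply(tab, `[`, numeric(1), 1L),
      dS = vapply(tab, `[`, numeric(1), 2L),
      row.names = NULL
    )
  }
  steps <- rbind(mk(.NN_WC, "WC"), mk(.NN_GT, "GT"))
  steps$dG37 <- gibbs_free_energy(steps$dH, steps$dS, T37K)
  list(
    steps = steps,
    initiation = list(GC = thermo_params(.NN_INIT$GC[1], .NN_INIT$GC[2]),
                      AT = thermo_params(.NN_INIT$AT[1], .NN_INIT$AT[2])),
    provenance = .NN_PROVENANCE
  )
}

# single-step lookup; NULL when the step has no published parameters
nn_step <- function(key) {
  if (!exists(key, envir = .nn_env, inherits = FALSE)) return(NULL)
  v <- get(key, envir = .nn_env)
  thermo_params(v[1], v[2])
}

# recognised base pairs (unordered)
.PAIRS <- c("AT", "GC", "GT", "IC", "IT", "DT")

pair_label <- function(a, b) {
  ab <- paste0(a, b)
  if (ab %in% .PAIRS || paste0(b, a) %in% .PAIRS) {
    # canonical order: as listed in .PAIRS
    if (ab %in% .PAIRS) ab else paste0(b, a)
  } else {
    NA_character_
  }
}

#' Validate and pair a DNA duplex
#'
#' Checks that two strands, both written 5' to 3' over the alphabet
#' `{A, C, G, T, I, D}` (I = inosine, D = 2,6-diaminopurine), form an
#' antiparallel duplex in which every position is one of the recognised
#' pairs A.T, G.C, G.T, I.C, I.T or D.T.
#'
#' @param top,bottom Strand sequences, 5' to 3'.
#' @return An object of class `duplex_seq`: list with `top`, `bottom`,
#'   `pairs` (per-position labels along the top strand, e.g. `"G.T"`) and
#'   `length`.
#' @export
#' @examples
#' d <- validate_duplex("TTTGTATCGCAAT", "ATTGTGATACAAA")
#' d$pairs[9]  # "G.T" at the central position
validate_duplex <- function(top, bottom) {
  stopifnot(is.character(top), is.character(bottom),
            length(top) == 1L, length(bottom) == 1L)
  top <- toupper(top); bottom <- toupper(bottom)
  if (nchar(top) == 0 || nchar(bottom) == 0) {
    stop("strands must be non-empty", call. = FALSE)
  }
  if (nchar(top) != nchar(bottom)) {
    stop("strand lengths differ: ", nchar(top), " vs ", nchar(bottom),
         call. = FALSE)
  }
  tc <- strsplit(top, "")[[1]]
  bc <- strsplit(bottom, "")[[1]]
  bad <- setdiff(unique(c(tc, bc)), c("A", "C", "G", "T", "I", "D"))
  if (length(bad) > 0) {
    stop("unrecognised bases: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (top == bottom) {
    stop(paste("identical strands imply a self-complementary duplex;",
               "only bimolecular heteroduplexes are supported"), call. = FALSE)
  }
  n <- length(tc)
  rb <- rev(bc)  # bottom aligned antiparallel, read 3'->5' left to right
  pairs <- character(n)
  for (i in seq_len(n)) {
    lbl <- pair_label(tc[i], rb[i])
    if (is.na(lbl)) {
      stop(sprintf("position %d: %s opposite %s is not a recognised pair",
                   i, tc[i], rb[i]), call. = FALSE)
    }
    pairs[i] <- paste0(substr(lbl, 1, 1), ".", substr(lbl, 2, 2))
  }
  structure(list(top = top, bottom = bottom, pairs = pairs, length = n),
            class = "duplex_seq")
}

#' @export
print.duplex_seq <- function(x, ...) {
  cat(sprintf("Duplex (%d bp):\n  5'-%s-3'\n  3'-%s-5'\n  pairs: %s\n",
              x$length, x$top, paste(rev(strsplit(x$bottom, "")[[1]]),
                                     collapse = ""),
              paste(x$pairs, collapse = " ")))
  invisible(x)
}

# dinucleotide step keys along a duplex, "XY/WZ" convention
duplex_step_keys <- function(duplex) {
  tc <- strsplit(duplex$top, "")[[1]]
  rb <- rev(strsplit(duplex$bottom, "")[[1]])
  n <- duplex$length
  vapply(seq_len(n - 1L), function(i) {
    paste0(tc[i], tc[i + 1L], "/", rb[i], rb[i + 1L])
  }, character(1))
}

nn_initiation_for <- function(duplex) {
  term <- c(duplex$pairs[1], duplex$pairs[duplex$length])
  init <- thermo_params(0, 0)
  for (p in term) {
    if (p %in% c("A.T")) {
      init <- tp_add(init, thermo_params(.NN_INIT$AT[1], .NN_INIT$AT[2]))
    } else if (p %in% c("G.C")) {
      init <- tp_add(init, thermo_params(.NN_INIT$GC[1], .NN_INIT$GC[2]))
    } else {
      stop("terminal pair ", p, " is not Watson-Crick; no initiation parameters",
           call. = FALSE)
    }
  }
  init
}

#' Nearest-neighbor prediction of duplex thermodynamics
#'
#' Sums the initiation terms for the two terminal pairs and the parameters
#' of every dinucleotide step.  Supported duplexes contain Watson-Crick
#' pairs and internal G.T wobble pairs; duplexes containing I or D are
#' rejected explicitly because no nearest-neighbor parameters are published
#' for them.
#'
#' @param duplex A [validate_duplex()] result.
#' @return A [thermo_params()] for duplex formation at 1 M NaCl.
#' @export
#' @examples
#' d <- validate_duplex("TTTGTATCACAAT", "ATTGTGATACAAA")
#' nn_predict(d)
nn_predict <- function(duplex) {
  stopifnot(inherits(duplex, "duplex_seq"))
  if (grepl("[ID]", duplex$top) || grepl("[ID]", duplex$bottom)) {
    stop("no published nearest-neighbor parameters for I or D containing duplexes",
         call. = FALSE)
  }
  total <- nn_initiation_for(duplex)
  for (key in duplex_step_keys(duplex)) {
    tp <- nn_step(key)
    if (is.null(tp)) {
      stop("no nearest-neighbor parameters for step ", key, call. = FALSE)
    }
    total <- tp_add(total, tp)
  }
  total
}

#' Nearest-neighbor contribution of a trinucleotide core
#'
#' The thermodynamic contribution of the two dinucleotide steps spanning a
#' trinucleotide (no initiation share).  The central pair may be a G.T
#' wobble; the flanking pairs must be Watson-Crick.  This is the quantity
#' compared against the core extracted from a measured duplex by
#' [trinucleotide_core_from_measured()].
#'
#' @param tri_top,tri_bottom 3-mers, 5' to 3'.
#' @return A [thermo_params()] for the two spanning steps.
#' @export
#' @examples
#' nn_trinucleotide("CGC", "GTG")  # wobble core: -dG37 = 1.06, -dH = 8.5
nn_trinucleotide <- function(tri_top, tri_bottom) {
  if (nchar(tri_top) != 3L || nchar(tri_bottom) != 3L) {
    stop("trinucleotide strands must be 3-mers", call. = FALSE)
  }
  d <- validate_duplex(tri_top, tri_bottom)
  if (!all(d$pairs[c(1, 3)] %in% c("A.T", "G.C"))) {
    stop("flanking pairs of the trinucleotide must be Watson-Crick", call. = FALSE)
  }
  total <- thermo_params(0, 0)
  for (key in duplex_step_keys(d)) {
    tp <- nn_step(key)
    if (is.null(tp)) {
      stop("no nearest-neighbor parameters for step ", key, call. = FALSE)
    }
    total <- tp_add(total, tp)
  }
  total
}

#' Trinucleotide core extracted from measured duplex thermodynamics
#'
#' Attributes the measured duplex parameters, minus the nearest-neighbor
#' initiation terms and every dinucleotide step NOT touching the central
#' pair, to the two steps spanning the central trinucleotide.  All
#' non-central steps must be Watson-Crick with published parameters; the
#' central pair itself may be any recognised pair (including I.C, I.T,
#' D.T), since its steps are never looked up.
#'
#' @param measured A [thermo_params()] for the whole duplex.
#' @param duplex A [validate_duplex()] result.
#' @param center 1-based position of the central pair on the top strand
#'   (must be interior).
#' @return A [thermo_params()] for the measured trinucleotide core.
#' @export
trinucleotide_core_from_measured <- function(measured, duplex, center) {
  stopifnot(inherits(measured, "thermo_params"), inherits(duplex, "duplex_seq"))
  n <- duplex$length
  if (center <= 1 || center >= n) {
    stop("center must be an interior position (2..", n - 1, ")", call. = FALSE)
  }
  keys <- duplex_step_keys(duplex)
  flank <- nn_initiation_for(duplex)
  for (i in seq_along(keys)) {
    if (i == center - 1L || i == center) next  # steps touching the center
    tp <- nn_step(keys[i])
    if (is.null(tp)) {
      stop("non-central step ", keys[i],
           " has no published nearest-neighbor parameters", call. = FALSE)
    }
    flank <- tp_add(flank, tp)
  }
  tp_sub(measured, flank)
}
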