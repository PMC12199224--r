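#' Describe one AQC-derivatized amino compound
#'
#' A compound spec records the chemical facts the pipeline needs about a
#' single analyte: how many carbon atoms the native (underivatized) compound
#' contributes, how many AQC tags are considered (each tag adds 10 reagent
#' carbons), and the monoisotopic m/z of the singly charged derivative ion.
#'
#' Derivative m/z values are treated as registry constants (taken from
#' instrument-confirmed values), never recomputed from elemental formulas.
#'
#' @param name compound identifier, e.g. `"Gly"`.
#' @param c_compound integer, carbon atoms in the native compound (>= 1).
#' @param n_tags integer, number of AQC tags considered. Lys and DAP can
#'   carry two tags chemically, but single-AQC derivatives are the
#'   convention and the default.
#' @param mz_m0 monoisotopic m/z of the derivative ion (Da), or `NA` when
#'   unknown.
#' @param rt_minutes optional retention time in minutes.
#' @return An object of class `"compound_spec"`: a list with fields `name`,
#'   `c_compound`, `n_tags`, `c_reagent` (= 10 * n_tags), `mz_m0`,
#'   `rt_minutes`.
#' @examples
#' gly <- compound_spec("Gly", 2, mz_m0 = 247.0949)
#' fold_dilution(gly)
#' isotopologue_ladder(gly)
#' @export
compound_spec <- function(name, c_compound, n_tags = 1L, mz_m0 = NA_real_,
                          rt_minutes = NA_real_) {
  c_compound <- as.integer(c_compound)
  n_tags <- as.integer(n_tags)
  if (length(c_compound) != 1L || is.na(c_compound) || c_compound < 1L)
    abort_aqc("'c_compound' must be a single integer >= 1",
              "aqc13c_invalid_spec")
  if (length(n_tags) != 1L || is.na(n_tags) || n_tags < 1L)
    abort_aqc("'n_tags' must be a single integer >= 1", "aqc13c_invalid_spec")
  mz_m0 <- as.numeric(mz_m0)
  if (!is.na(mz_m0) && mz_m0 <= 0)
    abort_aqc("'mz_m0' must be positive when present", "aqc13c_invalid_spec")
  structure(
    list(name = as.character(name),
         c_compound = c_compound,
         n_tags = n_tags,
         c_reagent = AQC_CARBONS_PER_TAG * n_tags,
         mz_m0 = mz_m0,
         rt_minutes = as.numeric(rt_minutes)),
    class = "compound_spec"
  )
}

#' @export
print.compound_spec <- function(x, ...) {
  cat(sprintf("<compound_spec> %s: %d compound C + %d reagent C (FD_C = %.3g)",
              x$name, x$c_compound, x$c_reagent, fold_dilution(x)))
  if (!is.na(x$mz_m0)) cat(sprintf(", M0 m/z %.4f", x$mz_m0))
  cat("\n")
  invisible(x)
}

#' Fold dilution of carbon number (FD_C)
#'
#' Derivatization dilutes the isotopic signal of the compound because the
#' reagent contributes carbon at natural abundance. FD_C is the ratio of
#' total carbons in the derivative to carbons in the native compound,
#' `(c_compound + c_reagent) / c_compound`. It ranges from 6 for glycine
#' down to 2.11 for tyrosine or phenylalanine among proteinogenic amino
#' acids, and is the predictor of the calibration cascade.
#'
#' @param x a [compound_spec()], a registry `data.frame`, or a numeric
#'   vector of compound carbon counts.
#' @param ... passed to methods; for the numeric method, `c_reagent`
#'   (default 10).
#' @return Numeric FD_C value(s), each > 1.
#' @examples
#' fold_dilution(compound_spec("Gly", 2))  # 6
#' fold_dilution(9)                        # Tyr/Phe: 19/9 = 2.11
#' @export
fold_dilution <- function(x, ...) UseMethod("fold_dilution")

#' @rdname fold_dilution
#' @export
fold_dilution.compound_spec <- function(x, ...) {
  (x$c_compound + x$c_reagent) / x$c_compound
}

#' @rdname fold_dilution
#' @param c_reagent reagent carbon count for the numeric method.
#' @export
fold_dilution.default <- function(x, c_reagent = AQC_CARBONS_PER_TAG, ...) {
  x <- as.numeric(x)
  if (any(!is.finite(x)) || any(x < 1))
    abort_aqc("compound carbon counts must be >= 1", "aqc13c_invalid_spec")
  (x + c_reagent) / x
}

#' @rdname fold_dilution
#' @export
fold_dilution.data.frame <- function(x, ...) {
  stats::setNames(
    fold_dilution.default(x$c_compound,
                          c_reagent = AQC_CARBONS_PER_TAG *
                            (if (is.null(x$n_tags)) 1L else x$n_tags)),
    x$name
  )
}

#' Isotopologue m/z ladder of a derivative
#'
#' Returns the m/z values M0..Mn of the recorded isotopologue window, where
#' n is the carbon count of the native compound: only the monoisotopic form
#' up to n heavy carbons is recorded, because higher isotopologues (which
#' would originate from reagent carbons) are not observed at low
#' enrichment. Successive isotopologues are spaced by the 13C-12C mass
#' difference, 1.003355 Da.
#'
#' @param spec a [compound_spec()] with known `mz_m0`.
#' @return Numeric vector of length `c_compound + 1`, named `M0`..`Mn`.
#' @examples
#' isotopologue_ladder(compound_spec("Gly", 2, mz_m0 = 247.0949))
#' @export
isotopologue_ladder <- function(spec) {
  stopifnot(inherits(spec, "compound_spec"))
  if (is.na(spec$mz_m0))
    abort_aqc(sprintf("no derivative m/z registered for '%s'", spec$name),
              "aqc13c_config_error")
  k <- 0:spec$c_compound
  stats::setNames(spec$mz_m0 + k * DELTA_13C, paste0("M", k))
}

#' Minimum mass resolution needed to separate two peaks
#'
#' The classic resolution requirement `R = m / delta_m`: to distinguish the
#' 13C1 from the 15N1 isotopologue of an AQC derivative (0.0063 Da apart),
#' derivatives between m/z 250 and 450 need resolutions between roughly
#' 39,680 and 71,430.
#'
#' @param mz m/z of the ion of interest (Da), > 0.
#' @param delta_m smallest mass difference to resolve (Da), > 0.
#' @return `mz / delta_m`, dimensionless.
#' @examples
#' required_resolution(250, 0.0063)
#' required_resolution(450, 0.0063)
#' @export
required_resolution <- function(mz, delta_m) {
  if (any(!is.finite(mz)) || any(mz <= 0) ||
      any(!is.finite(delta_m)) || any(delta_m <= 0))
    abort_aqc("'mz' and 'delta_m' must be positive", "aqc13c_domain_error")
  mz / delta_m
}

#' Monoisotopic m/z of the AMQ carbamoyl fragment cation
#'
#' AQC chemistry produces 6-aminoquinoline (AMQ) as its main byproduct; the
#' diagnostic carbamoyl fragment cation C10H7N2O+ appears at m/z 171.055.
#' Computed from monoisotopic atomic masses minus one electron mass.
#'
#' @return The fragment m/z in Da (single numeric).
#' @export
amq_fragment_mz <- function() {
  10 * MASS_C + 7 * MASS_H + 2 * MASS_N + MASS_O - MASS_E
}

#' Built-in compound registry
#'
#' Carbon counts for the 16 amino acids of the algal calibration mixture
#' (Ala, Arg, Asp, Glu, Gly, His, Ile, Leu, Lys, Met, Phe, Pro, Ser, Thr,
#' Tyr, Val) plus compounds typically lacking labeled standards: muramic
#' acid (MurA), hydroxyproline (Hyp), gamma-aminobutyric acid (GAB),
#' homoserine (Hse), diaminopimelic acid (DAP), Gln, Asn, Cys, Trp, and the
#' summed hexosamine pool (GlcN/GalN/ManN co-elute and are quantified as
#' their sum). Lys and DAP are registered with a single AQC tag, the
#' convention for all compounds; derivative m/z values are registry
#' constants and only the glycine derivative (m/z 247.0949) ships a value.
#'
#' @return A `data.frame` with columns `name`, `c_compound`, `n_tags`,
#'   `mz_m0`, `rt_minutes`.
#' @examples
#' reg <- default_registry()
#' range(fold_dilution(reg))
#' @export
default_registry <- function() {
  df <- data.frame(
    name = c("Ala", "Arg", "Asp", "Glu", "Gly", "His", "Ile", "Leu",
             "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Tyr", "Val",
             "MurA", "Hyp", "GAB", "Hse", "DAP", "Gln", "Asn", "Cys",
             "Trp", "Hexosamines"),
    c_compound = c(3L, 6L, 4L, 5L, 2L, 6L, 6L, 6L,
                   6L, 5L, 9L, 5L, 3L, 4L, 9L, 5L,
                   9L, 5L, 4L, 4L, 7L, 5L, 4L, 3L,
                   11L, 6L),
    n_tags = 1L,
    mz_m0 = NA_real_,
    rt_minutes = NA_real_,
    stringsAsFactors = FALSE
  )
  df$mz_m0[df$name == "Gly"] <- 247.0949
  df
}

#' Read a compound registry from CSV or JSON
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   delimited text).
#' @return A registry `data.frame` (see [default_registry()] for columns).
#' @export
read_registry <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    df <- as.data.frame(jsonlite::fromJSON(path))
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- c("name", "c_compound")
  miss <- setdiff(need, names(df))
  if (length(miss))
    abort_aqc(sprintf("registry is missing column(s): %s",
                      paste(miss, collapse = ", ")),
              "aqc13c_parse_error")
  if (is.null(df$n_tags)) df$n_tags <- 1L
  if (is.null(df$mz_m0)) df$mz_m0 <- NA_real_
  if (is.null(df$rt_minutes)) df$rt_minutes <- NA_real_
  if (any(duplicated(df$name)))
    abort_aqc("duplicate compound names in registry", "aqc13c_parse_error")
  if (any(!is.finite(df$c_compound)) || any(df$c_compound < 1))
    abort_aqc("registry carbon counts must be integers >= 1",
              "aqc13c_invalid_spec")
  df
}

#' Convert a registry table to a named list of compound specs
#'
#' @param registry a registry `data.frame`.
#' @return Named list of [compound_spec()] objects.
#' @export
registry_specs <- function(registry) {
  out <- lapply(seq_len(nrow(registry)), function(i) {
    compound_spec(registry$name[i], registry$c_compound[i],
                  n_tags = registry$n_tags[i], mz_m0 = registry$mz_m0[i],
                  rt_minutes = registry$rt_minutes[i])
  })
  stats::setNames(out, registry$name)
}
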