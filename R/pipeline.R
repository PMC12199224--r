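# schema validation for the long intensity table; errors name the offending
# rows so vendor-export problems are easy to locate
check_intensity_table <- function(table) {
  if (!is.data.frame(table))
    abort_aqc("intensity table must be a data.frame", "aqc13c_parse_error")
  need <- c("sample", "compound", "k", "intensity")
  miss <- setdiff(need, names(table))
  if (length(miss))
    abort_aqc(sprintf("intensity table is missing column(s): %s",
                      paste(miss, collapse = ", ")),
              "aqc13c_parse_error")
  if (nrow(table) == 0L) return(invisible(table))
  bad_k <- which(!is.finite(table$k) | table$k < 0 |
                   table$k != floor(table$k))
  if (length(bad_k))
    abort_aqc(sprintf("invalid isotopologue index k at row(s): %s",
                      paste(utils::head(bad_k, 5), collapse = ", ")),
              "aqc13c_parse_error")
  bad_i <- which(!is.finite(table$intensity) | table$intensity < 0)
  if (length(bad_i))
    abort_aqc(sprintf("negative or missing intensity at row(s): %s",
                      paste(utils::head(bad_i, 5), collapse = ", ")),
              "aqc13c_parse_error")
  invisible(table)
}

#' Read a long-format isotopologue intensity table
#'
#' The interchange schema mirrors vendor transition-report exports: one
#' row per sample x compound x isotopologue with columns `sample`,
#' `compound`, `k` (isotopologue index, 0..n), optional `mz`, and
#' `intensity`. CSV and TSV are supported (chosen by extension).
#'
#' @param path file path.
#' @return Validated `data.frame`.
#' @export
read_intensity_table <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  check_intensity_table(df)
  df
}

#' Pipeline configuration
#'
#' Bundles the knobs of the end-to-end analysis: where the registry,
#' standards and samples live, the low-range calibration bound, the
#' reference concentration anchoring the offset correction, the cascade
#' stage form, and the seed for any simulated inputs.
#'
#' @param registry path to a registry file, or a registry `data.frame`.
#' @param standards path to (or `data.frame` of) the isotope standards
#'   intensity table; optional.
#' @param samples path to (or `data.frame` of) the samples intensity
#'   table; optional.
#' @param low_range_hi upper bound of the low calibration range, atom %.
#' @param reference_concentration reference concentration in uM
#'   (default 300, the top of the concentration-standard series).
#' @param cascade_form stage 2-4 functional form, `"quadratic"` or
#'   `"power"`.
#' @param seed integer seed.
#' @param output_dir where CLI outputs are written.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(registry = default_registry(), standards = NULL,
                            samples = NULL, low_range_hi = 5,
                            reference_concentration = 300,
                            cascade_form = "quadratic", seed = 1L,
                            output_dir = ".") {
  if (!is.finite(reference_concentration) || reference_concentration <= 0)
    abort_aqc("'reference_concentration' must be > 0", "aqc13c_domain_error")
  if (!is.finite(low_range_hi) || low_range_hi <= NATURAL_13C * 100)
    abort_aqc("'low_range_hi' must exceed natural abundance (1.1 atom %)",
              "aqc13c_domain_error")
  structure(
    list(registry = registry, standards = standards, samples = samples,
         low_range_hi = low_range_hi,
         reference_concentration = reference_concentration,
         cascade_form = match.arg(cascade_form, c("quadratic", "power")),
         seed = as.integer(seed), output_dir = output_dir),
    class = "pipeline_config"
  )
}

#' Fit a concentration calibration curve
#'
#' Ordinary least squares of total peak area (summed over all
#' isotopologues) on known concentration. Routine practice expects
#' R^2 > 0.991; a lower value triggers a warning. The inverse mapping for
#' unknowns is [concentration_from_area()].
#'
#' @param points `data.frame` with columns `concentration_uM` and
#'   `total_area`.
#' @param compound optional identifier.
#' @return An object of class `"concentration_curve"` with `slope`
#'   (area per uM), `intercept`, `r2`.
#' @export
fit_concentration_curve <- function(points, compound = NA_character_) {
  df <- points[stats::complete.cases(
    points[, c("concentration_uM", "total_area")]), ]
  if (nrow(df) < 3L)
    abort_aqc("need at least 3 concentration standards", "aqc13c_fit_error")
  if (length(unique(df$concentration_uM)) < 2L)
    abort_aqc("degenerate concentration spread", "aqc13c_fit_error")
  fit <- stats::lm(total_area ~ concentration_uM, data = df)
  cf <- stats::coef(fit)
  ss_tot <- sum((df$total_area - mean(df$total_area))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  if (r2 < 0.991)
    warning(sprintf("concentration calibration R^2 = %.4f is below 0.991%s",
                    r2, if (is.na(compound)) "" else paste0(" for ", compound)),
            call. = FALSE)
  structure(
    list(compound = compound, slope = unname(cf[2]),
         intercept = unname(cf[1]), r2 = r2, n = nrow(df),
         range_uM = range(df$concentration_uM)),
    class = "concentration_curve"
  )
}

#' @export
print.concentration_curve <- function(x, ...) {
  cat(sprintf(
    "<concentration_curve>%s area = %.5g * uM + %.5g, R^2 = %.4f (n = %d)\n",
    if (is.na(x$compound)) "" else paste0(" ", x$compound, ":"),
    x$slope, x$intercept, x$r2, x$n))
  invisible(x)
}

#' @rdname fit_concentration_curve
#' @param curve a `"concentration_curve"`.
#' @param total_area total peak area(s) of unknowns.
#' @return `concentration_from_area()`: concentrations in uM.
#' @export
concentration_from_area <- function(curve, total_area) {
  stopifnot(inherits(curve, "concentration_curve"))
  (total_area - curve$intercept) / curve$slope
}

#' Calibrate an enrichment table
#'
#' Applies per-compound isotope calibration curves to offset-corrected
#' enrichments. The pipeline order is fixed: offset correction must come
#' first, so this function refuses tables lacking a `corrected_atom_pct`
#' column. Compounds without a curve are flagged (`"no_curve"`), never
#' silently dropped; the curve provenance (`"measured"` or `"predicted"`)
#' is recorded per row.
#'
#' @param enrichment enrichment `data.frame` with `corrected_atom_pct`.
#' @param curves named list of `"calibration_curve"` objects.
#' @return Input with `calibrated_atom_pct` and `curve_source` columns.
#' @export
calibrate_enrichment <- function(enrichment, curves) {
  if (is.null(enrichment$corrected_atom_pct))
    abort_aqc("offset correction must be applied before calibration (no 'corrected_atom_pct' column)",
              "aqc13c_order_error")
  nms <- vapply(curves, function(cv) cv$compound, character(1))
  names(curves) <- nms
  enrichment$calibrated_atom_pct <- NA_real_
  enrichment$curve_source <- "none"
  for (nm in unique(enrichment$compound)) {
    idx <- which(enrichment$compound == nm & enrichment$flag == "ok")
    if (!length(idx)) next
    if (!nm %in% nms) {
      enrichment$curve_source[enrichment$compound == nm] <- "no_curve"
      next
    }
    cv <- curves[[nm]]
    enrichment$calibrated_atom_pct[idx] <- suppressWarnings(
      as.numeric(apply_calibration(cv, enrichment$corrected_atom_pct[idx])))
    enrichment$curve_source[idx] <-
      if (isTRUE(cv$predicted)) "predicted" else "measured"
  }
  enrichment
}

#' Run the full per-sample analysis
#'
#' Executes the analysis stages in their fixed order for every sample x
#' compound in a long intensity table: (1) total area, and concentration
#' if a concentration curve is available; (2) apparent atom % 13C;
#' (3) concentration-dependent offset correction; (4) isotope calibration
#' with measured curves where available and predicted curves otherwise.
#' QC flags mark undefined and monoisotopic-only measurements; missing
#' curves and offset models are flagged gaps, not silent omissions.
#'
#' @param samples long intensity table (`data.frame` or path).
#' @param registry registry `data.frame`.
#' @param curves named list of `"calibration_curve"` objects.
#' @param offset_models optional named list of `"offset_model"`s per
#'   compound; compounds without one are left uncorrected
#'   (`corrected = apparent`).
#' @param concentration_curves optional named list of
#'   `"concentration_curve"`s per compound.
#' @return A `data.frame` with one row per sample x compound: `sample`,
#'   `compound`, `total_area`, `concentration_uM`, `apparent_atom_pct`,
#'   `corrected_atom_pct`, `calibrated_atom_pct`, `curve_source`, `flag`.
#' @export
process_samples <- function(samples, registry = default_registry(), curves,
                            offset_models = NULL,
                            concentration_curves = NULL) {
  if (is.character(samples)) samples <- read_intensity_table(samples)
  enr <- enrichment_table(samples, registry)
  if (nrow(enr) == 0L) {
    enr$concentration_uM <- numeric()
    enr$corrected_atom_pct <- numeric()
    enr$calibrated_atom_pct <- numeric()
    enr$curve_source <- character()
    return(enr)
  }
  enr$concentration_uM <- NA_real_
  if (!is.null(concentration_curves)) {
    for (nm in intersect(unique(enr$compound), names(concentration_curves))) {
      idx <- enr$compound == nm
      enr$concentration_uM[idx] <- concentration_from_area(
        concentration_curves[[nm]], enr$total_area[idx])
    }
  }
  enr$corrected_atom_pct <- enr$apparent_atom_pct
  if (!is.null(offset_models)) {
    for (nm in intersect(unique(enr$compound), names(offset_models))) {
      idx <- which(enr$compound == nm & enr$flag == "ok")
      if (!length(idx)) next
      enr$corrected_atom_pct[idx] <- enr$apparent_atom_pct[idx] +
        suppressWarnings(predict(offset_models[[nm]], enr$total_area[idx]))
    }
  }
  calibrate_enrichment(enr, curves)
}

#' Write a JSON run manifest
#'
#' Records package version, seed and a digest of the configuration so a
#' run can be reproduced byte-for-byte.
#'
#' @param path output file.
#' @param cfg a [pipeline_config()].
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, cfg) {
  cfg_flat <- cfg[c("low_range_hi", "reference_concentration",
                    "cascade_form", "seed")]
  js <- jsonlite::toJSON(cfg_flat, auto_unbox = TRUE)
  digest <- sprintf("%08x",
                    sum(utf8ToInt(as.character(js)) *
                          (seq_len(nchar(js)) %% 97 + 1)) %% .Machine$integer.max)
  manifest <- list(
    package = "aqc13c",
    version = as.character(utils::packageVersion("aqc13c")),
    r_version = as.character(getRversion()),
    seed = cfg$seed,
    config = cfg_flat,
    config_digest = digest
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
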