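#' Apparent atom % 13C from an isotopologue spectrum
#'
#' The intensity-weighted heavy-carbon fraction
#' `100 * sum(k * S_k) / (n * sum(S_k))`, where S_k is the intensity of the
#' isotopologue with k heavy carbons and n is the carbon count of the
#' native compound (reagent carbons are excluded from the denominator, so
#' at natural abundance the apparent value exceeds 1.1 atom % by roughly
#' the fold dilution FD_C). The estimator is invariant to rescaling the
#' spectrum.
#'
#' @param x numeric intensity vector S0..Sm (k = 0, 1, ...), or an
#'   `"isotopologue_spectrum"`.
#' @param n carbon count of the native compound; defaults to
#'   `length(x) - 1` for the recorded window M0..Mn.
#' @return Apparent atom % 13C (numeric scalar).
#' @examples
#' atom_percent_13c(c(1, 0, 0), n = 2)  # 0
#' atom_percent_13c(c(0, 0, 1), n = 2)  # 100
#' @export
atom_percent_13c <- function(x, n = NULL) UseMethod("atom_percent_13c")

#' @rdname atom_percent_13c
#' @export
atom_percent_13c.isotopologue_spectrum <- function(x, n = NULL) {
  atom_percent_13c(unname(x$intensities), n = n)
}

#' @rdname atom_percent_13c
#' @export
atom_percent_13c.default <- function(x, n = NULL) {
  x <- as.numeric(x)
  if (is.null(n)) n <- length(x) - 1L
  if (length(x) < 1L || n < 1L)
    abort_aqc("need at least two isotopologues (n >= 1)",
              "aqc13c_domain_error")
  if (any(x < 0))
    abort_aqc("intensities must be nonnegative", "aqc13c_domain_error")
  tot <- sum(x)
  if (tot <= 0)
    abort_aqc("all-zero spectrum: atom % 13C is undefined",
              "aqc13c_undefined_measurement")
  k <- seq_along(x) - 1L
  100 * sum(k * x) / (n * tot)
}

#' Summarise a long intensity table into per-measurement enrichments
#'
#' Computes total area and apparent atom % 13C (see
#' [atom_percent_13c()]) for every sample x compound in a long intensity
#' table, with QC flags: measurements where no isotopologue was detected
#' are `"undefined"` (apparent is `NA`, never 0), and measurements where
#' only the monoisotopic form was detected are flagged
#' `"monoisotopic_only"` (enrichment cannot be meaningfully reported for
#' them).
#'
#' @param table long intensity table (`sample`, `compound`, `k`,
#'   `intensity`).
#' @param registry registry `data.frame` giving `c_compound` per compound.
#' @return A `data.frame` with columns `sample`, `compound`, `total_area`,
#'   `apparent_atom_pct`, `flag` plus any of `true_atom_pct`,
#'   `concentration_uM` present in the input.
#' @export
enrichment_table <- function(table, registry = default_registry()) {
  check_intensity_table(table)
  empty <- data.frame(sample = character(), compound = character(),
                      total_area = numeric(), apparent_atom_pct = numeric(),
                      flag = character(), stringsAsFactors = FALSE)
  if (nrow(table) == 0L) return(empty)
  unknown <- setdiff(unique(table$compound), registry$name)
  if (length(unknown))
    abort_aqc(sprintf("compound(s) not in registry: %s",
                      paste(unknown, collapse = ", ")),
              "aqc13c_parse_error")
  carry <- intersect(c("true_atom_pct", "concentration_uM", "replicate"),
                     names(table))
  key <- interaction(table$sample, table$compound, drop = TRUE, sep = "\r")
  rows <- lapply(split(table, key), function(df) {
    df <- df[order(df$k), ]
    n <- registry$c_compound[match(df$compound[1L], registry$name)]
    s <- df$intensity
    tot <- sum(s)
    if (tot <= 0) {
      app <- NA_real_; flag <- "undefined"
    } else if (all(s[-1L] == 0)) {
      app <- 0; flag <- "monoisotopic_only"
    } else {
      app <- atom_percent_13c(s, n = n); flag <- "ok"
    }
    out <- data.frame(sample = df$sample[1L], compound = df$compound[1L],
                      total_area = tot, apparent_atom_pct = app,
                      flag = flag, stringsAsFactors = FALSE)
    for (cc in carry) out[[cc]] <- df[[cc]][1L]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Fit the concentration-dependent isotope offset model
#'
#' With decreasing signal, higher isotopologues fall below the detection
#' limit one after another and the apparent atom % 13C declines. This
#' function quantifies the underestimation relative to a reference signal
#' (the 300 uM standard in routine use) from natural-abundance standards
#' measured across a concentration series: the deviation
#' `apparent(reference) - apparent(area)` is fitted as a monotone function
#' of `log10(total_area)`.
#'
#' Two functional forms are available. The default, `"interpolation"`,
#' fits a decreasing isotonic regression of the deviation on log area and
#' interpolates linearly between fitted points — this tracks the step-like
#' character of detection loss. `"quadratic"` fits a second-order
#' polynomial in log10(area), anchored to zero deviation at the reference
#' area. Both are clamped to the fitted area range when evaluated outside
#' it.
#'
#' @param natural_series `data.frame` with columns `total_area`,
#'   `apparent_atom_pct`, measured at natural abundance.
#' @param reference_area total area of the reference standard.
#' @param compound optional compound identifier stored in the model.
#' @param form `"interpolation"` (default) or `"quadratic"`.
#' @return An object of class `"offset_model"` with fields `compound`,
#'   `reference_area`, `form`, `fit_r2`, `area_range` and a deviation
#'   function accessible through [predict.offset_model()].
#' @export
fit_offset_model <- function(natural_series, reference_area,
                             compound = NA_character_,
                             form = c("interpolation", "quadratic")) {
  form <- match.arg(form)
  df <- natural_series[stats::complete.cases(
    natural_series[, c("total_area", "apparent_atom_pct")]), ]
  if (nrow(df) < 4L)
    abort_aqc("need at least 4 natural-abundance points to fit the offset",
              "aqc13c_fit_error")
  if (max(df$total_area) / min(df$total_area) < 10)
    abort_aqc("offset fit needs at least a 10-fold spread in total area",
              "aqc13c_fit_error")
  if (!is.finite(reference_area) || reference_area <= 0)
    abort_aqc("'reference_area' must be positive", "aqc13c_fit_error")
  la <- log10(df$total_area)
  la_ref <- log10(reference_area)
  dref <- abs(la - la_ref)
  if (min(dref) > log10(2))
    abort_aqc("no measurement near the reference area", "aqc13c_fit_error")
  ref_apparent <- mean(df$apparent_atom_pct[dref <= min(dref) + 1e-8])
  dev <- ref_apparent - df$apparent_atom_pct
  if (form == "interpolation") {
    ord <- order(la)
    iso <- stats::isoreg(la[ord], -dev[ord])   # deviation decreases in area
    dev_fit <- -iso$yf
    # collapse duplicated abscissae for interpolation
    ux <- tapply(dev_fit, la[ord], mean)
    xs <- as.numeric(names(ux))
    fun_la <- stats::approxfun(xs, as.numeric(ux), rule = 2)
    fitted <- fun_la(la)
  } else {
    fit <- stats::lm(dev ~ la + I(la^2))
    cf <- stats::coef(fit)
    qf <- function(z) cf[[1]] + cf[[2]] * z + cf[[3]] * z^2
    lo <- min(la); hi <- max(la)
    fun_la <- function(z) {
      z <- pmin(pmax(z, lo), hi)
      qf(z) - qf(min(max(la_ref, lo), hi))
    }
    fitted <- fun_la(la)
  }
  ss_res <- sum((dev - fitted)^2)
  ss_tot <- sum((dev - mean(dev))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(compound = compound, reference_area = reference_area,
         reference_apparent = ref_apparent, form = form,
         fun_la = fun_la, fit_r2 = r2,
         area_range = range(df$total_area), n = nrow(df)),
    class = "offset_model"
  )
}

#' @export
print.offset_model <- function(x, ...) {
  cat(sprintf(
    "<offset_model>%s %s in log10(area), %d points, R^2 = %.4f\n",
    if (is.na(x$compound)) "" else paste0(" ", x$compound, ":"),
    x$form, x$n, x$fit_r2))
  cat(sprintf("  reference area %.4g (apparent %.4g atom %%), area range [%.4g, %.4g]\n",
              x$reference_area, x$reference_apparent,
              x$area_range[1], x$area_range[2]))
  invisible(x)
}

#' Predicted isotope deviation at a given total area
#'
#' Evaluates the fitted deviation (atom % 13C lost to detection censoring,
#' relative to the reference area). Areas outside the fitted range are
#' clamped to the nearest bound with a warning.
#'
#' @param object an `"offset_model"`.
#' @param total_area numeric vector of total areas.
#' @param ... unused.
#' @return Deviation in atom % 13C, same length as `total_area`.
#' @export
predict.offset_model <- function(object, total_area, ...) {
  out_of_range <- total_area < object$area_range[1] |
    total_area > object$area_range[2]
  if (any(out_of_range))
    warning("total area outside the fitted range; deviation clamped to the nearest fitted bound",
            call. = FALSE)
  la <- log10(pmin(pmax(total_area, object$area_range[1]),
                   object$area_range[2]))
  object$fun_la(la)
}

#' Apply the concentration-dependent offset correction
#'
#' Adds the fitted deviation back onto the apparent atom % 13C:
#' `corrected = apparent + deviation(total_area)`. This step precedes the
#' isotope calibration; only corrected values enter calibration curves.
#'
#' @param meas enrichment `data.frame` (from [enrichment_table()]) with
#'   columns `apparent_atom_pct` and `total_area`, or a numeric vector of
#'   apparent values with `total_area` supplied.
#' @param model an `"offset_model"` for the same compound.
#' @param total_area required when `meas` is numeric.
#' @return Input with a `corrected_atom_pct` column added (data frame
#'   input) or a numeric vector of corrected values.
#' @export
apply_offset_correction <- function(meas, model, total_area = NULL) {
  stopifnot(inherits(model, "offset_model"))
  if (is.data.frame(meas)) {
    if (!is.na(model$compound) &&
        any(meas$compound != model$compound, na.rm = TRUE))
      abort_aqc("offset model was fitted for a different compound",
                "aqc13c_domain_error")
    dev <- predict(model, meas$total_area)
    meas$corrected_atom_pct <- meas$apparent_atom_pct + dev
    meas
  } else {
    if (is.null(total_area))
      abort_aqc("'total_area' is required for numeric input",
                "aqc13c_domain_error")
    as.numeric(meas) + predict(model, total_area)
  }
}
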