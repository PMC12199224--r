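#' Compare observed against predicted calibration values
#'
#' Standard model-evaluation statistics for a predicted calibration against
#' its measured counterpart: mean absolute deviation
#' `MAD = mean(|obs - pred|)`, mean absolute percentage deviation
#' `MAPD = 100 * mean(|obs - pred| / obs)`, and the 1:1-line regression of
#' predicted on observed (slope, intercept, R^2; the ideal model has slope
#' 1, intercept 0). MAPD classifies prediction quality: excellent
#' (MAPD < 10%), good (10% <= MAPD <= 20%), reasonable (MAPD <= 50%),
#' poor otherwise. MAD is symmetric under swapping observed and predicted;
#' MAPD is not (observed values form the denominator).
#'
#' @param observed numeric vector of observed (measured-calibration)
#'   atom % values; must be nonzero for MAPD.
#' @param predicted numeric vector of predicted values, same length.
#' @param compound identifier stored in the report (default `"overall"`).
#' @return An object of class `"validation_report"`: list with `compound`,
#'   `r2`, `mad`, `mapd`, `slope`, `intercept`, `n`, `category`.
#' @examples
#' evaluate_prediction(c(1, 2, 3), c(1.1, 1.9, 3.3))
#' @export
evaluate_prediction <- function(observed, predicted, compound = "overall") {
  if (length(observed) != length(predicted))
    abort_aqc("'observed' and 'predicted' must have equal length",
              "aqc13c_domain_error")
  if (length(observed) < 3L)
    abort_aqc("need at least 3 points", "aqc13c_domain_error")
  if (any(observed == 0))
    abort_aqc("MAPD is undefined for zero observed values",
              "aqc13c_undefined_measurement")
  mad_ <- mean(abs(observed - predicted))
  mapd <- 100 * mean(abs(observed - predicted) / abs(observed))
  fit <- stats::lm(predicted ~ observed)
  cf <- stats::coef(fit)
  ss_tot <- sum((predicted - mean(predicted))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  structure(
    list(compound = compound, r2 = r2, mad = mad_, mapd = mapd,
         slope = unname(cf[2]), intercept = unname(cf[1]),
         n = length(observed), category = mapd_category(mapd)),
    class = "validation_report"
  )
}

#' MAPD quality category
#'
#' @param mapd mean absolute percentage deviation, in percent.
#' @return `"excellent"` (< 10), `"good"` (10 to 20, inclusive),
#'   `"reasonable"` (<= 50) or `"poor"` (> 50).
#' @export
mapd_category <- function(mapd) {
  vapply(mapd, function(m) {
    if (m < 10) "excellent"
    else if (m <= 20) "good"
    else if (m <= 50) "reasonable"
    else "poor"
  }, character(1))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s (n = %d): %s\n",
              x$compound, x$n, x$category))
  cat(sprintf("  MAD %.4g atom %%, MAPD %.4g%%, slope %.4g, intercept %.4g, R^2 %.4g\n",
              x$mad, x$mapd, x$slope, x$intercept, x$r2))
  invisible(x)
}

#' Concentration limits of detection and quantification
#'
#' Extrapolated from the lowest detected concentration within the linear
#' range and its observed signal-to-noise ratio, using S/N criteria of 3
#' (LOD) and 10 (LOQ): `lod = lowest * 3 / sn`, `loq = lowest * 10 / sn`.
#' LOQ is always exactly 10/3 of LOD.
#'
#' @param lowest_detected lowest detected concentration (uM).
#' @param observed_sn signal-to-noise ratio observed at that
#'   concentration, > 0.
#' @return Named numeric vector `c(lod = , loq = )` in uM.
#' @examples
#' lod_loq_concentration(10, 25)  # lod 1.2, loq 4
#' @export
lod_loq_concentration <- function(lowest_detected, observed_sn) {
  if (any(!is.finite(observed_sn)) || any(observed_sn <= 0))
    abort_aqc("'observed_sn' must be positive", "aqc13c_domain_error")
  if (any(!is.finite(lowest_detected)) || any(lowest_detected <= 0))
    abort_aqc("'lowest_detected' must be positive", "aqc13c_domain_error")
  c(lod = lowest_detected * 3 / observed_sn,
    loq = lowest_detected * 10 / observed_sn)
}

#' Isotopic limits of detection and quantification
#'
#' Based on the precision of atom % 13C in natural-abundance samples:
#' `lod = 3 * sd`, `loq = 10 * sd`, where sd is the standard deviation of
#' apparent atom % 13C across natural-abundance replicates. Pass either
#' the replicate measurements (>= 3 values; the sd is computed) or a
#' single precomputed standard deviation.
#'
#' @param x numeric: natural-abundance atom % replicates (length >= 3) or
#'   one standard deviation (length 1).
#' @return Named numeric vector `c(lod = , loq = )` in atom % 13C.
#' @examples
#' lod_loq_isotope(0.012)  # lod 0.036, loq 0.12
#' @export
lod_loq_isotope <- function(x) {
  if (length(x) == 1L) {
    natural_sd <- x
  } else if (length(x) >= 3L) {
    natural_sd <- stats::sd(x)
  } else {
    abort_aqc("need >= 3 natural-abundance replicates to estimate the sd",
              "aqc13c_insufficient_replication")
  }
  if (!is.finite(natural_sd) || natural_sd < 0)
    abort_aqc("standard deviation must be >= 0", "aqc13c_domain_error")
  c(lod = 3 * natural_sd, loq = 10 * natural_sd)
}
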