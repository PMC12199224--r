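#' Fit an isotope calibration curve
#'
#' Relates the measured (offset-corrected) atom % 13C of a derivative
#' (x-axis) to the true 13C enrichment of the compound (y-axis), fitted on
#' mixed labeled/unlabeled standards. Over the full enrichment range
#' (natural abundance to ~98 atom %) the relationship is linear; at low
#' enrichment it bends because higher isotopologues drop out of detection,
#' and a second-order polynomial `y = a x^2 + b x + c` is used.
#'
#' [fit_full_range()] and [fit_low_range()] are the two conventional
#' entry points; `fit_calibration()` is the underlying engine.
#'
#' @param points `data.frame` with columns `measured` (atom % 13C on the
#'   instrument scale) and `true` (known standard enrichment, atom %).
#' @param form `"quadratic"` or `"linear"`.
#' @param compound optional compound identifier stored in the curve.
#' @return An object of class `"calibration_curve"` with terms `a`, `b`,
#'   `c` (a = 0 for linear curves), validity range `range_lo`/`range_hi`
#'   (on the measured scale), `r2`, and a `predicted` flag (`FALSE` for
#'   curves fitted on standards).
#' @seealso [apply_calibration()], [predict.calibration_curve()]
#' @export
fit_calibration <- function(points, form = c("quadratic", "linear"),
                            compound = NA_character_) {
  form <- match.arg(form)
  df <- points[stats::complete.cases(points[, c("measured", "true")]), ]
  min_pts <- if (form == "quadratic") 4L else 3L
  if (nrow(df) < min_pts)
    abort_aqc(sprintf("need at least %d points for a %s calibration",
                      min_pts, form), "aqc13c_fit_error")
  n_unique <- length(unique(df$measured))
  if (n_unique < (if (form == "quadratic") 3L else 2L))
    abort_aqc("degenerate x spread: too few distinct measured values",
              "aqc13c_fit_error")
  fit <- if (form == "quadratic")
    stats::lm(true ~ measured + I(measured^2), data = df)
  else
    stats::lm(true ~ measured, data = df)
  cf <- stats::coef(fit)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((df$true - mean(df$true))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(
    list(compound = compound, form = form,
         a = if (form == "quadratic") unname(cf[3]) else 0,
         b = unname(cf[2]), c = unname(cf[1]),
         range_lo = min(df$measured), range_hi = max(df$measured),
         r2 = r2, n = nrow(df), predicted = FALSE,
         points = df[, c("measured", "true")]),
    class = "calibration_curve"
  )
}

#' @rdname fit_calibration
#' @details `fit_full_range()` requires standards spanning at least
#'   50 atom % of true enrichment; `fit_low_range()` expects standards in
#'   the low range (natural abundance up to roughly 5 atom %) and warns
#'   when the polynomial fit falls below the customary R^2 > 0.990.
#' @export
fit_full_range <- function(points, compound = NA_character_) {
  df <- points[stats::complete.cases(points[, c("measured", "true")]), ]
  if (nrow(df) >= 2L && diff(range(df$true)) < 50)
    abort_aqc("full-range calibration needs standards spanning >= 50 atom %",
              "aqc13c_fit_error")
  fit_calibration(df, form = "linear", compound = compound)
}

#' @rdname fit_calibration
#' @param low_range_hi upper bound (atom % true enrichment) of the low
#'   calibration range; default 5.
#' @export
fit_low_range <- function(points, compound = NA_character_,
                          low_range_hi = 5) {
  df <- points[stats::complete.cases(points[, c("measured", "true")]), ]
  if (nrow(df) && any(df$true > low_range_hi + 0.5))
    warning(sprintf("standards above %.3g atom %% included in a low-range fit",
                    low_range_hi), call. = FALSE)
  curve <- fit_calibration(df, form = "quadratic", compound = compound)
  if (curve$r2 < 0.990)
    warning(sprintf("low-range calibration R^2 = %.4f is below 0.990%s",
                    curve$r2,
                    if (is.na(compound)) "" else paste0(" for ", compound)),
            call. = FALSE)
  curve
}

#' Evaluate a calibration curve
#'
#' Maps measured (offset-corrected) atom % 13C to calibrated true atom %
#' by evaluating `a x^2 + b x + c`. Values outside the curve's validity
#' range are still returned but flagged: the result carries a logical
#' attribute `"out_of_range"` and a warning is raised.
#'
#' @param curve a `"calibration_curve"`.
#' @param measured numeric vector of measured atom % values.
#' @param tol slack (atom %) beyond the fitted range before a value is
#'   considered out of range; default 0.5.
#' @return Calibrated atom % values with attribute `out_of_range`.
#' @export
apply_calibration <- function(curve, measured, tol = 0.5) {
  stopifnot(inherits(curve, "calibration_curve"))
  oor <- measured < curve$range_lo - tol | measured > curve$range_hi + tol
  if (any(oor, na.rm = TRUE))
    warning(sprintf(
      "%d measured value(s) outside the calibrated range [%.3g, %.3g]; returned but flagged",
      sum(oor, na.rm = TRUE), curve$range_lo, curve$range_hi), call. = FALSE)
  out <- curve$a * measured^2 + curve$b * measured + curve$c
  attr(out, "out_of_range") <- oor
  out
}

#' @rdname apply_calibration
#' @param object a `"calibration_curve"`.
#' @param ... unused.
#' @export
predict.calibration_curve <- function(object, measured, tol = 0.5, ...) {
  apply_calibration(object, measured, tol = tol)
}

#' @export
coef.calibration_curve <- function(object, ...) {
  c(a = object$a, b = object$b, c = object$c)
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(
    "<calibration_curve>%s %s%s: y = %s%.5g x + %.5g\n",
    if (is.na(x$compound)) "" else paste0(" ", x$compound, ":"),
    x$form, if (isTRUE(x$predicted)) " (predicted)" else "",
    if (x$form == "quadratic") sprintf("%.5g x^2 + ", x$a) else "",
    x$b, x$c))
  cat(sprintf("  measured range [%.4g, %.4g] atom %%, R^2 = %.4f, n = %d\n",
              x$range_lo, x$range_hi, x$r2, x$n))
  if (!is.null(attr(x, "extrapolated")) && attr(x, "extrapolated"))
    cat("  warning: FD_C outside the cascade training range (extrapolated)\n")
  invisible(x)
}

#' @export
plot.calibration_curve <- function(x, ..., n_grid = 100) {
  xs <- seq(x$range_lo, x$range_hi, length.out = n_grid)
  ys <- x$a * xs^2 + x$b * xs + x$c
  graphics::plot(xs, ys, type = "l",
                 xlab = "measured atom % 13C",
                 ylab = "true atom % 13C",
                 main = sprintf("%s calibration (%s)",
                                ifelse(is.na(x$compound), "", x$compound),
                                x$form), ...)
  if (!is.null(x$points) && nrow(x$points))
    graphics::points(x$points$measured, x$points$true, pch = 19)
  invisible(x)
}

#' Serialize calibration curves to a parameter table
#'
#' @param curves a list of `"calibration_curve"` objects.
#' @return A `data.frame` with columns `compound`, `form`, `a`, `b`, `c`,
#'   `range_lo`, `range_hi`, `r2`, `predicted`.
#' @export
curves_to_table <- function(curves) {
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(compound = cv$compound, form = cv$form,
               a = cv$a, b = cv$b, c = cv$c,
               range_lo = cv$range_lo, range_hi = cv$range_hi,
               r2 = cv$r2, predicted = isTRUE(cv$predicted),
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild calibration curves from a parameter table
#'
#' Inverse of [curves_to_table()]; fitted points are not restored.
#'
#' @param table a parameter `data.frame` as written by [curves_to_table()].
#' @return Named list of `"calibration_curve"` objects.
#' @export
table_to_curves <- function(table) {
  out <- lapply(seq_len(nrow(table)), function(i) {
    structure(
      list(compound = table$compound[i], form = table$form[i],
           a = table$a[i], b = table$b[i], c = table$c[i],
           range_lo = table$range_lo[i], range_hi = table$range_hi[i],
           r2 = table$r2[i], n = NA_integer_,
           predicted = isTRUE(table$predicted[i]), points = NULL),
      class = "calibration_curve"
    )
  })
  stats::setNames(out, table$compound)
}
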