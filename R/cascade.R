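#' Fit the calibration-prediction regression cascade
#'
#' Compounds without isotopically labeled standards cannot be calibrated
#' directly, but their calibration terms turn out to be predictable from a
#' single chemical property: the fold dilution of carbon number FD_C (see
#' [fold_dilution()]). The cascade chains four regressions fitted on the
#' compounds that do have standards:
#'
#' 1. natural-abundance apparent atom % 13C on FD_C (linear);
#' 2. constant term `c` of the low-range polynomial on the
#'    natural-abundance apparent value;
#' 3. linear term `b` on `c`;
#' 4. quadratic term `a` on `c`.
#'
#' Stages 2-4 are nonlinear; the default form is a second-order polynomial
#' in the predictor, with a power law (`y = alpha * x^beta`) as
#' alternative. Molecular weight and C:N ratio were no better than FD_C as
#' stage-1 predictors and are not used.
#'
#' @param curves list of quadratic `"calibration_curve"` objects fitted on
#'   standards (named by compound, or carrying `compound` fields).
#' @param specs registry `data.frame` or list of [compound_spec()]s
#'   covering the calibrated compounds.
#' @param natural_measurements `data.frame` with columns `compound` and
#'   `natural_atom_pct` (offset-corrected apparent atom % 13C of unlabeled
#'   standards).
#' @param form functional form for stages 2-4: `"quadratic"` (default) or
#'   `"power"`.
#' @return An object of class `"cascade_model"` carrying the four stage
#'   fits, per-stage R^2, the training table and the FD_C training range.
#' @export
fit_cascade <- function(curves, specs, natural_measurements,
                        form = c("quadratic", "power")) {
  form <- match.arg(form)
  if (is.data.frame(specs)) specs <- registry_specs(specs)
  ctab <- curves_to_table(curves)
  if (any(ctab$form != "quadratic"))
    abort_aqc("cascade is fitted on low-range quadratic curves",
              "aqc13c_fit_error")
  fdc <- vapply(specs, fold_dilution, numeric(1))
  tab <- merge(ctab, natural_measurements, by = "compound")
  tab$fdc <- fdc[tab$compound]
  tab <- tab[stats::complete.cases(tab[, c("fdc", "natural_atom_pct",
                                           "a", "b", "c")]), ]
  if (nrow(tab) < 5L)
    abort_aqc("cascade needs at least 5 calibrated compounds",
              "aqc13c_fit_error")
  if (max(tab$fdc) / min(tab$fdc) < 2)
    abort_aqc("cascade needs at least a 2-fold spread in FD_C",
              "aqc13c_fit_error")
  stage1 <- fit_stage(tab$fdc, tab$natural_atom_pct, "linear")
  stage2 <- fit_stage(tab$natural_atom_pct, tab$c, form)
  stage3 <- fit_stage(tab$c, tab$b, form)
  stage4 <- fit_stage(tab$c, tab$a, form)
  structure(
    list(stage1 = stage1, stage2 = stage2, stage3 = stage3, stage4 = stage4,
         form = form, training = tab,
         fdc_range = range(tab$fdc),
         x_range = c(min(tab$range_lo), max(tab$range_hi))),
    class = "cascade_model"
  )
}

# one cascade stage: linear, quadratic-polynomial, or power-law regression
fit_stage <- function(x, y, form) {
  if (form == "power") {
    if (any(x <= 0) || any(y <= 0))
      abort_aqc("power-law stages need strictly positive values; use form = 'quadratic'",
                "aqc13c_fit_error")
    fit <- stats::lm(log(y) ~ log(x))
    cf <- stats::coef(fit)
    fun <- function(z) exp(cf[[1]]) * z^cf[[2]]
  } else if (form == "quadratic") {
    fit <- stats::lm(y ~ x + I(x^2))
    cf <- stats::coef(fit)
    fun <- function(z) cf[[1]] + cf[[2]] * z + cf[[3]] * z^2
  } else {
    fit <- stats::lm(y ~ x)
    cf <- stats::coef(fit)
    fun <- function(z) cf[[1]] + cf[[2]] * z
  }
  yhat <- fun(x)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else 1
  list(form = form, coef = stats::coef(fit), fun = fun, r2 = r2)
}

#' @export
print.cascade_model <- function(x, ...) {
  cat(sprintf("<cascade_model> %d compounds, FD_C in [%.3g, %.3g], stages 2-4 '%s'\n",
              nrow(x$training), x$fdc_range[1], x$fdc_range[2], x$form))
  cat(sprintf("  stage 1 (natural apparent ~ FD_C):  R^2 = %.4f\n", x$stage1$r2))
  cat(sprintf("  stage 2 (c ~ natural apparent):     R^2 = %.4f\n", x$stage2$r2))
  cat(sprintf("  stage 3 (b ~ c):                    R^2 = %.4f\n", x$stage3$r2))
  cat(sprintf("  stage 4 (a ~ c):                    R^2 = %.4f\n", x$stage4$r2))
  invisible(x)
}

#' @export
summary.cascade_model <- function(object, ...) {
  print(object)
  cat("\nTraining compounds:\n")
  print(object$training[, c("compound", "fdc", "natural_atom_pct",
                            "a", "b", "c")], row.names = FALSE)
  invisible(object)
}

#' Predict a calibration curve for an uncalibrated compound
#'
#' Chains the four cascade stages: the compound's FD_C gives its expected
#' natural-abundance apparent atom % 13C, which gives the constant term
#' `c`, from which the linear term `b` and quadratic term `a` follow. The
#' returned quadratic curve is flagged `predicted` and carries the stage
#' R^2 values; if the compound's FD_C lies outside the training range the
#' curve is additionally flagged as extrapolated, with a warning.
#'
#' @param model a fitted `"cascade_model"`.
#' @param spec a [compound_spec()] for the target compound.
#' @return A `"calibration_curve"` (quadratic, `predicted = TRUE`) with
#'   attributes `stage_r2` and `extrapolated`.
#' @export
predict_curve <- function(model, spec) {
  stopifnot(inherits(model, "cascade_model"))
  if (inherits(spec, "compound_spec")) {
    fdc <- fold_dilution(spec)
    nm <- spec$name
  } else {
    fdc <- as.numeric(spec)
    nm <- NA_character_
  }
  extrapolated <- fdc < model$fdc_range[1] - 1e-9 ||
    fdc > model$fdc_range[2] + 1e-9
  if (extrapolated)
    warning(sprintf(
      "FD_C %.3g outside the cascade training range [%.3g, %.3g]; predicted curve is extrapolated",
      fdc, model$fdc_range[1], model$fdc_range[2]), call. = FALSE)
  nat <- model$stage1$fun(fdc)
  c_hat <- model$stage2$fun(nat)
  b_hat <- model$stage3$fun(c_hat)
  a_hat <- model$stage4$fun(c_hat)
  curve <- structure(
    list(compound = nm, form = "quadratic",
         a = unname(a_hat), b = unname(b_hat), c = unname(c_hat),
         range_lo = model$x_range[1], range_hi = model$x_range[2],
         r2 = NA_real_, n = nrow(model$training),
         predicted = TRUE, points = NULL,
         predicted_natural_atom_pct = unname(nat)),
    class = "calibration_curve"
  )
  attr(curve, "stage_r2") <- c(stage1 = model$stage1$r2,
                               stage2 = model$stage2$r2,
                               stage3 = model$stage3$r2,
                               stage4 = model$stage4$r2)
  attr(curve, "extrapolated") <- extrapolated
  curve
}

#' @rdname predict_curve
#' @param object a `"cascade_model"`.
#' @param ... unused.
#' @export
predict.cascade_model <- function(object, spec, ...) {
  predict_curve(object, spec)
}

#' Leave-one-out evaluation of the cascade
#'
#' For each calibrated compound, refits the cascade without it, predicts
#' its calibration curve from FD_C alone, and compares predicted against
#' measured calibrated values on a grid of measured atom % points spanning
#' the compound's calibration range. Per-compound accuracy is summarised
#' by [evaluate_prediction()] (R^2, MAD, MAPD, 1:1-line regression) and
#' all points are pooled for an overall 1:1 regression.
#'
#' @param curves,specs,natural_measurements,form as in [fit_cascade()].
#' @param n_points number of evaluation points per compound (default 5,
#'   matching the number of low-enrichment standards per curve).
#' @return A list with `per_compound` (a `data.frame` of per-compound
#'   statistics), `overall` (a `"validation_report"` on the pooled
#'   points), and `points` (the pooled observed/predicted values).
#' @export
evaluate_cascade_loo <- function(curves, specs, natural_measurements,
                                 form = c("quadratic", "power"),
                                 n_points = 5) {
  form <- match.arg(form)
  if (is.data.frame(specs)) specs <- registry_specs(specs)
  nms <- vapply(curves, function(cv) cv$compound, character(1))
  names(curves) <- nms
  per <- list(); pooled <- list()
  for (nm in nms) {
    train <- curves[nms != nm]
    model <- fit_cascade(train, specs, natural_measurements, form = form)
    pred <- suppressWarnings(predict_curve(model, specs[[nm]]))
    mc <- curves[[nm]]
    xs <- seq(mc$range_lo, mc$range_hi, length.out = n_points)
    obs <- as.numeric(apply_calibration(mc, xs))
    est <- suppressWarnings(as.numeric(apply_calibration(pred, xs)))
    rep_i <- evaluate_prediction(obs, est, compound = nm)
    per[[nm]] <- as.data.frame(unclass(rep_i), stringsAsFactors = FALSE)
    pooled[[nm]] <- data.frame(compound = nm, observed = obs,
                               predicted = est)
  }
  pts <- do.call(rbind, pooled)
  overall <- evaluate_prediction(pts$observed, pts$predicted,
                                 compound = "overall")
  list(per_compound = do.call(rbind, per), overall = overall, points = pts)
}
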