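test_that("calibration fits recover exact generating curves", {
  # identity line over the full range
  pts <- data.frame(measured = c(1.1, 25, 50, 75, 98),
                    true = c(1.1, 25, 50, 75, 98))
  cv <- fit_full_range(pts)
  expect_equal(cv$form, "linear")
  expect_equal(cv$b, 1, tolerance = 1e-12)
  expect_equal(cv$a, 0)
  expect_equal(cv$c, 0, tolerance = 1e-10)
  expect_equal(cv$r2, 1, tolerance = 1e-12)
  # exact quadratic recovered to numerical precision
  x <- c(1, 2, 3, 4, 5)
  qpts <- data.frame(measured = x, true = 0.5 * x^2 + 2 * x + 1)
  qcv <- fit_calibration(qpts, form = "quadratic")
  expect_equal(unname(coef(qcv)), c(0.5, 2, 1), tolerance = 1e-9)
  expect_equal(qcv$r2, 1, tolerance = 1e-12)
})

test_that("degenerate and insufficient inputs are rejected", {
  expect_error(fit_calibration(
    data.frame(measured = c(2, 2, 2, 2), true = 1:4), form = "quadratic"),
    class = "aqc13c_fit_error")
  expect_error(fit_calibration(
    data.frame(measured = c(2, 2, 3), true = 1:3), form = "linear"),
    regexp = NA)  # 2 distinct x is enough for a line
  expect_error(fit_calibration(
    data.frame(measured = c(2, 2), true = c(1, 5)), form = "linear"),
    class = "aqc13c_fit_error")
  expect_error(fit_low_range(
    data.frame(measured = 1:3, true = 1:3)), class = "aqc13c_fit_error")
  # full-range fit demands a wide span of standards
  expect_error(fit_full_range(
    data.frame(measured = c(1, 2, 3), true = c(1, 2, 3))),
    class = "aqc13c_fit_error")
  # a visibly poor polynomial fit warns about the R^2 convention
  set.seed(5)
  noisy <- data.frame(measured = seq(1, 5, length.out = 8))
  noisy$true <- noisy$measured + rnorm(8, sd = 1.5)
  expect_warning(fit_low_range(noisy, low_range_hi = 10), "below 0.990")
})

test_that("noise-free full-window standards give slope 1 and the FD_C intercept", {
  for (nm in c("Gly", "Glu", "Phe")) {
    sp <- registry_specs(default_registry())[[nm]]
    levels <- c(1.1, 10, 30, 50, 75, 98)
    measured <- vapply(levels, function(lev) {
      f <- (lev / 100 - 0.011) / (0.98 - 0.011)
      cfg <- simulation_config(label_fraction = f, noise_cv = 0,
                               detection_floor = 0)
      atom_percent_13c(unname(simulate_spectrum(sp, cfg,
                                                window = "full")$intensities),
                       n = sp$c_compound)
    }, numeric(1))
    cv <- fit_full_range(data.frame(measured = measured, true = levels),
                         compound = nm)
    expect_equal(cv$b, 1, tolerance = 1e-6)
    expect_equal(cv$c, -(fold_dilution(sp) - 1) * 1.1, tolerance = 1e-6)
  }
})

test_that("fitted low-range curves recover held-out enrichments", {
  gly <- compound_spec("Gly", 2)
  set.seed(7)
  std <- simulate_dilution_series(gly, c(1.1, 1.5, 2, 2.5, 3, 4, 5),
                                  simulation_config())
  enr <- enrichment_table(std, data.frame(name = "Gly", c_compound = 2L))
  cv <- fit_low_range(data.frame(measured = enr$apparent_atom_pct,
                                 true = enr$true_atom_pct),
                      compound = "Gly")
  expect_gt(cv$r2, 0.99)
  # curve passes close to the noise-free expected points
  nf <- vapply(c(1.1, 2, 3, 5), function(lev) {
    f <- (lev / 100 - 0.011) / (0.98 - 0.011)
    cfg <- simulation_config(label_fraction = f, noise_cv = 0)
    atom_percent_13c(simulate_spectrum(gly, cfg), n = 2)
  }, numeric(1))
  fitted <- as.numeric(apply_calibration(cv, nf))
  expect_true(all(abs(fitted - c(1.1, 2, 3, 5)) < 0.05))
  # held-out noisy spectrum at true 2 atom % recovered within 0.1
  f2 <- (2 / 100 - 0.011) / (0.98 - 0.011)
  held <- simulate_spectrum(gly, simulation_config(label_fraction = f2,
                                                   seed = 12))
  expect_equal(as.numeric(apply_calibration(cv, atom_percent_13c(held, n = 2))),
               2, tolerance = 0.1 / 2)
})

test_that("low-range quadratic agrees with full-range linear at 5 atom %", {
  gly <- compound_spec("Gly", 2)
  meas <- function(lev, window) {
    f <- (lev / 100 - 0.011) / (0.98 - 0.011)
    cfg <- simulation_config(label_fraction = f, noise_cv = 0,
                             detection_floor = 0)
    sp <- simulate_spectrum(gly, cfg, window = window)
    atom_percent_13c(unname(sp$intensities), n = 2)
  }
  # the uncensored, untruncated response is exactly linear in the true
  # enrichment, so the two calibration forms must coincide
  lowlv <- c(1.1, 2, 3, 4, 5)
  low <- fit_low_range(data.frame(
    measured = vapply(lowlv, meas, numeric(1), window = "full"),
    true = lowlv))
  fulllv <- c(1.1, 5, 25, 50, 75, 98)
  full <- fit_full_range(data.frame(
    measured = vapply(fulllv, meas, numeric(1), window = "full"),
    true = fulllv))
  x5 <- meas(5, "full")
  expect_equal(as.numeric(apply_calibration(low, x5)),
               as.numeric(suppressWarnings(apply_calibration(full, x5))),
               tolerance = 0.2 / 5)
})

test_that("calibration application flags out-of-range inputs but returns values", {
  ident <- fit_calibration(
    data.frame(measured = c(1, 2, 3, 4), true = c(1, 2, 3, 4)),
    form = "quadratic")
  got <- apply_calibration(ident, 3.0)
  expect_equal(as.numeric(got), 3, tolerance = 1e-9)
  expect_false(any(attr(got, "out_of_range")))
  expect_warning(far <- apply_calibration(ident, 40), "flagged")
  expect_true(attr(far, "out_of_range"))
  expect_equal(as.numeric(far), 40, tolerance = 1e-6)
})

test_that("curve parameter tables round-trip", {
  x <- 1:5
  cv <- fit_calibration(data.frame(measured = x, true = 0.1 * x^2 + x),
                        form = "quadratic", compound = "Gly")
  tab <- curves_to_table(list(cv))
  back <- table_to_curves(tab)[["Gly"]]
  expect_equal(coef(back), coef(cv))
  expect_equal(back$range_lo, cv$range_lo)
  expect_false(back$predicted)
})
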