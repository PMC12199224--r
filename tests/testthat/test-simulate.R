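test_that("isotopologue distribution matches atom-level enumeration", {
  cases <- list(
    list(c1 = 2L, p1 = 0.5, c2 = 2L, p2 = 0.1),
    list(c1 = 3L, p1 = 0.98, c2 = 2L, p2 = 0.011),
    list(c1 = 1L, p1 = 0.25, c2 = 4L, p2 = 0.05)
  )
  for (cs in cases) {
    spec <- compound_spec("toy", cs$c1, n_tags = 1L)
    spec$c_reagent <- cs$c2  # small reagent for tractable enumeration
    got <- isotopologue_distribution(spec, cs$p1, cs$p2)
    expect_equal(got, enumerate_distribution(cs$c1, cs$p1, cs$c2, cs$p2),
                 tolerance = 1e-12)
    expect_equal(sum(got), 1, tolerance = 1e-12)
    # linearity of expectation for the mean heavy-atom count
    k <- seq_along(got) - 1
    expect_equal(sum(k * got), cs$c1 * cs$p1 + cs$c2 * cs$p2,
                 tolerance = 1e-12)
  }
})

test_that("distribution agrees with the polynomial-product oracle for real compounds", {
  for (nm in c("Gly", "Glu", "Phe")) {
    sp <- registry_specs(default_registry())[[nm]]
    expect_equal(isotopologue_distribution(sp, 0.011),
                 polyprod_distribution(sp$c_compound, 0.011,
                                       sp$c_reagent, 0.011),
                 tolerance = 1e-12)
  }
  expect_equal(
    isotopologue_distribution(compound_spec("x", 2), 0, p_natural = 0),
    c(1, rep(0, 12)))
})

test_that("noise-free spectra are proportional to the analytic window", {
  gly <- compound_spec("Gly", 2)
  cfg <- simulation_config(label_fraction = 0.3, noise_cv = 0,
                           detection_floor = 0)
  sp <- simulate_spectrum(gly, cfg)
  lab <- isotopologue_distribution(gly, 0.98)
  unl <- isotopologue_distribution(gly, 0.011)
  mix <- (0.3 * lab + 0.7 * unl)[1:3]
  expect_equal(unname(sp$intensities), 1e6 * mix, tolerance = 1e-12)
  expect_equal(sp$total_area, sum(sp$intensities))
  # degenerate config: everything monoisotopic
  cfg0 <- simulation_config(p_natural = 0, label_fraction = 0,
                            noise_cv = 0, detection_floor = 0)
  sp0 <- simulate_spectrum(gly, cfg0)
  expect_equal(unname(sp0$intensities), c(1e6, 0, 0))
})

test_that("spectra are reproducible under a fixed seed", {
  gly <- compound_spec("Gly", 2)
  cfg <- simulation_config(seed = 99)
  expect_identical(simulate_spectrum(gly, cfg), simulate_spectrum(gly, cfg))
  s1 <- simulate_dilution_series(gly, c(1.1, 2, 5), cfg)
  s2 <- simulate_dilution_series(gly, c(1.1, 2, 5), cfg)
  expect_identical(s1, s2)
})

test_that("full-window natural-abundance apparent equals 1.1 x FD_C exactly", {
  specs <- registry_specs(default_registry())
  for (sp in specs) {
    d <- isotopologue_distribution(sp, 0.011)
    apparent <- atom_percent_13c(d, n = sp$c_compound)
    expect_equal(apparent, 1.1 * fold_dilution(sp), tolerance = 1e-9)
    # window truncation loses < 0.1 atom % at natural abundance
    win <- d[seq_len(sp$c_compound + 1)]
    expect_lt(1.1 * fold_dilution(sp) -
                atom_percent_13c(win, n = sp$c_compound), 0.1)
  }
})

test_that("dilution series solves the mixing fraction correctly", {
  gly <- compound_spec("Gly", 2)
  cfg <- simulation_config(noise_cv = 0, detection_floor = 0)
  # round trip: full-window apparent minus the reagent contribution
  # recovers the requested enrichment level
  for (lev in c(1.1, 5, 50, 98)) {
    f <- (lev / 100 - 0.011) / (0.98 - 0.011)
    cfg_i <- simulation_config(label_fraction = f, noise_cv = 0,
                               detection_floor = 0)
    full <- simulate_spectrum(gly, cfg_i, window = "full")
    apparent <- atom_percent_13c(unname(full$intensities), n = 2)
    recovered <- apparent - (gly$c_reagent / gly$c_compound) * 1.1
    expect_equal(recovered, lev, tolerance = 1e-9)
  }
  # level at natural abundance means no labeled material
  std <- simulate_dilution_series(gly, c(1.1, 2), cfg)
  expect_true(all(std$true_atom_pct %in% c(1.1, 2)))
  expect_error(simulate_dilution_series(gly, 99.5, cfg),
               class = "aqc13c_domain_error")
  expect_error(simulate_dilution_series(gly, 0.5, cfg),
               class = "aqc13c_domain_error")
})

test_that("the five lowest levels are simulated in triplicate", {
  gly <- compound_spec("Gly", 2)
  cfg <- simulation_config(noise_cv = 0)
  levels <- c(1.1, 1.5, 2, 2.5, 3, 4, 5)
  std <- simulate_dilution_series(gly, levels, cfg)
  reps <- tapply(std$replicate, std$true_atom_pct, max)
  expect_equal(as.vector(reps[as.character(c(1.1, 1.5, 2, 2.5, 3))]),
               rep(3, 5))
  expect_equal(as.vector(reps[as.character(c(4, 5))]), rep(1, 2))
  # explicit override wins
  std1 <- simulate_dilution_series(gly, levels, cfg, replicates = 1L)
  expect_true(all(std1$replicate == 1L))
})

test_that("concentration series reproduces proportional areas and censoring bias", {
  gly <- compound_spec("Gly", 2)
  cfg0 <- simulation_config(noise_cv = 0, detection_floor = 0)
  ser <- simulate_concentration_series(gly, c(75, 150, 300), cfg0)
  areas <- tapply(ser$intensity, ser$concentration_uM, sum)
  expect_equal(unname(areas["150"] / areas["300"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(areas["75"] / areas["300"]), 0.25, tolerance = 1e-12)
  # without a floor the top concentration matches the analytic window value
  top <- ser[ser$concentration_uM == 300, ]
  expect_equal(atom_percent_13c(top$intensity[order(top$k)], n = 2),
               atom_percent_13c(isotopologue_distribution(gly, 0.011)[1:3],
                                n = 2),
               tolerance = 1e-12)
  # with the floor, low concentrations lose higher isotopologues and the
  # apparent value can only decrease (monotone censoring bias)
  cfg <- simulation_config(noise_cv = 0)
  serc <- simulate_concentration_series(gly, default_concentration_series(),
                                        cfg)
  enr <- enrichment_table(serc)
  enr <- enr[order(enr$total_area), ]
  expect_lt(enr$apparent_atom_pct[1],
            enr$apparent_atom_pct[nrow(enr)])
  expect_true(all(enr$apparent_atom_pct <=
                    enr$apparent_atom_pct[nrow(enr)] + 1e-9))
  expect_error(simulate_concentration_series(gly, c(-1, 10), cfg),
               class = "aqc13c_domain_error")
})
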