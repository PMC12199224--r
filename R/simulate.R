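#' Simulator configuration
#'
#' Parameters of the mechanistic isotopologue simulator. The simulator
#' emulates what the mass spectrometer records for an AQC derivative: a
#' mixture of molecules drawn from a uniformly labeled pool (compound
#' carbons at `p_compound` fractional 13C) and an unlabeled pool (compound
#' carbons at natural abundance), with reagent carbons always at natural
#' abundance; intensities carry multiplicative lognormal noise and any
#' isotopologue falling below the detection floor is censored to zero.
#'
#' Defaults correspond to a 300 uM reference injection: total intensity
#' 1e6 with a detection floor of 1e3, which reproduces the detection-loss
#' biases seen on Orbitrap data (tenths of an atom % up to several atom %
#' at the lowest concentrations of a 2.3-300 uM series), and a 0.2%
#' intensity CV, which reproduces the reported precision of
#' natural-abundance atom % 13C measurements (replicate SD of a few
#' hundredths of an atom %).
#'
#' @param p_compound fractional 13C enrichment of compound carbons in the
#'   labeled pool (0-1); uniformly labeled commercial mixtures are 97-99
#'   atom %, default 0.98.
#' @param p_natural natural fractional 13C abundance, default 0.011.
#' @param label_fraction fraction of molecules drawn from the labeled pool.
#' @param total_intensity summed intensity of the full (untruncated)
#'   isotopologue distribution, arbitrary units.
#' @param detection_floor intensity below which an isotopologue is not
#'   detected (censored to 0).
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   intensity noise.
#' @param seed optional integer seed for reproducible draws.
#' @return An object of class `"simulation_config"`.
#' @export
simulation_config <- function(p_compound = 0.98, p_natural = NATURAL_13C,
                              label_fraction = 0, total_intensity = 1e6,
                              detection_floor = 1e3, noise_cv = 0.002,
                              seed = NULL) {
  for (p in c(p_compound, p_natural, label_fraction))
    if (!is.finite(p) || p < 0 || p > 1)
      abort_aqc("probabilities must lie in [0, 1]", "aqc13c_domain_error")
  if (!is.finite(total_intensity) || total_intensity <= 0)
    abort_aqc("'total_intensity' must be > 0", "aqc13c_domain_error")
  if (!is.finite(detection_floor) || detection_floor < 0)
    abort_aqc("'detection_floor' must be >= 0", "aqc13c_domain_error")
  if (!is.finite(noise_cv) || noise_cv < 0)
    abort_aqc("'noise_cv' must be >= 0", "aqc13c_domain_error")
  structure(
    list(p_compound = p_compound, p_natural = p_natural,
         label_fraction = label_fraction, total_intensity = total_intensity,
         detection_floor = detection_floor, noise_cv = noise_cv,
         seed = seed),
    class = "simulation_config"
  )
}

#' Analytic isotopologue distribution of a derivative
#'
#' Probability of observing k heavy carbons in the derivative, for
#' k = 0..(c_compound + c_reagent): the convolution of
#' Binomial(c_compound, p_compound) for the compound carbons with
#' Binomial(c_reagent, p_natural) for the reagent carbons. This is the
#' mechanistic reason the apparent enrichment of a derivative exceeds the
#' true enrichment of the compound: reagent carbons contribute heavy
#' isotopologues of their own.
#'
#' @param spec a [compound_spec()].
#' @param p_compound fractional 13C of the compound carbons.
#' @param p_natural fractional 13C of the reagent carbons.
#' @return Numeric probability vector of length
#'   `c_compound + c_reagent + 1`, summing to 1.
#' @examples
#' d <- isotopologue_distribution(compound_spec("Gly", 2), 0.011)
#' sum(d)  # 1
#' @export
isotopologue_distribution <- function(spec, p_compound,
                                      p_natural = NATURAL_13C) {
  stopifnot(inherits(spec, "compound_spec"))
  if (p_compound < 0 || p_compound > 1 || p_natural < 0 || p_natural > 1)
    abort_aqc("probabilities must lie in [0, 1]", "aqc13c_domain_error")
  d1 <- stats::dbinom(0:spec$c_compound, spec$c_compound, p_compound)
  d2 <- stats::dbinom(0:spec$c_reagent, spec$c_reagent, p_natural)
  out <- numeric(spec$c_compound + spec$c_reagent + 1L)
  for (i in seq_along(d1)) {
    idx <- (i - 1L) + seq_along(d2)
    out[idx] <- out[idx] + d1[i] * d2
  }
  out
}

# labeled/unlabeled two-pool mixture over the full heavy-atom range
mixture_distribution <- function(spec, cfg) {
  lab <- isotopologue_distribution(spec, cfg$p_compound, cfg$p_natural)
  unl <- isotopologue_distribution(spec, cfg$p_natural, cfg$p_natural)
  cfg$label_fraction * lab + (1 - cfg$label_fraction) * unl
}

#' Simulate one isotopologue spectrum
#'
#' Draws the recorded intensities S0..Sn (n = compound carbon count) of one
#' derivative: the two-pool mixture distribution is scaled to
#' `total_intensity`, truncated to the recorded window M0..Mn, perturbed by
#' multiplicative lognormal noise (mean 1, CV `noise_cv`), and censored at
#' the detection floor. With `window = "full"` the untruncated distribution
#' over all heavy-atom counts is returned instead (useful for closed-form
#' checks; a real instrument records only the window).
#'
#' @param spec a [compound_spec()].
#' @param cfg a [simulation_config()].
#' @param window `"recorded"` (M0..Mn, default) or `"full"`.
#' @return An object of class `"isotopologue_spectrum"`: list with
#'   `compound`, `intensities` (named `M0`..), `total_area`.
#' @export
simulate_spectrum <- function(spec, cfg, window = c("recorded", "full")) {
  stopifnot(inherits(spec, "compound_spec"),
            inherits(cfg, "simulation_config"))
  window <- match.arg(window)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  p <- mixture_distribution(spec, cfg)
  if (window == "recorded") p <- p[seq_len(spec$c_compound + 1L)]
  intens <- cfg$total_intensity * p
  if (cfg$noise_cv > 0) {
    sdlog <- sqrt(log1p(cfg$noise_cv^2))
    intens <- intens * stats::rlnorm(length(intens), -sdlog^2 / 2, sdlog)
  }
  intens[intens < cfg$detection_floor] <- 0
  structure(
    list(compound = spec$name,
         intensities = stats::setNames(intens,
                                       paste0("M", seq_along(intens) - 1L)),
         total_area = sum(intens)),
    class = "isotopologue_spectrum"
  )
}

#' @export
print.isotopologue_spectrum <- function(x, ...) {
  cat(sprintf("<isotopologue_spectrum> %s: %d isotopologues, total area %.4g\n",
              x$compound, length(x$intensities), x$total_area))
  print(signif(x$intensities, 4))
  invisible(x)
}

# label_fraction achieving a target atom % for the compound carbons
label_fraction_for <- function(level_pct, p_compound, p_natural) {
  (level_pct / 100 - p_natural) / (p_compound - p_natural)
}

#' Simulate an isotopic dilution series of standards
#'
#' Emulates mixing a uniformly 13C-labeled and an unlabeled standard so the
#' compound carbons average the requested atom % 13C levels (from natural
#' abundance up to the labeled-pool enrichment). Following standard
#' practice for determining isotopic detection limits, the five lowest
#' levels are simulated in triplicate and the rest singly, unless
#' `replicates` overrides this.
#'
#' @param spec a [compound_spec()].
#' @param enrichment_levels true atom % 13C levels of the compound carbons.
#' @param cfg a [simulation_config()]; its `label_fraction` is ignored
#'   (derived per level) and `seed`, if set, seeds the whole series once.
#' @param replicates optional integer vector (recycled) of replicate counts
#'   per level.
#' @return A long-format `data.frame` with columns `sample`, `compound`,
#'   `true_atom_pct`, `replicate`, `k`, `mz`, `intensity` — the same schema
#'   the analysis functions read.
#' @export
simulate_dilution_series <- function(spec, enrichment_levels, cfg,
                                     replicates = NULL) {
  stopifnot(inherits(spec, "compound_spec"),
            inherits(cfg, "simulation_config"))
  lo <- cfg$p_natural * 100
  hi <- cfg$p_compound * 100
  if (any(enrichment_levels < lo - 1e-9) || any(enrichment_levels > hi + 1e-9))
    abort_aqc(sprintf(
      "enrichment levels must lie between natural abundance (%.3g) and the labeled pool (%.3g atom %%)",
      lo, hi), "aqc13c_domain_error")
  if (is.null(replicates)) {
    replicates <- rep(1L, length(enrichment_levels))
    n_trip <- min(5L, length(enrichment_levels))
    replicates[order(enrichment_levels)[seq_len(n_trip)]] <- 3L
  } else {
    replicates <- rep_len(as.integer(replicates), length(enrichment_levels))
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mz <- if (is.na(spec$mz_m0)) rep(NA_real_, spec$c_compound + 1L)
        else isotopologue_ladder(spec)
  rows <- list()
  for (i in seq_along(enrichment_levels)) {
    lev <- enrichment_levels[i]
    cfg_i <- cfg
    cfg_i$label_fraction <- min(max(
      label_fraction_for(lev, cfg$p_compound, cfg$p_natural), 0), 1)
    cfg_i$seed <- NULL
    for (r in seq_len(replicates[i])) {
      sp <- simulate_spectrum(spec, cfg_i)
      rows[[length(rows) + 1L]] <- data.frame(
        sample = sprintf("std_%g_r%d", lev, r),
        compound = spec$name,
        true_atom_pct = lev,
        replicate = r,
        k = seq_along(sp$intensities) - 1L,
        mz = unname(mz),
        intensity = unname(sp$intensities),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate a concentration series at fixed enrichment
#'
#' Total intensity scales proportionally with concentration while the
#' detection floor stays fixed, so lower concentrations successively lose
#' their higher isotopologues — the mechanism behind the
#' concentration-dependent underestimation of apparent atom % 13C.
#'
#' @param spec a [compound_spec()].
#' @param concentrations concentrations in uM, > 0.
#' @param cfg a [simulation_config()]; `total_intensity` is the intensity
#'   at `reference_concentration`.
#' @param reference_concentration concentration (uM) at which
#'   `cfg$total_intensity` applies; default 300.
#' @return A long-format `data.frame` with columns `sample`, `compound`,
#'   `concentration_uM`, `k`, `mz`, `intensity`.
#' @export
simulate_concentration_series <- function(spec, concentrations, cfg,
                                          reference_concentration = 300) {
  stopifnot(inherits(spec, "compound_spec"),
            inherits(cfg, "simulation_config"))
  if (any(concentrations <= 0))
    abort_aqc("concentrations must be > 0", "aqc13c_domain_error")
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  mz <- if (is.na(spec$mz_m0)) rep(NA_real_, spec$c_compound + 1L)
        else isotopologue_ladder(spec)
  rows <- lapply(concentrations, function(conc) {
    cfg_i <- cfg
    cfg_i$total_intensity <- cfg$total_intensity *
      conc / reference_concentration
    cfg_i$seed <- NULL
    sp <- simulate_spectrum(spec, cfg_i)
    data.frame(
      sample = sprintf("conc_%g", conc),
      compound = spec$name,
      concentration_uM = conc,
      k = seq_along(sp$intensities) - 1L,
      mz = unname(mz),
      intensity = unname(sp$intensities),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Default serial dilution used for concentration standards
#'
#' Two-fold serial dilution from 300 uM down to 2.344 uM (8 levels).
#'
#' @return Numeric vector of concentrations in uM, increasing.
#' @export
default_concentration_series <- function() {
  300 / 2^(7:0)
}

#' Rebuild spectra from a long intensity table
#'
#' @param table long-format intensity table with columns `sample`,
#'   `compound`, `k`, `intensity` (extra columns are carried along in the
#'   attribute `"meta"` of each spectrum).
#' @return Named list of `"isotopologue_spectrum"` objects, one per
#'   sample x compound, names `"<sample>.<compound>"`.
#' @export
as_spectra <- function(table) {
  check_intensity_table(table)
  if (nrow(table) == 0L) return(list())
  key <- interaction(table$sample, table$compound, drop = TRUE, sep = ".")
  lapply(split(table, key), function(df) {
    df <- df[order(df$k), ]
    structure(
      list(compound = df$compound[1L],
           intensities = stats::setNames(df$intensity, paste0("M", df$k)),
           total_area = sum(df$intensity)),
      class = "isotopologue_spectrum"
    )
  })
}
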