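---
title: "Isotope calibration of AQC-derivatized amino compounds: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope calibration of AQC-derivatized amino compounds: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aqc13c)
```

## The measurement problem

Amino acids and amino sugars are routinely quantified by LC-MS after
precolumn derivatization with AQC
(6-aminoquinolyl-N-hydroxysuccinimidyl carbamate), which tags primary and
secondary amines and adds exactly 10 carbon atoms per tag. For stable
isotope tracing this tag is a mixed blessing: it makes the compounds
chromatograph and ionize well, but it dilutes the ¹³C signal of the
compound with reagent carbon at natural abundance. A glycine derivative
carries 2 compound carbons and 10 reagent carbons, so only one sixth of
its carbon reports on the tracer. The package quantifies this dilution as
the *fold dilution of carbon number*,

$$FD_C = \frac{C_{compound} + C_{reagent}}{C_{compound}},$$

which spans 6 (glycine) down to 2.11 (tyrosine, phenylalanine) across the
proteinogenic amino acids (`fold_dilution()`).

The enrichment estimator works on the isotopologue intensities
$S_0 \dots S_n$ of the derivative, where $n$ is the carbon count of the
*native* compound — only the window $M_0 \dots M_n$ is recorded, because
higher isotopologues are not observed at low enrichment:

$$\text{atom \% }^{13}C = 100 \cdot
  \frac{\sum_{k=1}^{n} k\, S_k}{n \sum_{k=0}^{n} S_k}.$$

This apparent value systematically exceeds the true enrichment of the
compound because reagent carbons contribute heavy isotopologues of their
own. For an uncensored, untruncated spectrum the relationship is exact and
linear: the apparent value at natural abundance equals
$1.1 \times FD_C$ atom % (linearity of expectation over the binomial
convolution below). This closed form is the mechanistic anchor of the
whole calibration strategy, and the package tests verify it against an
atom-level enumeration oracle.

Two further biases push the apparent value *down*:

* **Window truncation.** Isotopologues beyond $M_n$ are never recorded.
* **Detection censoring.** With falling signal (lower concentration, or
  lower enrichment at fixed concentration), higher isotopologues drop
  below the instrument's detection limit one at a time. This produces the
  concentration-dependent underestimation corrected by the offset model,
  and the curvature that makes low-range calibrations quadratic.

## The forward model (simulator)

`isotopologue_distribution()` computes the heavy-atom distribution of a
derivative as the convolution of Binomial($C_{compound}$, $p$) for the
compound carbons with Binomial($C_{reagent}$, 0.011) for the reagent
carbons. Isotopic standards are a *mixture of two pools* — a uniformly
labeled pool ($p = 0.98$, matching commercial U-¹³C material at 97–99
atom %) and an unlabeled pool ($p = 0.011$) — not a single binomial at an
intermediate enrichment; the two give different isotopologue patterns at
the same mean enrichment, and the mixture is what mixing standards
physically does. `simulate_spectrum()` scales the mixture to a total
intensity, truncates to the recorded window, applies multiplicative
lognormal noise (mean 1), and censors intensities below a detection
floor.

Defaults, chosen once on physical grounds:

| parameter | default | rationale |
|---|---|---|
| `p_compound` | 0.98 | U-¹³C labeled standards are 97–99 atom % |
| `p_natural` | 0.011 | natural ¹³C abundance (1.1 atom %) |
| `total_intensity` | 1e6 | arbitrary units at the 300 µM reference |
| `detection_floor` | 1e3 | 1e-3 relative floor reproduces isotope deviations of ~0.3 up to several atom % at the bottom of a 2.34–300 µM two-fold dilution series, the magnitude observed on Orbitrap data |
| `noise_cv` | 0.002 | yields a replicate SD of apparent atom % at natural abundance of ~0.02 atom %, matching the reported precision of such measurements (SDs of 0.0001–0.05, average 0.012 atom %) |

The simulator emulates: binomial isotope incorporation, reagent dilution,
two-pool mixing, truncation, censoring, and intensity noise. It does
*not* emulate chromatographic peak shapes, co-elution, fine isotope
structure (¹⁵N/¹⁸O/²H), adduct chemistry, ion suppression, or
matrix effects — so passing tests demonstrate that the *statistical
machinery* recovers truth under the stated error mechanisms, not that any
particular instrument is bias-free. Resolution 70,000 separates ¹³C from
¹⁵N isotopologues (0.0063 Da apart; `required_resolution()`), which is
why a carbon-only model is adequate for the intended platform.

## Offset correction

The deviation `apparent(reference) − apparent(area)` of natural-abundance
standards is modelled as a monotone decreasing function of
log₁₀(total area), anchored at zero deviation at the reference area (the
300 µM standard, where all quantitatively important isotopologues are
measured). Corrected values are
`apparent + deviation(total_area)`, applied **before** isotope
calibration; the pipeline enforces this order.

The default functional form is an isotonic (monotone) regression with
linear interpolation between fitted points, clamped outside the fitted
area range. A smooth low-order polynomial was considered and is available
(`form = "quadratic"`, anchored at the reference), but with a hard
detection floor the noise-free deviation is a *step* function of log
area — each step is one isotopologue crossing the floor — and a
three-parameter parabola leaves residuals of the order of 1 atom % for
high-$FD_C$ compounds, defeating the purpose of the correction. The
isotonic form restores uncensored values exactly on noise-free series and
to within a few hundredths of an atom % under the default noise.

The deviation is treated as additive in atom % (it is defined as a
difference from the reference); a multiplicative variant was not
implemented because the correction is anchored where the deviation is
zero, where the two parameterizations coincide.

## Calibration curves

Calibration relates measured (offset-corrected) atom % ¹³C ($x$) to the
true enrichment of the standards ($y$):

* `fit_full_range()` — ordinary least squares line across the whole
  range (natural abundance to 98 atom %); requires a span of at least
  50 atom %.
* `fit_low_range()` — unweighted least-squares quadratic
  $y = ax^2 + bx + c$ for the low range (natural abundance to ~5 atom %,
  the regime of realistic tracer studies); warns when $R^2 < 0.990$, the
  conventional acceptance threshold for these fits.

Choices made where the design was open: the low-range upper bound
defaults to 5 atom % (keeping at least five standard levels in range)
and is configurable; triplicate standards enter as individual points;
the polynomial is *not* constrained through the natural-abundance point
(the unconstrained fit lets the data determine the intercept, and the
round-trip tests confirm calibrated natural-abundance standards converge
to 1.1 atom % regardless); fits are unweighted. Degenerate inputs
(fewer than 4 points for a quadratic, fewer than 3 distinct abscissae)
raise classed fit errors rather than returning silently singular fits.
Out-of-range evaluation returns the value but flags it
(`attr(, "out_of_range")`) and warns — a calibration is a statement about
an interval, and users should see when they leave it.

## The prediction cascade

Many biogeochemically important compounds (muramic acid, hydroxyproline,
diaminopimelic acid, amino sugars) are unavailable or prohibitively
expensive as ¹³C-labeled standards. The cascade predicts their low-range
calibration curves from chemistry alone:

1. natural-abundance apparent atom % ~ $FD_C$ (linear; the closed form
   above predicts slope ≈ 1.1 atom % per $FD_C$ unit, attenuated
   slightly by window truncation);
2. constant term $c$ ~ natural-abundance apparent (nonlinear);
3. linear term $b$ ~ $c$ (nonlinear);
4. quadratic term $a$ ~ $c$ (nonlinear).

The nonlinear stages default to a second-order polynomial in the
predictor — the lowest-order form able to bend, fitted stably on few
compounds — with a power law ($y = \alpha x^\beta$, fitted on log–log
scale, positive data only) as the alternative. The form identifier is
stored in the model. Molecular weight and C:N ratio were considered as
stage-1 predictors and rejected; $FD_C$ is the mechanistically motivated
choice and the only one used. Uncertainty propagates through the chain
(a predicted $c$ feeds stages 3 and 4); the package reports per-stage
$R^2$ and deliberately no formal confidence intervals, which would
suggest more precision than a four-stage chain on a handful of compounds
supports.

`predict_curve()` refuses nothing but warns and flags: curves for
compounds outside the training $FD_C$ range carry an `extrapolated`
attribute, and every predicted curve is flagged `predicted` so downstream
tables record provenance.

Evaluation follows the 1:1-line convention: `evaluate_cascade_loo()`
refits the cascade leaving one compound out, predicts its curve from
$FD_C$ alone, and regresses predicted against measured calibrated values
(slope ≈ 1, intercept ≈ 0 for an accurate model), alongside MAD
(mean absolute deviation, atom %) and MAPD (mean absolute percentage
deviation) with the conventional categories: excellent (MAPD < 10%),
good (10–20%), reasonable (≤ 50%), poor beyond. Boundaries are closed
exactly as stated (MAPD = 10 and 20 are "good", 50 is "reasonable").
The highest-$FD_C$ compound (glycine) is reliably the hardest to
predict — its leave-one-out prediction is an extrapolation in $FD_C$ —
and typically lands in the "reasonable" class while all others are
excellent or good; the same pattern is seen on real calibration sets.

## Detection limits

Concentration limits follow the S/N convention:
$LOD = c_{lowest} \cdot 3 / (S/N)$, $LOQ = c_{lowest} \cdot 10 / (S/N)$.
Isotopic limits scale the replicate precision of natural-abundance
measurements: $LOD = 3\sigma$, $LOQ = 10\sigma$ (≥ 3 replicates
required). Both pairs satisfy $LOQ/LOD = 10/3$ identically, and both are
first-order homogeneous in their noise input — properties the tests
assert exactly.

## Problem sizes and reproducibility

The test suite and the acceptance script run entirely on simulated data:
calibration sets of 5–10 compounds with 7 standard levels (five lowest in
triplicate, 17 spectra per compound), concentration series of 8 two-fold
dilution levels in up to 3 replicates, and 100-replicate
natural-abundance batches — sizes matching the laboratory workflow the
package models, where a calibration batch is a few dozen injections per
compound. Every stochastic step flows from a single user-supplied seed;
rerunning any pipeline with the same inputs and seed reproduces outputs
exactly, which the tests check with `identical()`.

## Known limitations

* Derivative m/z values are registry constants; the package does not
  compute them from elemental formulas, and ships only the glycine value.
  The isotopologue ladder therefore requires a registered `mz_m0`.
* ¹⁵N tracers are out of scope: the calibrations and cascade would need
  to be re-established for nitrogen, though the machinery is agnostic.
* The hexosamines (glucosamine, galactosamine, mannosamine) co-elute
  under the modelled chromatography and are registered as a single summed
  pool.
* Cascade predictions inherit the training set's instrument and batch
  conditions; transferring curves between platforms is explicitly not
  supported.
* The simulator's noise and censoring parameters are assumptions
  calibrated to reproduce reported bias and precision magnitudes, not
  fitted to raw instrument data.
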