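---
title: "OSLD-based CT dosimetry: models, calibration protocols, and uncertainty"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OSLD-based CT dosimetry: models, calibration protocols, and uncertainty}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osldose)
```

## The dose formalism

Point dosimetry with an Al~2~O~3~:C optically stimulated luminescent
dosimeter (OSLD, the "nanoDot" form factor) determines absorbed dose to
water from a reader signal through a multiplicative chain:

$$D \;=\; \bar M_{corr}\times N_{D,W}\times k_L\, k_F\, k_G\, k_\theta\, k_Q$$

where $\bar M_{corr}$ is the corrected mean reader signal (counts),
$N_{D,W}$ the calibration coefficient (mGy/count), and the $k$ factors
correct for linearity, fading, irradiation geometry, detector angle, and
beam quality. At CT doses and with dosimeters placed flat in the bore,
read out on a consistent schedule, $k_L = k_F = k_\theta = 1$ exactly;
the interesting factors are $k_Q$ — strongly energy-dependent for
Al~2~O~3~:C at diagnostic energies — and, for a megavoltage calibration,
the geometry factor $k_G = 1.03$ (static en-face calibration versus a
source rotating around the detector face).

`osldose` implements this chain end to end: signal correction
(`correct_reading_sequence`, `pool_corrected_signals`), ion-chamber
reference dosimetry (`chamber_dose_to_water`), three calibration
protocols (`calibrate_vendor`, `calibrate_ct_air`,
`calibrate_megavoltage`), correction-factor lookup (`factor_set_for`),
dose computation (`compute_dose`), and exact-moment uncertainty
propagation (`var_product`, `var_chain`, `dose_uncertainty_budget`) with
a Monte Carlo oracle (`mc_oracle`). A synthetic-data module
(`scanner_truth_model`, `simulate_study`) generates seeded sessions with
the statistical structure the analysis assumes, so every stage is
testable without instruments.

## The corrected signal

Each optical read depletes the stored signal by a small fraction
(default 1.6% per read for a 7-s strong-LED readout). The estimator is

$$\bar M_{corr} = k_{s,i}\cdot\frac{1}{J}\sum_{j=1}^{J} M_{raw,j}\, c_d^{\,j-1} \;-\; M_{bkg}$$

with $c_d = (1-\ell)^{-1}$ the restoring factor for per-read loss
$\ell$: later reads are corrected *upward* to first-read equivalence, so
the mean of $J$ reads estimates the first-read signal, which is what a
calibration against a known dose requires. Commissioning data expressed
as a raw retention factor instead are supported through the
`convention = "retention"` toggle of `depletion_model()`. Background
defaults to 0 and is treated as exact; it is subtracted last, after the
sensitivity scaling, exactly as the formalism is written.

**Element-sensitivity convention.** The estimator multiplies by the
per-dosimeter factor $k_{s,i}$. For that multiplication to cancel
element-to-element variation, the package adopts the convention that a
dosimeter's raw response is proportional to $1/k_{s,i}$ — i.e. the
stored $k_s$ is the *correction*, whose batch mean carries the batch's
inherent-sensitivity scale (0.85 for the vendor calibration batch, 0.93
for the experimental batch in the commissioning this package mirrors).
`measure_element_sensitivity()` implements the batch procedure
(irradiate all dosimeters to a common dose; each factor is own signal
over batch-mean signal), so measured factors average to exactly 1 over
the defining batch. Under this convention a whole batch's corrected
signals scale as (experimental mean / own-batch mean), which is
precisely what the multiplicative vendor batch adjustment
$0.93/0.85 = 1.094$ undoes — and the package's vendor calibration is,
by construction and by test, invariant to a global rescaling of the
calibration batch's sensitivity.

**Variance.** For $J\ge 2$ reads the variance of a single dosimeter's
mean is the unbiased sample variance of the corrected reads over $J$;
for $J = 1$ it falls back to a configured reader-noise model (default
0.8% at 2 sigma). Pooling replicate dosimeters uses the sample variance
of the pooled values over $n$: the observed between-dosimeter scatter
already contains read noise and sensitivity error in expectation, so
nothing is double-counted. For explicitly correlated reads,
`mean_signal_variance()` exposes the shared-latent model: reads of one
dosimeter share the true signal (covariance = latent variance, no $1/J$
reduction of that part), dosimeters are independent.

## Calibration protocols

* **Vendor** — manufacturer-irradiated standards (80 kVp on PMMA, dose
  levels 0/3/20 mGy, stated to ±5% at 2 sigma). A single coefficient is
  fitted by zero-intercept least squares of dose on signal over the
  non-zero levels: the through-origin fit is the multi-level
  generalization of the defining ratio $N_{D,W} = D/\bar M_{corr}$, and
  the zero level is carried only as a background check. The batch
  adjustment multiplies the result. The vendor's energy handling is a
  single constant $k_Q = 1.19$ for all CT measurements — the source of
  this protocol's large, energy-dependent residual bias.
* **Free-in-air CT** — OSLD standards and a calibrated farmer-type
  chamber irradiated identically at isocenter (120 kVp, no phantom).
  The chamber dose uses the TG-111 form
  $D_w = q\,P_{TP}\,P_{elec}\,N_k\,(\bar\mu_{en}/\rho)_{air}^{water}$;
  reference conditions default to 22 °C / 101.33 kPa and the
  water-to-air mass energy-absorption ratio defaults to 1.06 — both are
  visible configuration, not hard-coded physics. Repeated chamber doses
  are pooled so that the systematic (calibration-chain, ±5% at 2 sigma)
  component does *not* average down; only repeatability scatter does.
* **Megavoltage (Co-60)** — standards irradiated to a known dose
  (45 mGy in the reference design) in a Co-60 beam, the delivered dose
  decay-corrected with half-life 1925.28 d (configurable) and known to
  0.9% at 2 sigma. This buys a very precise coefficient at the cost of
  a large, less certain $k_Q$ (≈0.29–0.39) plus $k_G = 1.03$.

## Correction-factor tables

$k_Q$ values ship as versioned JSON (`inst/extdata/kq_tables.json`),
never as code constants, because they are specific to the scanner
spectrum they were derived for. Three routes exist, in order of
preference: interpolation in mean spectral energy (for characterized
spectra; linear, exact at nodes, no extrapolation outside
45.4–64.9 keV), lookup by nominal kVp and position (the clinical
simplification; 3×3 per protocol), and the vendor constant. Loading
validates ranges and ordering (non-decreasing in energy/kVp; surface ≥
periphery ≥ center). The shipped energy table contains one printed
non-monotone pair (58.1 → 58.7 keV); validation *flags* it in a
`monotonicity_exceptions` attribute rather than "correcting" data.

The relative 2-sigma uncertainties attached to factors on lookup are
also configuration. The shipped defaults ($k_Q$: 12.4% vendor, 6.2% CT,
8.2% megavoltage; $k_G$: 1.0%) were chosen once so that the
demonstration budget lands on the published total-dose uncertainties
(≈13.5/8.3/8.5% at 2 sigma) given the published reading and
delivered-dose components; the underlying per-factor values come from
spectrum-specific cavity-theory work that is input, not output, here.

## Exact-moment uncertainty propagation

Rather than first-order quadrature, variances propagate through the
exact identities

$$\mathrm{var}(XY) = \mathrm{var}(X)\mathrm{var}(Y) + \mathrm{var}(X)E(Y)^2 + \mathrm{var}(Y)E(X)^2$$
$$\mathrm{var}(X+Y) = \mathrm{var}(X) + \mathrm{var}(Y) + 2\,\mathrm{Cov}(X,Y)$$

folded recursively over the dose chain (`var_chain`); the result is
independent of fold order, and strictly exceeds the root-sum-square
whenever two or more factors have positive variance. No normality
assumption enters. Quantities are stored as (expected value, absolute
variance) pairs; interfaces report relative 2-sigma percentages, the
field's convention. For quotients (the calibration coefficient) the
denominator's reciprocal is taken at first order
($\mathrm{var}(1/Y)\approx\mathrm{var}(Y)/E(Y)^4$, preserving its
relative variance) and then the exact product rule is applied; with the
reference components this yields the familiar coefficient uncertainties
1.6% (reading 1.3% ⊕ dose 0.9%) and 5.2% (reading 1.3% ⊕ dose 5%).

Independence assumptions: $\bar M_{corr}$, $N_{D,W}$ and the $k$
factors are treated as mutually independent; correlation is handled
only inside $\bar M_{corr}$ (repeated reads of one dosimeter) via the
covariance sum rule. `mc_oracle()` provides a seeded sampling check of
any propagation claim; the test suite requires agreement within three
Monte Carlo standard errors at $n = 10^6$.

```{r budget}
cond <- measurement_condition(120, "center", "32 cm",
                              mean_spectral_energy_keV = 55.3)
nd <- uq_from_rel(1e-3, coefficient_uncertainty(1.3, 5), "N_D")
dose_uncertainty_budget(uq_from_rel(3e4, 1.3, "M_corr"), nd,
                        factor_set_for("ct_air", cond))
```

## The synthetic-data generator

`scanner_truth_model()` fixes a ground truth — per-condition doses (the
packaged validation doses, 25–40 mGy), true coefficients, and the
energy-table $k_Q$ chain per protocol — and the generator inverts the
dose equation to produce raw count sequences: read $j$ of dosimeter $i$
has expectation $(M/k_{s,i})\cdot s_{batch}\cdot(1-\ell)^{\,j-1}$ with
multiplicative lognormal noise (signals are positive and all quoted
uncertainties are relative; a Gaussian switch exists). Defaults: read
noise 0.8% (2σ), element-sensitivity spread 1.0% (2σ) around the batch
mean, sensitivity-measurement error 1.0% (2σ), depletion 1.6%/read,
chamber repeatability 0.5% (2σ). Calibration sessions draw the
protocol's systematic delivered-dose/reporting error at its configured
scale (5/5/0.9% at 2σ), and measurement sessions draw the generating
$k_Q$ around its table value at the configured uncertainty, so
empirical dose errors are statistically consistent with the propagated
budget — which is what the coverage tests verify.

At `noise = FALSE` every protocol path is exactly invertible: simulated
calibrations recover the true coefficients to machine precision and the
full pipeline returns the true dose at every condition. The vendor path
is exact only because the generating vendor $k_Q$ equals the applied
constant 1.19; anchoring the signals to the CT chain instead reproduces
the energy-dependent vendor bias qualitatively.

What the generator does **not** emulate: spectral/photon-transport
physics (mean spectral energies are taken from the design table),
bowtie/phantom scatter, reader drift between sessions, angular
response, fading, and dose-response nonlinearity. Passing tests
therefore demonstrate the correctness and statistical honesty of the
*analysis chain*, not the physical accuracy of any particular scanner's
factor tables.

## Numerical choices and problem sizes

* Through-origin fit variance by the delta method on the slope, then
  the exact product rule for the common dose error.
* Linear interpolation only inside the tabulated energy span; missing
  lookup keys raise errors listing the available keys — never silent
  extrapolation.
* Degenerate inputs: single-read sequences use the reader-noise model;
  single-signal pools pass their own variance through; a corrected
  signal ≤ 0 is flagged `nonphysical` (and warned about) rather than
  erroring, since unirradiated standards legitimately sit near zero.
* Test problem sizes were chosen for statistical resolution at
  interactive runtimes: 200 simulated calibration sessions per protocol
  for bias/spread recovery (standard error of the spread ratio ≈ 5%),
  1000 replicates for 2-sigma coverage (binomial SE ≈ 0.7%), and
  $n = 10^6$ Monte Carlo draws for the propagation oracle.

## Known limitations

* The reciprocal in quotient propagation is first-order; for the
  percent-level relative uncertainties of this application the error is
  far below reporting precision, but the engine is not exact for
  quotients the way it is for products.
* The CT-protocol coefficient uncertainty is reproduced from configured
  components only; published budgets quote a slightly larger value
  whose extra component (chamber reading repeatability is a candidate)
  is not itemized anywhere, and the package does not guess it.
* Recomputing a published comparison table from rounded dose columns
  cannot reproduce every printed percent difference to one decimal;
  the package reports full-precision values and rounds only for
  display.
* $k_\theta\ne 1$ scenarios (non-flat placement) are supported only as
  user-supplied factors; the package contains no angular-response
  model.
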