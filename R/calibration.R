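#' Calibration coefficient N_D,W
#'
#' Dose-to-water per reader count, tagged with the protocol that produced
#' it. The three supported protocols are `"vendor"` (manufacturer-supplied
#' pre-irradiated standards), `"ct_air"` (free-in-air cross-calibration
#' against an ion chamber in a 120 kVp CT beam) and `"megavoltage"`
#' (Co-60 reference beam).
#'
#' @param value Coefficient in mGy per count. Positive.
#' @param variance Variance of the coefficient.
#' @param protocol One of `"vendor"`, `"ct_air"`, `"megavoltage"`.
#' @param batch_id Optional dosimeter-batch identifier.
#' @return An object of class `calibration_coefficient`.
#' @export
calibration_coefficient <- function(value, variance,
                                    protocol = c("vendor", "ct_air",
                                                 "megavoltage"),
                                    batch_id = NA_character_) {
  protocol <- match.arg(protocol)
  if (!is.numeric(value) || value <= 0)
    stop("coefficient value must be positive", call. = FALSE)
  if (variance < 0) stop("variance must be non-negative", call. = FALSE)
  structure(list(value = as.numeric(value), variance = as.numeric(variance),
                 protocol = protocol, batch_id = as.character(batch_id)),
            class = "calibration_coefficient")
}

#' @export
print.calibration_coefficient <- function(x, ...) {
  cat(sprintf("<calibration_coefficient> %s: %.6g mGy/count (rel 2-sigma %.2f%%)\n",
              x$protocol, x$value, rel_2sigma(as_uq(x))))
  invisible(x)
}

#' @export
as_uq.calibration_coefficient <- function(x, label = "N_D") {
  uq(x$value, x$variance, label)
}

#' Derive a calibration coefficient from one dose/signal pair
#'
#' `N_D = delivered dose / OSLD signal`, with the variance propagated by
#' the exact product rule applied to the dose and the reciprocal signal
#' (see [uq_quotient]).
#'
#' @param delivered_dose Dose to water in mGy, as a [uq] (or plain number
#'   for an exact dose). Must be positive.
#' @param signal A [corrected_signal] or [uq]; must be positive.
#' @param protocol Protocol tag for the result.
#' @param batch_id Optional batch identifier.
#' @return A [calibration_coefficient].
#' @examples
#' derive_coefficient(uq(45, 0), corrected_signal(45000, 0), "megavoltage")
#' @export
derive_coefficient <- function(delivered_dose, signal,
                               protocol = c("vendor", "ct_air", "megavoltage"),
                               batch_id = NA_character_) {
  protocol <- match.arg(protocol)
  d <- as_uq(delivered_dose, "D_delivered")
  s <- as_uq(signal, "M_corr")
  if (s$expected <= 0)
    stop("signal must be positive to derive a coefficient", call. = FALSE)
  if (d$expected <= 0)
    stop("delivered dose must be positive", call. = FALSE)
  q <- uq_quotient(d, s, "N_D")
  calibration_coefficient(q$expected, q$variance, protocol, batch_id)
}

#' Vendor calibration standard set
#'
#' The manufacturer-irradiated standards: known dose levels (0, 3 and
#' 20 mGy for the reader used here), the corrected signals read from them,
#' and the mean inherent sensitivities of the calibration and experimental
#' batches (0.85 and 0.93 in the commissioning that motivated this
#' package), whose ratio is the batch adjustment.
#'
#' @param dose_levels_mGy Non-negative dose levels, one per signal.
#' @param signals List of [corrected_signal] objects, one per level.
#' @param calibration_batch_mean_sensitivity Mean inherent sensitivity of
#'   the vendor calibration batch. Positive.
#' @param experimental_batch_mean_sensitivity Mean inherent sensitivity of
#'   the batch used for measurements. Positive.
#' @return An object of class `vendor_standard_set`.
#' @export
vendor_standard_set <- function(dose_levels_mGy, signals,
                                calibration_batch_mean_sensitivity = 0.85,
                                experimental_batch_mean_sensitivity = 0.93) {
  if (length(dose_levels_mGy) != length(signals))
    stop("one signal per dose level is required", call. = FALSE)
  if (any(dose_levels_mGy < 0))
    stop("dose levels must be non-negative", call. = FALSE)
  if (calibration_batch_mean_sensitivity <= 0 ||
      experimental_batch_mean_sensitivity <= 0)
    stop("batch mean sensitivities must be positive", call. = FALSE)
  structure(
    list(dose_levels_mGy = as.numeric(dose_levels_mGy), signals = signals,
         calibration_batch_mean_sensitivity = calibration_batch_mean_sensitivity,
         experimental_batch_mean_sensitivity = experimental_batch_mean_sensitivity),
    class = "vendor_standard_set"
  )
}

#' Vendor batch-sensitivity adjustment
#'
#' Ratio of the experimental batch's mean inherent sensitivity to the
#' calibration batch's, applied multiplicatively to the vendor
#' coefficient. For batch means 0.93 and 0.85 this is 1.094.
#'
#' @param v A [vendor_standard_set].
#' @return The adjustment factor (positive scalar).
#' @export
vendor_batch_adjustment <- function(v) {
  if (!inherits(v, "vendor_standard_set"))
    stop("'v' must be a vendor_standard_set", call. = FALSE)
  v$experimental_batch_mean_sensitivity /
    v$calibration_batch_mean_sensitivity
}

#' Calibrate against the vendor-provided standards
#'
#' Fits a single coefficient by zero-intercept least squares of dose on
#' signal over the non-zero dose levels (the multi-level generalization of
#' the dose/signal ratio), then applies the batch-sensitivity adjustment.
#' The random part of the variance comes from the signals' variances via
#' the delta method on the through-origin slope; the systematic
#' delivered-dose uncertainty (default 5% at 2 sigma, common to all
#' levels) multiplies in via the exact product rule.
#'
#' @param v A [vendor_standard_set] with at least two levels, at least one
#'   of them non-zero.
#' @param dose_rel_2sigma Relative 2-sigma uncertainty (percent) of the
#'   vendor-delivered doses. Default 5.
#' @return A [calibration_coefficient] tagged `"vendor"`.
#' @export
calibrate_vendor <- function(v, dose_rel_2sigma = 5) {
  if (!inherits(v, "vendor_standard_set"))
    stop("'v' must be a vendor_standard_set", call. = FALSE)
  if (length(v$dose_levels_mGy) < 2L)
    stop("vendor calibration needs at least two dose levels", call. = FALSE)
  keep <- v$dose_levels_mGy > 0
  if (!any(keep))
    stop("all dose levels are zero; cannot calibrate", call. = FALSE)
  D <- v$dose_levels_mGy[keep]
  S <- vapply(v$signals[keep], `[[`, numeric(1), "value")
  Svar <- vapply(v$signals[keep], `[[`, numeric(1), "variance")
  if (any(S <= 0))
    stop("non-positive signal at a non-zero dose level", call. = FALSE)
  Q <- sum(S^2)
  slope <- sum(D * S) / Q
  # delta method: d slope / d S_k = D_k/Q - 2 S_k slope / Q
  grad <- (D - 2 * S * slope) / Q
  var_fit <- sum(grad^2 * Svar)
  n_random <- uq(slope, var_fit, "slope")
  n_total <- var_product(n_random, uq_from_rel(1, dose_rel_2sigma, "D_standards"))
  adj <- vendor_batch_adjustment(v)
  calibration_coefficient(adj * n_total$expected, adj^2 * n_total$variance,
                          "vendor")
}

#' Pool uncertain dose measurements
#'
#' Mean of repeated dose determinations whose stated variances are
#' dominated by a common (systematic) calibration-chain component: the
#' systematic part (mean of the individual variances) does not average
#' down, while the observed repeatability scatter contributes its sample
#' variance of the mean.
#'
#' @param doses Non-empty list of [uq] doses.
#' @return A pooled [uq].
#' @export
pool_uncertain <- function(doses) {
  if (!is.list(doses) || length(doses) == 0L)
    stop("'doses' must be a non-empty list", call. = FALSE)
  doses <- lapply(doses, as_uq)
  values <- vapply(doses, `[[`, numeric(1), "expected")
  vars <- vapply(doses, `[[`, numeric(1), "variance")
  n <- length(values)
  repeat_var <- if (n >= 2L) stats::var(values) / n else 0
  uq(mean(values), mean(vars) + repeat_var, "D_pooled")
}

#' Calibrate against a free-in-air CT beam
#'
#' Cross-calibration at the scanner: OSLD standards and a calibrated ion
#' chamber are irradiated under identical free-in-air conditions (120 kVp
#' in the reference implementation), the chamber doses are pooled
#' (systematic component preserved, repeatability averaged), the OSLD
#' signals are pooled, and the coefficient is their ratio.
#'
#' @param osld_signals Non-empty list of [corrected_signal] objects
#'   (six dosimeters, three reads each, in the reference design).
#' @param chamber_doses Non-empty list of [uq] doses in mGy (three chamber
#'   readings in the reference design).
#' @param batch_id Optional batch identifier.
#' @return A [calibration_coefficient] tagged `"ct_air"`.
#' @export
calibrate_ct_air <- function(osld_signals, chamber_doses,
                             batch_id = NA_character_) {
  if (length(osld_signals) == 0L || length(chamber_doses) == 0L)
    stop("need at least one OSLD signal and one chamber dose", call. = FALSE)
  pooled_signal <- pool_corrected_signals(osld_signals)
  pooled_dose <- pool_uncertain(chamber_doses)
  derive_coefficient(pooled_dose, pooled_signal, "ct_air", batch_id)
}

#' Co-60 source description
#'
#' @param dose_rate_at_ref Dose rate in mGy/min at the reference distance
#'   on the reference date. Positive.
#' @param reference_date Date of the reference dose-rate determination
#'   (anything `as.Date` accepts).
#' @param half_life_days Half-life in days. Default 1925.28 (Co-60).
#' @return An object of class `co60_source`.
#' @export
co60_source <- function(dose_rate_at_ref, reference_date,
                        half_life_days = 1925.28) {
  if (dose_rate_at_ref <= 0 || half_life_days <= 0)
    stop("dose rate and half-life must be positive", call. = FALSE)
  structure(list(dose_rate_at_ref = dose_rate_at_ref,
                 reference_date = as.Date(reference_date),
                 half_life_days = half_life_days),
            class = "co60_source")
}

#' Decay-corrected delivered dose from a Co-60 source
#'
#' `dose = rate_ref * 2^(-dt / half_life) * beam_on_time`, with the
#' reference-dosimetry uncertainty attached (default 0.9% at 2 sigma, the
#' precision of clinical megavoltage reference dosimetry).
#'
#' @param src A [co60_source].
#' @param irradiation_date Date of the irradiation (on or after the
#'   reference date).
#' @param beam_on_time_min Beam-on time in minutes. Positive.
#' @param dose_rel_2sigma Relative 2-sigma uncertainty (percent) of the
#'   delivered dose. Default 0.9.
#' @return A [uq] dose in mGy.
#' @export
decay_corrected_dose <- function(src, irradiation_date, beam_on_time_min,
                                 dose_rel_2sigma = 0.9) {
  if (!inherits(src, "co60_source"))
    stop("'src' must be a co60_source", call. = FALSE)
  dt <- as.numeric(as.Date(irradiation_date) - src$reference_date)
  if (dt < 0) stop("irradiation date precedes the source reference date",
                   call. = FALSE)
  if (beam_on_time_min <= 0) stop("beam-on time must be positive", call. = FALSE)
  d <- src$dose_rate_at_ref * 2^(-dt / src$half_life_days) * beam_on_time_min
  uq_from_rel(d, dose_rel_2sigma, "D_Co60")
}

#' Calibrate against a megavoltage (Co-60) beam
#'
#' Pools the corrected signals of the standards (four dosimeters, three
#' reads each, in the reference design) and divides the decay-corrected
#' delivered dose by the pooled signal.
#'
#' @param signals Non-empty list of [corrected_signal] objects.
#' @param delivered Delivered dose as a [uq] in mGy (e.g. from
#'   [decay_corrected_dose]; 45 mGy in the reference design).
#' @param batch_id Optional batch identifier.
#' @return A [calibration_coefficient] tagged `"megavoltage"`.
#' @export
calibrate_megavoltage <- function(signals, delivered,
                                  batch_id = NA_character_) {
  if (length(signals) == 0L)
    stop("need at least one standard signal", call. = FALSE)
  pooled <- pool_corrected_signals(signals)
  derive_coefficient(delivered, pooled, "megavoltage", batch_id)
}

#' Write a calibration-coefficient record to JSON
#'
#' @param nd A [calibration_coefficient].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_coefficient <- function(nd, path) {
  if (!inherits(nd, "calibration_coefficient"))
    stop("'nd' must be a calibration_coefficient", call. = FALSE)
  rec <- list(value = nd$value, variance = nd$variance,
              rel_2sigma_pct = rel_2sigma(as_uq(nd)),
              protocol = nd$protocol, batch_id = nd$batch_id,
              units = "mGy/count",
              created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
              generator = paste0("osldose ",
                                 as.character(utils::packageVersion("osldose"))))
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a calibration-coefficient record from JSON
#'
#' @param path Path written by [write_coefficient].
#' @return A [calibration_coefficient].
#' @export
read_coefficient <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_coefficient(rec$value, rec$variance, rec$protocol,
                          rec$batch_id)
}
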