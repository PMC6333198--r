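#' Ion-chamber measurement record
#'
#' One reading of an open-to-atmosphere farmer-type CT chamber, with the
#' ambient conditions needed for the air-density correction.
#'
#' @param reading_q Chamber reading (charge or exposure, in the units the
#'   chamber was calibrated for). Positive.
#' @param temperature_C Air temperature in degrees Celsius (> -273.2).
#' @param pressure_kPa Air pressure in kPa. Positive.
#' @return An object of class `chamber_measurement`.
#' @export
chamber_measurement <- function(reading_q, temperature_C, pressure_kPa) {
  if (!is.numeric(reading_q) || reading_q <= 0)
    stop("'reading_q' must be positive", call. = FALSE)
  if (!is.numeric(temperature_C) || temperature_C <= -273.2)
    stop("'temperature_C' must exceed absolute zero (-273.2 C)", call. = FALSE)
  if (!is.numeric(pressure_kPa) || pressure_kPa <= 0)
    stop("'pressure_kPa' must be positive", call. = FALSE)
  structure(list(reading_q = reading_q, temperature_C = temperature_C,
                 pressure_kPa = pressure_kPa),
            class = "chamber_measurement")
}

#' Ion-chamber calibration data
#'
#' @param N_k Air-kerma calibration coefficient (dose per reading unit),
#'   from an accredited calibration lab. Positive.
#' @param P_elec Electrometer correction factor. Positive, default 1.
#' @param muen_ratio Ratio of mass energy-absorption coefficients,
#'   water to air, converting air kerma to dose to water. The default 1.06
#'   is representative of diagnostic CT beam qualities; it is deliberately
#'   a visible, overridable input rather than a hard-coded constant.
#' @return An object of class `chamber_calibration`.
#' @export
chamber_calibration <- function(N_k, P_elec = 1, muen_ratio = 1.06) {
  if (!all(c(N_k, P_elec, muen_ratio) > 0))
    stop("all calibration factors must be positive", call. = FALSE)
  structure(list(N_k = N_k, P_elec = P_elec, muen_ratio = muen_ratio),
            class = "chamber_calibration")
}

#' Temperature-pressure correction factor
#'
#' Normalizes an open chamber's reading to reference air density:
#' `P_TP = ((273.2 + T) / (273.2 + T_ref)) * (P_ref / P)`. Monotone
#' increasing in temperature, decreasing in pressure.
#'
#' @param m A [chamber_measurement].
#' @param ref_temperature_C Reference temperature, default 22 C.
#' @param ref_pressure_kPa Reference pressure, default 101.33 kPa.
#' @return The correction factor (positive scalar).
#' @examples
#' m <- chamber_measurement(1, 25, 100)
#' pressure_temperature_factor(m)  # (298.2/295.2) * (101.33/100)
#' @export
pressure_temperature_factor <- function(m, ref_temperature_C = 22,
                                        ref_pressure_kPa = 101.33) {
  if (!inherits(m, "chamber_measurement"))
    stop("'m' must be a chamber_measurement", call. = FALSE)
  if (ref_pressure_kPa <= 0 || ref_temperature_C <= -273.2)
    stop("non-physical reference conditions", call. = FALSE)
  ((273.2 + m$temperature_C) / (273.2 + ref_temperature_C)) *
    (ref_pressure_kPa / m$pressure_kPa)
}

#' Chamber dose to water
#'
#' Point dose to water from a calibrated chamber reading:
#' `D_water = q * P_TP * P_elec * N_k * (muen/rho)_air^water`. The
#' uncertainty attached to the result is the configured relative 2-sigma
#' of the delivered/reference dose for the beam in use (default 5%, the
#' conventional CT free-in-air reference-dose uncertainty).
#'
#' @param m A [chamber_measurement].
#' @param cal A [chamber_calibration].
#' @param ref_temperature_C,ref_pressure_kPa Reference conditions for
#'   [pressure_temperature_factor].
#' @param dose_rel_2sigma Relative 2-sigma uncertainty (percent) attached
#'   to the dose. Default 5.
#' @return A [uq] dose in mGy (same dose unit as `N_k`).
#' @export
chamber_dose_to_water <- function(m, cal, ref_temperature_C = 22,
                                  ref_pressure_kPa = 101.33,
                                  dose_rel_2sigma = 5) {
  if (!inherits(cal, "chamber_calibration"))
    stop("missing or invalid chamber calibration", call. = FALSE)
  ptp <- pressure_temperature_factor(m, ref_temperature_C, ref_pressure_kPa)
  d <- m$reading_q * ptp * cal$P_elec * cal$N_k * cal$muen_ratio
  uq_from_rel(d, dose_rel_2sigma, "D_chamber")
}

#' Read ion-chamber records from CSV
#'
#' Expected columns: `reading_q`, `temperature_C`, `pressure_kPa`, `N_k`,
#' `P_elec`, `muen_ratio`; one row per measurement.
#'
#' @param path Path to the CSV file.
#' @return The data.frame of records.
#' @export
read_chamber_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("reading_q", "temperature_C", "pressure_kPa", "N_k", "P_elec",
            "muen_ratio")
  if (!all(need %in% names(df)))
    stop("chamber CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df
}

#' Chamber doses from a record table
#'
#' Applies [chamber_dose_to_water] row-wise to a data.frame as returned by
#' [read_chamber_csv].
#'
#' @param df Chamber record data.frame.
#' @param ... Passed to [chamber_dose_to_water] (reference conditions,
#'   `dose_rel_2sigma`).
#' @return List of [uq] doses.
#' @export
chamber_doses <- function(df, ...) {
  lapply(seq_len(nrow(df)), function(i) {
    m <- chamber_measurement(df$reading_q[i], df$temperature_C[i],
                             df$pressure_kPa[i])
    cal <- chamber_calibration(df$N_k[i], df$P_elec[i], df$muen_ratio[i])
    chamber_dose_to_water(m, cal, ...)
  })
}
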